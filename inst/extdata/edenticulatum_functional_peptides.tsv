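# Previously reported verified and predicted emulsifier and antioxidant
# peptides from enzymatic Eucheuma denticulatum protein extracts, with
# published predictor score, parent protein ID(s) in the de novo reference
# database, sequence, length and net charge at pH 7 (one decimal).
# Classes: alpha/beta/gamma = EmulsiPred emulsifier conformation classes;
# SCA/CHE = AnOxPePred radical-scavenging / metal-chelating scores.
annotation	class	verified	score	protein_ids	peptide_sequence	length	charge_ph7
80-S-A	alpha	TRUE	3.3	c7052_g1_i1;c7052_g1_i2	IGYTVRNSLRVTVRDLSNLGLILDALVR	28	2
81-S-A	alpha	TRUE	2.9	c7052_g1_i1	AVKDAVRRATLLTKAAGTGLGKVLS	25	4
83-S-B	beta	TRUE	3.18	c7052_g1_i1;c7052_g1_i2	RAGSNSLSRISFGISNEADLRDQAR	25	1
84-S-B	beta	TRUE	2.75	c6313_g1_i1	VGFACSGSAQTYLSFEGDNTGRGEEEVAI	29	-4.1
85-S-B	beta	TRUE	3.27	c7052_g1_i1	LSIREGGRSTGGFSAQVRAR	20	3
86-S-B	beta	TRUE	5.43	c7052_g1_i1	ELQVSARVTLEIEL	14	-2
87-S-G	gamma	TRUE	5.72	c1505_g2_i1	RELQRDDNVRNVRILLSSLVLLLDWLVCLL	30	-0.1
88-S-G	gamma	TRUE	5.06	c1505_g2_i1	AVLVVCLQQVRELQRDDNVRN	21	-0.1
pEa-1	alpha	FALSE	3.77	c1545_g1_i1	VKRISGLIYEETRNVLKVF	19	2
pEa-2	alpha	FALSE	3.64	c13559_g1_i1;c6825_g1_i1	IYKVLKQV	8	2
pEa-3	alpha	FALSE	3.62	c10861_g1_i1	RFFLRVVRGVRQKV	14	5
pEa-4	alpha	FALSE	3.44	c14987_g1_i1	VQKLSRVID	9	1
pEa-5	alpha	FALSE	3.37	c6825_g1_i1	VADLFERIASEAAKL	15	-1
pEb-1	beta	FALSE	4.8	c7216_g1_i1	VRIRVDCK	8	1.9
pEb-2	beta	FALSE	4.12	c14987_g1_i1	RLNCKID	7	0.9
pEb-3	beta	FALSE	3.72	c4419_g1_i1	LKVELNSGGQMR	12	1
pEb-4	beta	FALSE	3.55	c907_g1_i1	NIQKESTLHLVLRLRGGL	18	2.1
pEb-5	beta	FALSE	3.2	c13533_g1_i1	AKVRVTC	7	1.9
pEg-1	gamma	FALSE	5.2	c13533_g1_i1	ITTVLALVCVITQVMQASANEQEHVHEHEH	30	-3.7
pEg-2	gamma	FALSE	5.11	c24_g1_i1.p2	ILLVLCLSWLRRKVCRNHR	19	5
pEg-3	gamma	FALSE	5.1	c10861_g1_i1	EREYELQKEFATLVLAVV	18	-2
pEg-4	gamma	FALSE	4.69	c17933_g1_i1	FLLVFFFFFTDEDT	14	-3
pEg-5	gamma	FALSE	4.43	c907_g1_i1	QDQQRLIFA	9	0
120-S-SCA	SCA	TRUE	0.49	c6313_g1_i1	RYVWN	5	1
123-S-SCA	SCA	TRUE	0.38	c6313_g1_i1	DFPVR	5	0
124-S-SCA	SCA	TRUE	0.43	c17304_g1_i1	AGDWLIGDR	9	-1
pSCA-1	SCA	FALSE	0.72	c6963_g1_i1	DFYAYIVFTWAGYHGVDLAKNKIASDF	27	-0.9
pSCA-2	SCA	FALSE	0.71	c24_g1_i1	WYHY	4	0.1
pSCA-3	SCA	FALSE	0.66	c10861_g1_i1	LQGSKFAVVEYGGIVDPILGLQP	23	-1
pSCA-4	SCA	FALSE	0.64	c13533_g1_i1	ASANEQEHVHEHEHIIRTFS	20	-2.6
pSCA-5	SCA	FALSE	0.64	c4419_g1_i1	VVPFSSWYAEQQRI	14	0
pCHE-1	CHE	FALSE	0.39	c17933_g1_i1	FFFFTDEDTFPSGPSLTTFCSP	22	-3.1
pCHE-2	CHE	FALSE	0.36	c6405_g1_i2	FAISLFRIFPASFMFMPFTH	20	1.1
pCHE-3	CHE	FALSE	0.35	c6405_g1_i2	PHPN	4	0.1
pCHE-4	CHE	FALSE	0.34	c7216_g1_i1	FFSALLLLMNFPSPTMSLCTDDD	23	-3.1
pCHE-5	CHE	FALSE	0.34	c13559_g1_i1;c24_g1_i1;c6405_g1_i2;c6656_g1_i1;c6825_g1_i1	HP	2	0.1
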