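---
title: "Methods: quantification, filtering, composition and peptide mining in phycoprot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantification, filtering, composition and peptide mining in phycoprot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

phycoprot post-processes label-free bottom-up proteomics of enzymatic
seaweed protein extracts. This vignette records the models it implements,
the defaults it ships, and the design decisions taken where the underlying
methodology leaves choices open.

## Relative quantification

Search engines report identified peptides with MS1 intensities per sample,
assigned to protein groups. Within one quantification unit — a sample
(extract) x technical replicate x digestion-mode cell — two in-sample
normalized abundance measures are computed per group:

* **riBAQ.** iBAQ divides the group's summed peptide intensity by the
  number of theoretically observable tryptic peptides of its
  representative protein; riBAQ rescales iBAQ to sum to one over the
  groups in the unit. The theoretical digest uses cleavage after Lys/Arg
  except before Pro. Defaults for the denominator window are 7–30 residues
  and zero missed cleavages — the common iBAQ convention; both are
  arguments of `quantify_groups()` because search-engine practice varies.
  Proteins with no in-range peptide are floored at a count of 1 so the
  quotient stays defined.
* **I~L~^rel^.** The summed intensity divided by the representative
  sequence length, again normalized within the unit. Length normalization
  approximates molar weighting when observed intensity scales with both
  molar amount and the number of observable peptides (itself roughly
  proportional to length).

Decisions where conventions diverge:

* The representative protein of a group is its **longest member**, ties
  broken lexicographically by ID. Search engines typically use a "leading"
  protein; length is the quantity that actually enters both estimators, so
  the longest member is the conservative anchor.
* Rows of the same peptide within a unit (charge states, repeated scans)
  are **summed** before quantification.
* Shared peptides count once, for the group the input table assigns them
  to; razor-style reassignment is upstream's responsibility.
* Groups present with zero summed intensity keep a row with abundance 0
  rather than being dropped, so "identified in a replicate" stays
  decidable downstream.
* Quantification normalizes over **everything it is given**, including
  contaminants and decoys; removing those afterwards through
  `filter_decoys_contaminants()` is what makes their quantitative share
  observable in the ledger. `requantify()` then renormalizes the
  survivors.

## Quality filtering and diagnostics

`quality_filter()` keeps groups with protein score ≥ 40 and either ≥ 2
observed peptides or a score ≥ 100 (a high-confidence override for strong
single-peptide identifications). The score-40 default reflects where the
bulk of spurious identifications sits in typical Andromeda score
distributions of this data type; the exact thresholds are config, not
doctrine, and all three are arguments. With `require_duplicate = TRUE` a
group must have intensity > 0 in both technical replicates of its cell
("identified" means exactly that: summed intensity > 0).

**Quantitative loss** of a step is the share of that step's *input*
relative abundance held by the removed groups. Computed this way, losses
chain multiplicatively: 1 − Π(1 − loss~i~) over consecutive steps equals
the loss computed directly between the initial and final sets (asserted to
1e-9 in the tests).

`pairwise_pcc()` computes Pearson correlations between replicate, method
or extract pairs. By default it uses the **intersection** of groups
quantified (> 0) in both members — correlating what both runs actually
measured; a union-with-zeros mode is available since zero-filling is also
common practice and the choice is not canonical. Pairs with fewer than
three common groups or zero variance are reported as missing with a
reason, never silently dropped.

`merge_groups_across_methods()` merges groups sharing at least one member
protein under transitive closure (connected components of the
group–protein bipartite graph, via igraph), retaining per-method presence
for Venn-style counts. `flag_suspect_outliers()` marks the signature of a
promiscuous false positive — single peptide, single digestion method, and
an external match count ≥ 1000 for that peptide — but never removes
anything: exclusion is an explicit, separate action, mirroring the manual
curation such calls require. The match counts are inputs (e.g. from a
BLAST search), never computed here.

## Amino-acid composition

Three estimators share one output type (an `aa_composition` tibble whose
frequencies sum to 1):

* peptide-level: residue frequencies of each observed peptide weighted by
  its relative MS1 intensity within the observation set;
* protein-level: full-length residue frequencies weighted by
  I~L~^rel^;
* AAA conversion: mg/g concentrations → weight fractions → divided by the
  free amino-acid molecular weight and multiplied by the 128 g/mol mean
  residue weight (including water).

Whether to renormalize after the 128 g/mol conversion is not fixed by the
formula (the raw values sum to 128·Σ(w~i~/MW~i~), not 1); `aaa_to_molar()`
renormalizes by default and keeps the raw values in a `raw_molar` column
so both readings are available. Acid hydrolysis cannot distinguish
Asp/Asn and Glu/Gln, so AAA tables may carry pooled `Asx`/`Glx` keys;
these use the mean of the two constituent molecular weights, and
`compare_compositions()` pools sequence-derived compositions with
`pool_asx_glx()` before any comparison involving AAA data. Amino acids
absent from an AAA table (commonly Cys and Trp) are reported as missing,
not zero. The essential set for ΣEAA/ΣNEAA is His, Ile, Leu, Lys, Met,
Phe, Thr, Trp, Val (the FAO adult convention), overridable per call.

## Subcellular distributions

`bin_by_compartment()` sums I~L~^rel^ over the compartment label of each
group's representative protein. The ten-label DeepLoc vocabulary is a
controlled list; anything else maps to `"unknown"` with a warning, and
unknown is its own bin so the fractions always partition 1. Group-level
localization uses the representative (longest) protein's label — group
members can in principle disagree, and the representative is the sequence
the quantification already anchors to. The pooled "intracellular" fraction
is the sum of all non-extracellular known compartments; its replicate sd
is propagated as sqrt(Σ sd²) under independence.

`anova_tukey()` fits a one-way ANOVA (`stats::aov`) with Tukey HSD
(`stats::TukeyHSD`, i.e. the studentized-range distribution) and marks
pairs `*` (p < 0.05), `**` (p < 0.01) or `ns`. Letters come from the
standard insert-and-absorb compact-letter-display algorithm applied to
the TukeyHSD significance matrix — computed in-package so the letters are
always consistent with the reported adjusted p-values, with groups
ordered by mean for tie-breaking. Replicates are the observations; with
only technical duplicates the test is weak, which is a property of the
design, not the code. All-identical inputs make F undefined; that case
returns `ns` everywhere with an explanatory note rather than an error.
The choice of replicate means versus pooled replicates is left to the
caller — the function takes a plain label/value tibble, so either
aggregation can be passed in.

## Functional-peptide post-processing

Net charge at pH 7 is the Henderson–Hasselbalch sum over the termini and
the ionizable side chains. The default pKa set is N-term 9.0, C-term
3.55, Asp 3.65, Glu 4.25, Cys 8.3, His 6.0, Lys 10.5, Arg 12.5, Tyr 10.1
— all within published ranges for free peptides — and reproduces, after
rounding, the printed charges of every peptide in the shipped
*E. denticulatum* reference table (`read_functional_peptides()`), which
is the package's regression anchor for this calculation. Display rounding
is **half away from zero to one decimal**, matching how peptide property
calculators print (base R's round-half-to-even would flip boundary
cases).

Score thresholds are strict inequalities: emulsifier z-score > 2 (better
than 97.5% of random same-length peptides), SCA > 0.43, CHE > 0.3.
Length rules (α ≥ 15 residues preferred; β 9–16) are advisory flags only.

Overlap is defined **in parent-protein coordinates**: two records overlap
iff they share a parent and their 1-based inclusive intervals intersect;
identical sequences at different loci do not overlap. Clusters are the
connected components under transitive closure (computed by an interval
sweep, which is equivalent to pairwise closure and is cross-checked
against a brute-force union-find in the tests). Cluster representatives
are the highest score, then longer peptide, then smaller start.
`select_top_nonoverlapping()` is greedy in score order and stops at k per
class. The antioxidant predictors ship their own clustering whose linkage
rule is not documented; the interval-overlap closure here is a declared
stand-in, validated against the known worked structure in which the top
85 β-emulsifier records collapse to four clusters and the fifth
representative is the 86th-ranked record.

## The synthetic-data generator

`simulate_dataset()` emulates the statistical structure the estimators
assume, with every draw fixed by one seed:

* log-normal protein lengths (median 200 residues, sdlog 0.35) and molar
  abundances (sdlog 1.5 — a realistically skewed dynamic range);
* compartments drawn from a prior over the DeepLoc vocabulary; three
  extracts (`V`, `A`, `SC`) generated by multiplying non-extracellular
  abundances by 1, 0.25 and 1.5 respectively and renormalizing — an
  Alcalase-like profile suppressing intracellular protein versus
  cell-wall-degrading profiles enriching it;
* a realized digestion partition per protein and mode: tryptic sites are
  skipped with probability 0.2 (missed cleavages), semi-specific
  fragments are randomly split at one terminus, unspecific coverage uses
  random 5–65-residue fragments. Every realized digest is a complete,
  non-overlapping partition, so summed peptide signal per protein stays
  proportional to abundance x length;
* intensity = molar abundance x peptide length x 0.7 per Met/His/Trp/Cys
  residue (the detectability penalty), x log-normal noise at 20% CV per
  replicate, with 10% dropout — the generative convention under which the
  length-normalized and intensity-weighted estimators are exact in the
  noise-free limit, giving a clean recovery surface
  (`length_independent_intensity = TRUE` switches the length coupling off
  to study short-peptide bias);
* 5% contaminant signal share (`CON_` records), reversed decoys (`REV_`),
  and two spurious single-peptide single-method groups with scores drawn
  from (2, 20) plus an accompanying promiscuity table — the false-positive
  signature the outlier flagging looks for.

What it does **not** emulate: spectrum-level effects (charge states,
co-isolation, retention time), peptide-specific ionization beyond the
four-residue penalty, shared peptides between target proteins, FDR/decoy
competition, or modification chemistry. Tests passing on this generator
therefore validate the arithmetic and its invariants, not the behaviour
of any real LC-MS/MS pipeline.

## Numerical choices and test scale

Normalization invariants are asserted to 1e-9; oracle equivalences
(digest counts vs closed form, PCC vs the textbook formula, cluster
closure vs union-find, the loss chain rule) to 1e-9 on instances of ≤ 100
elements; noise-free recovery to 1e-9. The simulation studies in the test
suite and acceptance script use 50-protein proteomes over 20 seeds for
recovery and bias checks, 25 proteins for the noise-free limit, and
8-protein single-extract datasets (100 seeds in the tests) for the
normalization sweep — sizes at which every distributional property the
estimators rely on is already expressed while the whole suite stays
quick to run.

## Known limitations

* iBAQ denominators depend on the chosen window and missed-cleavage
  setting; published values vary between tools, so cross-study riBAQ
  comparisons should pin these arguments.
* Protein-level composition assumes intact full-length proteins; partial
  hydrolysis during extraction biases it in ways the package does not
  model.
* The AAA conversion inherits hydrolysis losses (Ser/Thr/Cys/Met/Trp)
  from the assay; no correction is applied.
* Compartment summaries trust the localization predictor; "unknown" is
  propagated, not imputed.
* With only technical duplicates, ANOVA significance is fragile; the
  compact letters should be read together with the propagated sds.
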