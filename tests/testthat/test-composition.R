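test_that("per-sequence residue frequencies are counts over length", {
  f <- peptide_aa_frequency("HP")
  expect_equal(f$frequency[f$aa == "H"], 0.5)
  expect_equal(f$frequency[f$aa == "P"], 0.5)
  expect_equal(sum(f$frequency), 1)
  f2 <- peptide_aa_frequency("AAAA")
  expect_equal(f2$frequency[f2$aa == "A"], 1)
  # frequency x length is always a whole count
  set.seed(2)
  for (i in 1:10) {
    s <- random_protein(sample(5:40, 1))
    f <- peptide_aa_frequency(s)
    expect_equal(f$frequency * nchar(s), round(f$frequency * nchar(s)))
    expect_equal(sum(f$frequency), 1)
  }
})

test_that("peptide-level composition weights by relative MS1 intensity", {
  one <- composition_from_peptides(obs_row("GK", "g", 123))
  expect_equal(one$frequency[one$aa == "G"], 0.5)
  expect_equal(one$frequency[one$aa == "K"], 0.5)
  two <- composition_from_peptides(dplyr::bind_rows(
    obs_row("AA", "g", 3), obs_row("CC", "g", 1)))
  expect_equal(two$frequency[two$aa == "A"], 0.75)
  expect_equal(two$frequency[two$aa == "C"], 0.25)
  expect_error(composition_from_peptides(obs_row("AA", "g", 0)), "zero")
})

test_that("splitting an observation preserves the composition", {
  base <- dplyr::bind_rows(obs_row("ACDK", "g", 10), obs_row("WYW", "g", 4))
  split <- dplyr::bind_rows(obs_row("ACDK", "g", 10),
                            obs_row("WYW", "g", 1.5),
                            obs_row("WYW", "g", 2.5))
  expect_equal(composition_from_peptides(base)$frequency,
               composition_from_peptides(split)$frequency)
})

test_that("protein-level composition weights full sequences by il_rel", {
  db <- tibble::tibble(protein_id = c("h", "a", "c"),
                       sequence = c("HPHP", "AAAA", "CCCC"))
  one <- composition_from_proteins(
    tibble::tibble(group_id = "h", il_rel = 1), db)
  expect_equal(one$frequency[one$aa == "H"], 0.5)
  mix <- composition_from_proteins(
    tibble::tibble(group_id = c("a", "c"), il_rel = c(0.25, 0.75)), db)
  expect_equal(mix$frequency[mix$aa == "A"], 0.25)
  expect_equal(mix$frequency[mix$aa == "C"], 0.75)
  # duplicating a protein with the weight split in half changes nothing
  db2 <- dplyr::bind_rows(db, tibble::tibble(protein_id = "a2",
                                             sequence = "AAAA"))
  mix2 <- composition_from_proteins(
    tibble::tibble(group_id = c("a", "a2", "c"),
                   il_rel = c(0.125, 0.125, 0.75)), db2)
  expect_equal(mix2$frequency, mix$frequency)
  expect_error(composition_from_proteins(
    tibble::tibble(group_id = "nope", il_rel = 1), db), "missing")
})

test_that("AAA mg/g converts to relative molar fractions via 128 g/mol", {
  single <- aaa_to_molar(c(G = 10))
  expect_equal(single$frequency, 1)
  # equimolar Gly and Trp by construction: 1 mmol each
  mw <- aa_molecular_weights()
  both <- aaa_to_molar(c(G = unname(mw["G"]), W = unname(mw["W"])))
  expect_equal(both$frequency, c(0.5, 0.5))
  # raw values sum to 128 * sum(w_i / MW_i), not 1
  aaa <- c(G = 30, A = 20, L = 50)
  raw <- aaa_to_molar(aaa, renormalize = FALSE)
  w <- aaa / sum(aaa)
  expect_equal(sum(raw$frequency),
               mean_aa_weight() * sum(w / mw[names(aaa)]))
  expect_error(aaa_to_molar(c(Zz = 1)), "molecular weight|unknown")
})

test_that("EAA/NEAA ratio behaves at its boundaries", {
  all_ne <- tibble::tibble(aa = c("G", "A", "E"),
                           frequency = c(0.3, 0.3, 0.4))
  expect_equal(eaa_neaa_ratio(all_ne), 0)
  even <- tibble::tibble(aa = c("L", "G"), frequency = c(0.5, 0.5))
  expect_equal(eaa_neaa_ratio(even), 1)
  only_e <- tibble::tibble(aa = c("L", "K"), frequency = c(0.5, 0.5))
  expect_error(eaa_neaa_ratio(only_e), "undefined")
})

test_that("comparison pools Asx/Glx and reports per-AA differences", {
  seq_comp <- composition_from_peptides(obs_row("DNDNENQE", "g", 1))
  self <- compare_compositions(list(a = seq_comp, b = seq_comp))
  expect_true(all(self$diff_vs_reference == 0))
  # {D,N} pooled against an AAA Asx entry: difference 0
  dn <- composition_from_peptides(dplyr::bind_rows(
    obs_row("D", "g", 1), obs_row("NN", "g", 2)))
  aaa_like <- aaa_to_molar(c(Asx = 10))
  cmp <- compare_compositions(list(aaa = aaa_like, seq = dn))
  asx <- dplyr::filter(cmp, aa == "Asx")
  expect_equal(asx$diff_vs_reference[asx$source == "seq"], 0)
  # three sources -> 3 x alphabet rows
  three <- compare_compositions(list(a = seq_comp, b = seq_comp,
                                     c = seq_comp))
  expect_equal(nrow(three), 3 * dplyr::n_distinct(three$aa))
})

test_that("pooling keeps the total and merges only D/N and E/Q", {
  comp <- composition_from_peptides(obs_row("DDNNEEQQAG", "g", 5))
  pooled <- pool_asx_glx(comp)
  expect_equal(sum(pooled$frequency), 1)
  expect_equal(pooled$frequency[pooled$aa == "Asx"], 0.4)
  expect_equal(pooled$frequency[pooled$aa == "Glx"], 0.4)
  expect_false(any(c("D", "N", "E", "Q") %in% pooled$aa))
})
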