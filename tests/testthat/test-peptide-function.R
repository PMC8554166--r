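test_that("net charge follows Henderson-Hasselbalch summation", {
  pka <- default_pka_set()
  # glycine-only peptide is neutral at the midpoint of the terminal pKas
  mid <- (pka[["Nterm"]] + pka[["Cterm"]]) / 2
  expect_equal(net_charge("GGGG", pH = mid), 0, tolerance = 1e-12)
  # charge decreases monotonically with pH for any sequence
  set.seed(43)
  for (i in 1:8) {
    s <- random_protein(sample(4:20, 1))
    phs <- seq(2, 12, length.out = 15)
    zz <- vapply(phs, function(p) net_charge(s, pH = p), numeric(1))
    expect_true(all(diff(zz) <= 1e-12))
  }
})

test_that("published peptide charges reproduce with the default pKa set", {
  tbl <- read_functional_peptides()
  z <- net_charge(tbl$peptide_sequence)
  rounded <- sign(z) * floor(abs(z) * 10 + 0.5) / 10
  expect_equal(rounded, tbl$charge_ph7)
})

test_that("annotation fills length and rounded charge", {
  rec <- tibble::tibble(peptide_sequence = c("HP", "VRIRVDCK"))
  ann <- annotate_predictions(rec)
  expect_equal(ann$length, c(2L, 8L))
  expect_equal(ann$charge_ph7, c(0.1, 1.9))
  empty <- annotate_predictions(rec[0, ])
  expect_equal(nrow(empty), 0)
  expect_true(all(c("length", "charge_ph7") %in% names(empty)))
})

test_that("coordinates are validated against the parent sequence", {
  db <- tibble::tibble(protein_id = "P", sequence = "MKTAYIAKQR")
  good <- tibble::tibble(peptide_sequence = "TAYI", protein_id = "P",
                         start = 3, end = 6, class = "SCA", score = 0.5)
  expect_silent(ann <- annotate_predictions(good, db = db))
  bad <- dplyr::mutate(good, start = 4)
  expect_error(annotate_predictions(bad, db = db), "inconsistent")
})

test_that("score thresholds are strict inequalities per class", {
  rec <- tibble::tibble(
    peptide_sequence = c("AAAAA", "CCCCC", "DDDDD", "EEEEE", "FFFFF"),
    class = c("SCA", "SCA", "alpha", "alpha", "CHE"),
    score = c(0.49, 0.43, 2.0, 2.01, 0.31))
  res <- apply_score_thresholds(rec)
  expect_setequal(res$kept$peptide_sequence,
                  c("AAAAA", "EEEEE", "FFFFF"))
  counts <- res$counts
  expect_equal(counts$n_kept[counts$class == "SCA"], 1L)
  expect_equal(counts$n_kept[counts$class == "alpha"], 1L)
  expect_error(apply_score_thresholds(
    tibble::tibble(class = "mystery", score = 1)), "threshold")
})

test_that("length rules flag but never remove", {
  rec <- tibble::tibble(
    peptide_sequence = c("A", "B", "C", "D"),
    class = c("alpha", "beta", "beta", "gamma"),
    length = c(8L, 12L, 20L, 3L))
  out <- apply_length_rules(rec)
  expect_equal(nrow(out), 4)
  expect_equal(out$length_flag, c(TRUE, FALSE, TRUE, FALSE))
})

test_that("overlap clustering is transitive within a parent protein", {
  mk <- function(start, end, protein = "P", class = "beta", score = 1) {
    tibble::tibble(peptide_sequence = strrep("A", end - start + 1),
                   protein_id = protein, start = start, end = end,
                   class = class, score = score)
  }
  # different parents never cluster
  two <- dplyr::bind_rows(mk(1, 10, "P1"), mk(1, 10, "P2"))
  expect_equal(dplyr::n_distinct(cluster_by_overlap(two)$cluster_id), 2)
  # a single shared residue links
  touch <- dplyr::bind_rows(mk(1, 10), mk(10, 20))
  expect_equal(dplyr::n_distinct(cluster_by_overlap(touch)$cluster_id), 1)
  # chains close transitively even when the ends do not overlap
  chain <- dplyr::bind_rows(mk(1, 10, score = 3), mk(8, 15, score = 2),
                            mk(14, 22, score = 1))
  cl <- cluster_by_overlap(chain)
  expect_equal(dplyr::n_distinct(cl$cluster_id), 1)
  expect_true(cl$is_representative[cl$score == 3])
})

test_that("clustering agrees with a brute-force pairwise closure", {
  set.seed(47)
  for (rep in 1:5) {
    n <- 40
    start <- sample(1:150, n, replace = TRUE)
    len <- sample(4:20, n, replace = TRUE)
    rec <- tibble::tibble(
      peptide_sequence = strrep("A", len),
      protein_id = sample(c("P1", "P2"), n, replace = TRUE),
      start = start, end = start + len - 1,
      class = "SCA", score = runif(n))
    got <- cluster_by_overlap(rec)
    # brute force: union-find over all overlapping pairs
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (rec$protein_id[i] == rec$protein_id[j] &&
          rec$start[i] <= rec$end[j] && rec$end[i] >= rec$start[j]) {
        parent[find(i)] <- find(j)
      }
    }
    comp_oracle <- vapply(seq_len(n), find, integer(1))
    # identical partitions: pairing cluster ids with oracle components
    # creates no new classes in either direction
    key <- paste(got$protein_id, got$start, got$end)
    ord <- match(paste(rec$protein_id, rec$start, rec$end), key)
    joint <- dplyr::n_distinct(paste(got$cluster_id[ord], comp_oracle))
    expect_equal(joint, dplyr::n_distinct(got$cluster_id))
    expect_equal(joint, dplyr::n_distinct(comp_oracle))
  }
})

test_that("top non-overlapping selection is greedy by score", {
  mk <- function(start, end, score, protein = "P") {
    tibble::tibble(peptide_sequence = strrep("A", end - start + 1),
                   protein_id = protein, start = start, end = end,
                   class = "beta", score = score)
  }
  disjoint <- purrr::map_dfr(1:5, function(i) {
    mk(i * 20, i * 20 + 5, score = 6 - i)
  })
  sel <- select_top_nonoverlapping(disjoint, k = 5)
  expect_equal(nrow(sel), 5)
  expect_equal(sel$score, sort(sel$score, decreasing = TRUE))
  # k above the number of clusters returns one representative per cluster
  clustered <- dplyr::bind_rows(mk(1, 10, 5), mk(5, 12, 4), mk(50, 60, 3))
  sel2 <- select_top_nonoverlapping(clustered, k = 10)
  expect_equal(nrow(sel2), 2)
  expect_setequal(sel2$score, c(5, 3))
  # identical sequences at different loci do not overlap
  far <- dplyr::bind_rows(mk(1, 5, 2), mk(100, 104, 1))
  expect_equal(nrow(select_top_nonoverlapping(far, k = 5)), 2)
})

test_that("verified peptides cross-reference by exact substring", {
  db <- tibble::tibble(protein_id = c("c6313_g1_i1", "other"),
                       sequence = c("AAARYVWNCCC", "DDDDDD"))
  verified <- tibble::tibble(peptide_sequence = c("RYVWN", "RYVWN",
                                                  "MISSING"))
  hits <- crossref_verified(verified, db)
  expect_equal(nrow(hits), 1)  # deduplicated, absent peptide unmatched
  expect_equal(hits$protein_id, "c6313_g1_i1")
  expect_equal(hits$start, 4)
  expect_equal(hits$end, 8)
  # abundance attachment
  q <- toy_quant("c6313_g1_i1", 1.0)
  hits_q <- crossref_verified(verified, db, quant = q)
  expect_equal(hits_q$il_rel_V, 1)
})
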