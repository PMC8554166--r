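test_that("decoy/contaminant filtering records quantitative loss", {
  q <- toy_quant(c("g1", "g2", "g3"), c(0.5, 0.3, 0.2))
  q$is_decoy <- c(FALSE, FALSE, FALSE)
  q$is_contaminant <- c(FALSE, FALSE, TRUE)
  # no flags -> loss 0
  clean <- dplyr::mutate(q, is_contaminant = FALSE)
  expect_equal(filter_decoys_contaminants(clean)$ledger$quantitative_loss, 0)
  # a contaminant holding 20% of pre-filter weight
  res <- filter_decoys_contaminants(q)
  expect_equal(res$ledger$quantitative_loss, 0.2)
  expect_setequal(res$quant$group_id, c("g1", "g2"))
  # idempotent
  res2 <- filter_decoys_contaminants(res$quant)
  expect_equal(res2$ledger$quantitative_loss, 0)
  expect_equal(nrow(res2$quant), 2)
})

test_that("a contaminant holding 30% of il_rel yields loss 0.30", {
  q <- toy_quant(c("a", "b"), c(0.7, 0.3))
  q$is_decoy <- FALSE
  q$is_contaminant <- c(FALSE, TRUE)
  expect_equal(filter_decoys_contaminants(q)$ledger$quantitative_loss, 0.3)
})

test_that("score and peptide-count filtering keeps what passes", {
  q <- toy_quant(c("g1", "g2", "g3"), c(0.2, 0.5, 0.3))
  q$n_peptides_observed <- c(1L, 3L, 5L)
  scores <- tibble::tibble(group_id = c("g1", "g2", "g3"),
                           score = c(6.5, 45, 323))
  kept <- quality_filter(q, scores = scores, min_score = 40)$quant
  expect_setequal(kept$group_id, c("g2", "g3"))
  # identity configuration changes nothing
  id <- quality_filter(q, scores = scores, min_score = 0, min_peptides = 1)
  expect_equal(nrow(id$quant), 3)
  expect_equal(id$ledger$quantitative_loss, 0)
  # single-peptide group rescued by the high-confidence override
  q1 <- dplyr::mutate(q, n_peptides_observed = c(1L, 1L, 1L))
  kept1 <- quality_filter(q1, scores = scores, min_score = 40,
                          min_peptides = 2, score_override = 100)$quant
  expect_setequal(kept1$group_id, "g3")
})

test_that("require_duplicate keeps only groups identified in both replicates", {
  q <- dplyr::bind_rows(
    toy_quant(c("g1", "g2"), c(0.6, 0.4), rep = "R1"),
    toy_quant("g1", 1.0, rep = "R2"))
  q$n_peptides_observed <- 3L
  q$score <- 100
  res <- quality_filter(q, require_duplicate = TRUE)
  expect_setequal(res$quant$group_id, "g1")
  steps <- res$ledger$step
  expect_true("require_duplicate" %in% steps)
  # fewer than 2 replicates is an error
  q1 <- dplyr::filter(q, replicate_id == "R1")
  expect_error(quality_filter(q1, require_duplicate = TRUE), "replicate")
})

test_that("quantitative loss is the pre-filter weight of removed groups", {
  before <- toy_quant(c("a", "b", "c", "d"), c(0.6, 0.1, 0.05, 0.25))
  expect_equal(quantitative_loss(before, before)$quantitative_loss, 0)
  after <- before[before$group_id %in% c("a", "b"), ]
  expect_equal(quantitative_loss(before, after)$quantitative_loss, 0.30)
  none <- before[0, ]
  expect_equal(quantitative_loss(before, none)$quantitative_loss, 1)
  extra <- toy_quant("zzz", 1)
  expect_error(quantitative_loss(before, extra), "absent")
})

test_that("requantify renormalizes, is idempotent and preserves ranks", {
  q <- toy_quant(c("a", "b"), c(0.3, 0.3))
  r <- requantify(q)
  expect_equal(r$il_rel, c(0.5, 0.5))
  expect_equal(requantify(r)$il_rel, r$il_rel)
  single <- requantify(toy_quant("only", 0.12))
  expect_equal(single$il_rel, 1)
  set.seed(5)
  q2 <- toy_quant(letters[1:6], runif(6))
  expect_equal(order(requantify(q2)$il_rel), order(q2$il_rel))
  expect_error(requantify(q2[0, ]), "empty")
})

test_that("duplicate consensus averages and renormalizes common groups", {
  qa <- toy_quant(c("g1", "g2"), c(0.6, 0.4), rep = "R1")
  qb <- toy_quant(c("g1", "g2"), c(0.8, 0.2), rep = "R2")
  cons <- duplicate_consensus(dplyr::bind_rows(qa, qb))
  expect_equal(cons$il_rel[match(c("g1", "g2"), cons$group_id)],
               c(0.7, 0.3))
  # identical replicates -> unchanged
  cons2 <- duplicate_consensus(dplyr::bind_rows(
    qa, dplyr::mutate(qa, replicate_id = "R2")))
  expect_equal(cons2$il_rel[match(c("g1", "g2"), cons2$group_id)],
               c(0.6, 0.4))
  # group present in one replicate only is absent from the consensus
  qb3 <- toy_quant("g1", 1.0, rep = "R2")
  cons3 <- duplicate_consensus(dplyr::bind_rows(qa, qb3))
  expect_setequal(cons3$group_id, "g1")
})

test_that("pairwise PCC matches the textbook formula", {
  q <- dplyr::bind_rows(
    toy_quant(c("a", "b", "c"), c(1, 2, 3) / 6, rep = "R1"),
    toy_quant(c("a", "b", "c"), c(2, 4, 7) / 13, rep = "R2"))
  rep_pcc <- pairwise_pcc(q)
  x <- c(1, 2, 3) / 6; y <- c(2, 4, 7) / 13
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(rep_pcc$pcc, r_oracle, tolerance = 1e-12)
  expect_equal(rep_pcc$n_common, 3L)

  # perfect and anti-correlation
  qp <- dplyr::bind_rows(
    toy_quant(c("a", "b", "c"), c(0.2, 0.3, 0.5), rep = "R1"),
    toy_quant(c("a", "b", "c"), c(0.2, 0.3, 0.5), rep = "R2"))
  expect_equal(pairwise_pcc(qp)$pcc, 1)
  qn <- dplyr::bind_rows(
    toy_quant(c("a", "b", "c"), c(0.2, 0.3, 0.5), rep = "R1"),
    toy_quant(c("a", "b", "c"), 1 - c(0.2, 0.3, 0.5), rep = "R2"))
  expect_equal(pairwise_pcc(qn)$pcc, -1)
})

test_that("pairwise PCC agrees with brute-force covariance on random data", {
  set.seed(17)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    x <- runif(n); y <- runif(n)
    q <- dplyr::bind_rows(
      toy_quant(sprintf("g%02d", 1:n), x / sum(x), rep = "R1"),
      toy_quant(sprintf("g%02d", 1:n), y / sum(y), rep = "R2"))
    got <- pairwise_pcc(q)$pcc
    xv <- x / sum(x); yv <- y / sum(y)
    cov_xy <- mean(xv * yv) - mean(xv) * mean(yv)
    oracle <- cov_xy / sqrt((mean(xv^2) - mean(xv)^2) *
                            (mean(yv^2) - mean(yv)^2))
    expect_equal(got, oracle, tolerance = 1e-12)
  }
})

test_that("degenerate PCC inputs are reported as missing with a reason", {
  q <- dplyr::bind_rows(
    toy_quant(c("a", "b"), c(0.5, 0.5), rep = "R1"),
    toy_quant(c("a", "b"), c(0.6, 0.4), rep = "R2"))
  res <- pairwise_pcc(q)
  expect_true(is.na(res$pcc))
  expect_match(res$reason, "fewer than 3")
  qz <- dplyr::bind_rows(
    toy_quant(c("a", "b", "c"), c(1, 1, 1) / 3, rep = "R1"),
    toy_quant(c("a", "b", "c"), c(0.5, 0.3, 0.2), rep = "R2"))
  resz <- pairwise_pcc(qz)
  expect_true(is.na(resz$pcc))
  expect_match(resz$reason, "variance")
})

test_that("groups sharing members merge under transitive closure", {
  disjoint <- tibble::tibble(group_id = c("g1", "g2"),
                             protein_id = c("pA", "pB"),
                             method = c("tryptic", "semi"))
  m <- merge_groups_across_methods(disjoint)
  expect_equal(nrow(m$merged), 2)

  shared <- tibble::tibble(group_id = c("g1", "g1", "g2"),
                           protein_id = c("pA", "pB", "pB"),
                           method = c("tryptic", "tryptic", "semi"))
  m2 <- merge_groups_across_methods(shared)
  expect_equal(nrow(m2$merged), 1)
  expect_equal(m2$merged$n_methods, 2L)

  # chain g1-g2-g3 collapses to one merged group; brute-force closure agrees
  chain <- tibble::tibble(
    group_id = c("g1", "g1", "g2", "g2", "g3", "g3"),
    protein_id = c("p1", "p2", "p2", "p3", "p3", "p4"),
    method = c("tryptic", "tryptic", "semi", "semi", "unspecific",
               "unspecific"))
  m3 <- merge_groups_across_methods(chain)
  expect_equal(nrow(m3$merged), 1)
  # brute-force: iterate pairwise merges to a fixed point
  sets <- split(chain$protein_id, chain$group_id)
  repeat {
    merged_any <- FALSE
    for (i in seq_along(sets)) for (j in seq_along(sets)) {
      if (i < j && length(intersect(sets[[i]], sets[[j]])) > 0) {
        sets[[i]] <- union(sets[[i]], sets[[j]]); sets[[j]] <- NULL
        merged_any <- TRUE; break
      }
    }
    if (!merged_any) break
  }
  expect_equal(length(sets), nrow(m3$merged))
})

test_that("suspect outliers need one peptide, one method and promiscuity", {
  obs <- dplyr::bind_rows(
    obs_row("SLFSLLR", "sus", 5, method = "semi"),
    obs_row("AAAAK", "ok2", 5, method = "semi"),
    obs_row("CCCCK", "ok2", 5, method = "semi"),
    obs_row("DDDDK", "ok3", 5, method = "tryptic"),
    obs_row("DDDDK", "ok3", 5, method = "semi"),
    obs_row("DDDDK", "ok3", 5, method = "unspecific"))
  prom <- tibble::tibble(peptide_sequence = c("SLFSLLR", "DDDDK"),
                         n_matches = c(5000, 5000))
  fl <- flag_suspect_outliers(obs, prom)
  expect_true(fl$flagged[fl$group_id == "sus"])
  expect_false(fl$flagged[fl$group_id == "ok2"])   # two peptides
  expect_false(fl$flagged[fl$group_id == "ok3"])   # three methods
})

test_that("ledger losses chain multiplicatively to the direct loss", {
  set.seed(23)
  for (i in 1:5) {
    n <- 30
    q <- toy_quant(sprintf("g%02d", 1:n), {w <- runif(n); w / sum(w)})
    q$is_decoy <- runif(n) < 0.1
    q$is_contaminant <- runif(n) < 0.1
    q$n_peptides_observed <- sample(1:5, n, replace = TRUE)
    q$score <- exp(rnorm(n, log(60), 1))
    s1 <- filter_decoys_contaminants(q)
    s2 <- quality_filter(s1$quant, min_score = 40)
    losses <- c(s1$ledger$quantitative_loss, s2$ledger$quantitative_loss)
    direct <- quantitative_loss(q, s2$quant)$quantitative_loss
    expect_equal(1 - prod(1 - losses), direct, tolerance = 1e-9)
  }
})

test_that("raising the score threshold never decreases quantitative loss", {
  set.seed(29)
  n <- 40
  q <- toy_quant(sprintf("g%02d", 1:n), {w <- runif(n); w / sum(w)})
  q$n_peptides_observed <- 5L
  q$score <- exp(rnorm(n, log(60), 1))
  losses <- vapply(c(0, 20, 40, 80, 160, 320), function(th) {
    quality_filter(q, min_score = th)$ledger$quantitative_loss
  }, numeric(1))
  expect_true(all(diff(losses) >= -1e-12))
})
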