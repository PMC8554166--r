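# Quality-based filtering, quantitative-loss accounting, duplicate-consensus
# quantification, outlier flagging and correlation diagnostics.

# Per-unit ledger row set for one filtering step. Loss is the share of the
# step's *input* weight held by removed groups, so that losses chain
# multiplicatively: 1 - prod(1 - loss_i) equals the overall loss.
build_ledger <- function(step, before, after, weight = "il_rel") {
  units <- dplyr::distinct(before[, quant_unit_cols()])
  purrr::pmap_dfr(units, function(sample_id, replicate_id, method) {
    b <- dplyr::filter(before, .data$sample_id == !!sample_id,
                       .data$replicate_id == !!replicate_id,
                       .data$method == !!method)
    a <- dplyr::filter(after, .data$sample_id == !!sample_id,
                       .data$replicate_id == !!replicate_id,
                       .data$method == !!method)
    removed <- setdiff(b$group_id, a$group_id)
    tot <- sum(b[[weight]])
    loss <- if (tot > 0) sum(b[[weight]][b$group_id %in% removed]) / tot else 0
    tibble::tibble(
      step = step, sample_id = sample_id, replicate_id = replicate_id,
      method = method, groups_before = nrow(b), groups_after = nrow(a),
      quantitative_loss = loss, removed_ids = list(removed)
    )
  })
}

#' Remove decoy and contaminant protein groups
#'
#' Drops all groups flagged as reversed decoys or common contaminants and
#' records, per quantification unit, the quantitative loss: the share of
#' pre-filter relative abundance held by the removed groups.
#'
#' @param quant A quantification tibble from [quantify_groups()] carrying
#'   `is_decoy` and `is_contaminant`.
#' @param weight Abundance column used for loss accounting.
#' @return A list with elements `quant` (filtered tibble) and `ledger`
#'   (a [FilterLedger][build_ledger] tibble: step, unit, groups before/after,
#'   `quantitative_loss`, removed IDs).
#' @export
filter_decoys_contaminants <- function(quant, weight = "il_rel") {
  assert_columns(quant, c("group_id", "is_decoy", "is_contaminant", weight,
                          quant_unit_cols()), "quant")
  kept <- dplyr::filter(quant, !.data$is_decoy, !.data$is_contaminant)
  list(quant = kept,
       ledger = build_ledger("decoys_contaminants", quant, kept, weight))
}

#' Quality-based filtering of protein groups
#'
#' Keeps groups whose search-engine protein score passes `min_score` and
#' which are supported either by at least `min_peptides` observed peptides
#' or by a high-confidence score (`score_override`). With
#' `require_duplicate`, a group must additionally be identified (summed
#' intensity > 0) in both technical replicates of its sample x method cell.
#'
#' @param quant Quantification tibble; must carry a `score` column, or
#'   supply `scores`.
#' @param scores Optional tibble (`group_id`, `score`) joined onto `quant`.
#' @param min_score Minimum protein score (default 40, below which the bulk
#'   of spurious identifications fall).
#' @param min_peptides Minimum observed peptide count (default 2).
#' @param score_override Score at which a single-peptide identification is
#'   still accepted (default 100).
#' @param require_duplicate Require identification in both technical
#'   replicates.
#' @param weight Abundance column used for loss accounting.
#' @return A list with `quant` and `ledger` (one ledger row per step x unit).
#' @export
quality_filter <- function(quant, scores = NULL, min_score = 40,
                           min_peptides = 2, score_override = 100,
                           require_duplicate = FALSE, weight = "il_rel") {
  if (!is.null(scores)) {
    assert_columns(scores, c("group_id", "score"), "scores")
    quant <- dplyr::left_join(quant,
                              dplyr::distinct(scores[, c("group_id", "score")]),
                              by = "group_id")
  }
  assert_columns(quant, c("group_id", "score", "n_peptides_observed", weight,
                          quant_unit_cols()), "quant")

  kept <- dplyr::filter(
    quant,
    .data$score >= min_score,
    .data$n_peptides_observed >= min_peptides |
      .data$score >= score_override
  )
  ledger <- build_ledger("score_peptides", quant, kept, weight)

  if (require_duplicate) {
    reps <- kept |>
      dplyr::distinct(.data$sample_id, .data$method, .data$replicate_id) |>
      dplyr::count(.data$sample_id, .data$method)
    if (any(reps$n < 2)) {
      rlang::abort("require_duplicate needs two technical replicates per sample")
    }
    dup <- kept |>
      dplyr::filter(.data$summed_intensity > 0) |>
      dplyr::distinct(.data$sample_id, .data$method, .data$replicate_id,
                      .data$group_id) |>
      dplyr::count(.data$sample_id, .data$method, .data$group_id) |>
      dplyr::filter(.data$n >= 2)
    kept2 <- dplyr::semi_join(kept, dup,
                              by = c("sample_id", "method", "group_id"))
    ledger <- dplyr::bind_rows(
      ledger, build_ledger("require_duplicate", kept, kept2, weight))
    kept <- kept2
  }
  list(quant = kept, ledger = ledger)
}

#' Quantitative loss between two quantification states
#'
#' The relative abundance constituted by filtered groups prior to the
#' filtering step: per quantification unit,
#' `1 - sum(kept pre-filter weights) / sum(all pre-filter weights)`.
#'
#' @param before,after Quantification tibbles; `after` must contain a subset
#'   of `before`'s groups within every unit.
#' @param weight Abundance column evaluated on the `before` normalization.
#' @return A tibble with one row per unit and column `quantitative_loss`.
#' @export
quantitative_loss <- function(before, after, weight = "il_rel") {
  assert_columns(before, c("group_id", weight, quant_unit_cols()), "before")
  assert_columns(after, c("group_id", quant_unit_cols()), "after")
  extra <- dplyr::anti_join(after, before,
                            by = c("group_id", quant_unit_cols()))
  if (nrow(extra) > 0) {
    rlang::abort("`after` contains groups absent from `before`")
  }
  build_ledger("loss", before, after, weight)[
    , c(quant_unit_cols(), "groups_before", "groups_after",
        "quantitative_loss")]
}

#' Renormalize relative abundances after filtering
#'
#' Rescales `ribaq` and/or `il_rel` to sum to one within every
#' quantification unit over the surviving groups. Idempotent; preserves
#' within-unit rank order.
#'
#' @param quant Quantification tibble.
#' @return The tibble with renormalized abundance columns.
#' @export
requantify <- function(quant) {
  assert_columns(quant, c("group_id", quant_unit_cols()), "quant")
  if (nrow(quant) == 0) rlang::abort("cannot requantify an empty set")
  cols <- intersect(c("ribaq", "il_rel"), names(quant))
  if (length(cols) == 0) {
    rlang::abort("quant carries neither 'ribaq' nor 'il_rel'")
  }
  quant |>
    dplyr::group_by(dplyr::across(dplyr::all_of(quant_unit_cols()))) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(cols), function(w) {
      tot <- sum(w)
      if (tot <= 0) rlang::abort("cannot requantify: zero total abundance")
      w / tot
    })) |>
    dplyr::ungroup()
}

#' Duplicate-consensus quantification
#'
#' Averages the two technical replicates of every sample x method cell:
#' groups identified (summed intensity > 0) in both replicates are kept,
#' their relative abundances averaged and renormalized to one.
#'
#' @param quant Quantification tibble with exactly two replicates per
#'   sample x method.
#' @param replicate_label Replicate ID given to the consensus rows.
#' @return A consensus quantification tibble (one `replicate_id` level).
#' @export
duplicate_consensus <- function(quant, replicate_label = "avg") {
  assert_columns(quant, c("group_id", "summed_intensity",
                          quant_unit_cols()), "quant")
  cols <- intersect(c("ribaq", "il_rel"), names(quant))
  reps <- quant |>
    dplyr::distinct(.data$sample_id, .data$method, .data$replicate_id) |>
    dplyr::count(.data$sample_id, .data$method)
  if (any(reps$n != 2)) {
    rlang::abort("duplicate_consensus needs exactly two replicates per cell")
  }
  cons <- quant |>
    dplyr::filter(.data$summed_intensity > 0) |>
    dplyr::group_by(.data$sample_id, .data$method, .data$group_id) |>
    dplyr::filter(dplyr::n_distinct(.data$replicate_id) == 2) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(cols), mean),
      summed_intensity = mean(.data$summed_intensity),
      .groups = "drop"
    )
  if (nrow(cons) == 0) {
    rlang::abort("no groups identified in both replicates")
  }
  cons$replicate_id <- replicate_label
  requantify(cons)
}

# Pearson r between two aligned abundance vectors; NA with a reason when
# undefined.
pcc_pair <- function(x, y) {
  if (length(x) < 3) {
    return(list(pcc = NA_real_, n_common = length(x),
                reason = "fewer than 3 common groups"))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(pcc = NA_real_, n_common = length(x),
                reason = "zero variance"))
  }
  list(pcc = stats::cor(x, y), n_common = length(x), reason = NA_character_)
}

#' Pairwise Pearson correlation of relative abundances
#'
#' Computes the Pearson correlation coefficient (PCC) between every pair of
#' levels of one axis (technical replicates, digestion methods, or
#' extracts), holding the remaining unit variables fixed -- the standard
#' reproducibility diagnostic for label-free quantification.
#'
#' @param quant Quantification tibble.
#' @param value Abundance column to correlate.
#' @param by Unit column whose levels are paired (`"replicate_id"`,
#'   `"method"` or `"sample_id"`).
#' @param mode `"intersect"` correlates groups quantified (> 0) in both
#'   members of a pair; `"union"` aligns the union with zeros filled in.
#' @return A tibble with one row per pair and fixed-unit combination:
#'   `axis`, the fixed unit columns, `a`, `b`, `pcc`, `n_common`, `reason`
#'   (non-missing when the PCC is undefined).
#' @export
pairwise_pcc <- function(quant, value = "il_rel", by = "replicate_id",
                         mode = c("intersect", "union")) {
  mode <- match.arg(mode)
  stopifnot(by %in% quant_unit_cols())
  assert_columns(quant, c("group_id", value, quant_unit_cols()), "quant")
  fixed <- setdiff(quant_unit_cols(), by)
  combos <- dplyr::distinct(quant[, fixed])
  purrr::pmap_dfr(combos, function(...) {
    ctx <- tibble::tibble(...)
    sub <- dplyr::semi_join(quant, ctx, by = fixed)
    levels <- sort(unique(sub[[by]]))
    if (length(levels) < 2) return(tibble::tibble())
    pairs <- utils::combn(levels, 2, simplify = FALSE)
    purrr::map_dfr(pairs, function(p) {
      xa <- sub[sub[[by]] == p[1], c("group_id", value)]
      xb <- sub[sub[[by]] == p[2], c("group_id", value)]
      names(xa)[2] <- "va"; names(xb)[2] <- "vb"
      if (mode == "intersect") {
        m <- dplyr::inner_join(xa, xb, by = "group_id")
        m <- dplyr::filter(m, .data$va > 0, .data$vb > 0)
      } else {
        m <- dplyr::full_join(xa, xb, by = "group_id")
        m$va[is.na(m$va)] <- 0
        m$vb[is.na(m$vb)] <- 0
      }
      r <- pcc_pair(m$va, m$vb)
      dplyr::bind_cols(
        tibble::tibble(axis = by), ctx,
        tibble::tibble(a = p[1], b = p[2], pcc = r$pcc,
                       n_common = r$n_common, reason = r$reason))
    })
  })
}

#' Merge overlapping protein groups across digestion methods
#'
#' Protein groups reported separately by the tryptic, semi-specific and
#' unspecific searches are merged whenever they share at least one member
#' protein, under transitive closure (connected components of the
#' group--protein bipartite graph). Per-method presence is retained for
#' Venn-style counting.
#'
#' @param membership A tibble with columns `group_id`, `protein_id`,
#'   `method`.
#' @return A list with `mapping` (tibble `group_id`, `method`, `merged_id`)
#'   and `merged` (tibble `merged_id`, `n_groups`, `methods` list-column,
#'   `n_methods`).
#' @export
merge_groups_across_methods <- function(membership) {
  assert_columns(membership, c("group_id", "protein_id", "method"),
                 "membership")
  gnode <- paste0("g:", membership$group_id)
  pnode <- paste0("p:", membership$protein_id)
  g <- igraph::graph_from_edgelist(cbind(gnode, pnode), directed = FALSE)
  comp <- igraph::components(g)$membership
  grp_nodes <- grepl("^g:", names(comp))
  mapping <- tibble::tibble(
    group_id = sub("^g:", "", names(comp)[grp_nodes]),
    merged_id = paste0("M", match(comp[grp_nodes],
                                  sort(unique(comp[grp_nodes]))))
  )
  mapping <- dplyr::left_join(
    dplyr::distinct(membership[, c("group_id", "method")]),
    mapping, by = "group_id")
  merged <- mapping |>
    dplyr::group_by(.data$merged_id) |>
    dplyr::summarise(
      n_groups = dplyr::n_distinct(.data$group_id),
      methods = list(sort(unique(.data$method))),
      n_methods = dplyr::n_distinct(.data$method),
      .groups = "drop"
    )
  list(mapping = mapping, merged = merged)
}

#' Flag suspect single-peptide outlier groups
#'
#' Flags protein groups that rest on a single identified peptide, are
#' exclusive to one digestion method, and whose peptide maps to a very large
#' number of external database entries -- the signature of a promiscuous,
#' likely spurious identification. Flagging never removes anything:
#' exclusion is a separate, explicitly configured action, mirroring manual
#' curation.
#'
#' @param observations Peptide observation tibble.
#' @param promiscuity A tibble (`peptide_sequence`, `n_matches`) of external
#'   database match counts (e.g. from a BLAST search); these counts are
#'   inputs, never computed here.
#' @param min_match_count Match count at or above which a peptide counts as
#'   promiscuous (default 1000).
#' @return A tibble with one row per group: `group_id`, `n_peptides`,
#'   `n_methods`, `peptide_sequence` (the single peptide, when there is
#'   one), `n_matches`, `flagged`.
#' @export
flag_suspect_outliers <- function(observations, promiscuity,
                                  min_match_count = 1000) {
  assert_columns(observations, c("group_id", "peptide_sequence", "method"),
                 "observations")
  assert_columns(promiscuity, c("peptide_sequence", "n_matches"),
                 "promiscuity")
  summ <- observations |>
    dplyr::group_by(.data$group_id) |>
    dplyr::summarise(
      n_peptides = dplyr::n_distinct(.data$peptide_sequence),
      n_methods = dplyr::n_distinct(.data$method),
      peptide_sequence = dplyr::if_else(
        dplyr::n_distinct(.data$peptide_sequence) == 1L,
        dplyr::first(.data$peptide_sequence), NA_character_),
      .groups = "drop"
    ) |>
    dplyr::left_join(dplyr::distinct(promiscuity), by = "peptide_sequence")
  summ$n_matches[is.na(summ$n_matches)] <- 0
  summ$flagged <- summ$n_peptides == 1L & summ$n_methods == 1L &
    summ$n_matches >= min_match_count
  summ
}
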