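# Relative protein-group quantification: riBAQ and length-normalized
# relative intensity (I_L^rel).

# Resolve the representative protein (longest member; ties broken
# lexicographically by ID) of every group. `groups` maps group_id ->
# member protein_id; when NULL, group IDs are taken to be protein IDs.
group_representatives <- function(group_ids, db, groups = NULL) {
  assert_columns(db, c("protein_id", "sequence"), "protein database")
  if (is.null(groups)) {
    groups <- tibble::tibble(group_id = group_ids, protein_id = group_ids)
  }
  assert_columns(groups, c("group_id", "protein_id"), "group membership")
  groups <- dplyr::filter(groups, .data$group_id %in% group_ids)
  memb <- dplyr::inner_join(groups, db, by = "protein_id")
  missing <- setdiff(group_ids, memb$group_id)
  if (length(missing) > 0) {
    rlang::abort(sprintf("group(s) with no member in the database: %s",
                         paste(utils::head(missing, 5), collapse = ", ")))
  }
  memb |>
    dplyr::mutate(len = nchar(.data$sequence)) |>
    dplyr::group_by(.data$group_id) |>
    dplyr::arrange(dplyr::desc(.data$len), .data$protein_id,
                   .by_group = TRUE) |>
    dplyr::summarise(
      representative = dplyr::first(.data$protein_id),
      representative_sequence = dplyr::first(.data$sequence),
      representative_length = dplyr::first(.data$len),
      .groups = "drop"
    )
}

# Shared intensity summarisation: one row per group x quantification unit,
# with duplicate rows of the same peptide/unit summed first (charge states).
summarise_group_intensities <- function(observations) {
  assert_columns(observations,
                 c("peptide_sequence", "group_id", "intensity",
                   quant_unit_cols()),
                 "observations")
  if (any(observations$intensity < 0)) {
    rlang::abort("intensities must be non-negative")
  }
  observations |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c("group_id", quant_unit_cols(), "peptide_sequence")))) |>
    dplyr::summarise(intensity = sum(.data$intensity), .groups = "drop") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c("group_id", quant_unit_cols())))) |>
    dplyr::summarise(
      summed_intensity = sum(.data$intensity),
      n_peptides_observed = sum(.data$intensity > 0),
      .groups = "drop"
    )
}

#' Relative protein-group quantification (riBAQ and I_L^rel)
#'
#' Computes, per protein group and quantification unit (sample x replicate x
#' digestion method), both in-sample-normalized label-free abundance
#' measures:
#'
#' * **riBAQ** -- the summed peptide MS1 intensity divided by the number of
#'   theoretically observable tryptic peptides of the group's representative
#'   protein (iBAQ), normalized to sum 1 within each unit;
#' * **I_L^rel** -- the summed intensity divided by the representative
#'   sequence length, normalized to sum 1 within each unit.
#'
#' The representative protein of a group is its longest member (ties broken
#' lexicographically by ID). Rows of the same peptide within one unit are
#' summed before quantification. Groups present with zero summed intensity
#' receive zero abundance rather than being dropped. Normalization runs over
#' every group in the input: quantify first, then remove decoys and
#' contaminants with [filter_decoys_contaminants()] (which logs the
#' quantitative loss) and renormalize with [requantify()].
#'
#' @param observations A tibble of peptide observations with columns
#'   `peptide_sequence`, `group_id`, `sample_id`, `replicate_id`, `method`,
#'   `intensity`.
#' @param db Protein database tibble (`protein_id`, `sequence`, and
#'   optionally `is_decoy`, `is_contaminant`).
#' @param groups Optional group-membership tibble (`group_id`,
#'   `protein_id`); by default group IDs are taken to be protein IDs.
#' @param sample_id Optional single sample ID to restrict to.
#' @param ibaq_missed_cleavages,ibaq_min_len,ibaq_max_len Parameters of the
#'   theoretical tryptic digest behind the iBAQ denominator (defaults: no
#'   missed cleavages, 7--30 residues).
#' @return A tibble with one row per group x unit: `group_id`, `sample_id`,
#'   `replicate_id`, `method`, `summed_intensity`, `n_peptides_observed`,
#'   `n_theoretical_peptides`, `representative`, `representative_length`,
#'   `ribaq`, `il_rel`, and (when flags are available in `db`) `is_decoy`,
#'   `is_contaminant`.
#' @examples
#' db <- tibble::tibble(protein_id = c("p1", "p2"),
#'                      sequence = c("AAAKCCCRDDDK", "EEEKFFFK"))
#' obs <- tibble::tibble(
#'   peptide_sequence = c("AAAK", "EEEK"), group_id = c("p1", "p2"),
#'   sample_id = "V", replicate_id = "R1", method = "tryptic",
#'   intensity = c(10, 10))
#' quantify_groups(obs, db)
#' @export
quantify_groups <- function(observations, db, groups = NULL,
                            sample_id = NULL,
                            ibaq_missed_cleavages = 0,
                            ibaq_min_len = 7, ibaq_max_len = 30) {
  if (!is.null(sample_id)) {
    observations <- dplyr::filter(observations,
                                  .data$sample_id %in% !!sample_id)
  }
  if (nrow(observations) == 0) {
    rlang::abort("no observations to quantify")
  }
  quant <- summarise_group_intensities(observations)
  reps <- group_representatives(unique(quant$group_id), db, groups)
  reps$n_theoretical_peptides <- vapply(
    reps$representative_sequence, count_theoretical_peptides,
    integer(1), missed_cleavages = ibaq_missed_cleavages,
    min_len = ibaq_min_len, max_len = ibaq_max_len, USE.NAMES = FALSE
  )
  quant <- dplyr::left_join(
    quant,
    reps[, c("group_id", "representative", "representative_length",
             "n_theoretical_peptides")],
    by = "group_id"
  )

  totals <- quant |>
    dplyr::group_by(dplyr::across(dplyr::all_of(quant_unit_cols()))) |>
    dplyr::summarise(unit_total = sum(.data$summed_intensity),
                     .groups = "drop")
  if (any(totals$unit_total <= 0)) {
    rlang::abort("empty sample: a quantification unit has zero total intensity")
  }

  quant <- quant |>
    dplyr::mutate(
      ibaq = .data$summed_intensity / .data$n_theoretical_peptides,
      length_norm = .data$summed_intensity / .data$representative_length
    ) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(quant_unit_cols()))) |>
    dplyr::mutate(
      ribaq = .data$ibaq / sum(.data$ibaq),
      il_rel = .data$length_norm / sum(.data$length_norm)
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-"ibaq", -"length_norm")

  flag_cols <- intersect(c("is_decoy", "is_contaminant"), names(db))
  if (length(flag_cols) > 0) {
    quant <- dplyr::left_join(
      quant,
      dplyr::rename(db[, c("protein_id", flag_cols)],
                    representative = "protein_id"),
      by = "representative"
    )
  }
  dplyr::arrange(quant, .data$sample_id, .data$replicate_id, .data$method,
                 .data$group_id)
}

#' @rdname quantify_groups
#' @details `compute_ribaq()` and `compute_il_rel()` are thin views of
#'   [quantify_groups()] returning only the respective abundance column.
#' @export
compute_ribaq <- function(observations, db, groups = NULL, sample_id = NULL,
                          ibaq_missed_cleavages = 0, ibaq_min_len = 7,
                          ibaq_max_len = 30) {
  quantify_groups(observations, db, groups, sample_id,
                  ibaq_missed_cleavages, ibaq_min_len, ibaq_max_len) |>
    dplyr::select(-"il_rel")
}

#' @rdname quantify_groups
#' @export
compute_il_rel <- function(observations, db, groups = NULL,
                           sample_id = NULL) {
  quantify_groups(observations, db, groups, sample_id) |>
    dplyr::select(-"ribaq")
}
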