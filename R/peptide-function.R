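# Post-processing of functional-peptide predictions: physicochemical
# annotation, score thresholds, length rules, overlap clustering,
# non-redundant representative selection and cross-referencing against
# verified peptides.

#' Peptide net charge by Henderson--Hasselbalch summation
#'
#' Net charge of a peptide at a given pH: the free N-terminus and the side
#' chains of Lys, Arg and His contribute `+1 / (1 + 10^(pH - pKa))`; the
#' free C-terminus and the side chains of Asp, Glu, Cys and Tyr contribute
#' `-1 / (1 + 10^(pKa - pH))`. With the default pKa set the one-decimal
#' rounded charges of all peptides in [read_functional_peptides()]
#' reproduce their published values.
#'
#' @param sequence One or more peptide sequences.
#' @param pH The pH (default 7).
#' @param pka A named pKa vector as from [default_pka_set()].
#' @return A numeric vector of raw (unrounded) net charges. Round for
#'   display with one decimal, half away from zero, as peptide property
#'   calculators print it.
#' @examples
#' round(net_charge("VRIRVDCK"), 1)  # 1.9
#' @export
net_charge <- function(sequence, pH = 7, pka = default_pka_set()) {
  stopifnot(pH > 0, pH < 14, all(pka > 1), all(pka < 14))
  needed <- c("Nterm", "Cterm", "D", "E", "C", "Y", "H", "K", "R")
  if (!all(needed %in% names(pka))) {
    rlang::abort(sprintf("pKa set must name: %s",
                         paste(needed, collapse = ", ")))
  }
  assert_valid_sequence(sequence)
  vapply(sequence, function(s) {
    cts <- aa_counts(s)
    pos <- 1 / (1 + 10^(pH - pka["Nterm"])) +
      cts["K"] / (1 + 10^(pH - pka["K"])) +
      cts["R"] / (1 + 10^(pH - pka["R"])) +
      cts["H"] / (1 + 10^(pH - pka["H"]))
    neg <- 1 / (1 + 10^(pka["Cterm"] - pH)) +
      cts["D"] / (1 + 10^(pka["D"] - pH)) +
      cts["E"] / (1 + 10^(pka["E"] - pH)) +
      cts["C"] / (1 + 10^(pka["C"] - pH)) +
      cts["Y"] / (1 + 10^(pka["Y"] - pH))
    unname(pos - neg)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Annotate prediction records with length and net charge
#'
#' Fills in peptide length and net charge at pH 7 (raw in `charge_ph7_raw`,
#' one-decimal half-away-from-zero rounded in `charge_ph7`). When parent
#' sequences are supplied, start/end coordinates are validated against them.
#'
#' @param records Prediction tibble with `peptide_sequence` (and optionally
#'   `protein_id`, `start`, `end`).
#' @param db Optional protein database for coordinate validation.
#' @param pka pKa set for the charge calculation.
#' @return The records with `length`, `charge_ph7_raw`, `charge_ph7` added.
#' @export
annotate_predictions <- function(records, db = NULL,
                                 pka = default_pka_set()) {
  assert_columns(records, "peptide_sequence", "records")
  if (nrow(records) == 0) {
    return(dplyr::mutate(records, length = integer(),
                         charge_ph7_raw = numeric(), charge_ph7 = numeric()))
  }
  if (!is.null(db) && all(c("protein_id", "start", "end") %in%
                          names(records))) {
    validate_coordinates(records, db)
  }
  records |>
    dplyr::mutate(
      length = nchar(.data$peptide_sequence),
      charge_ph7_raw = net_charge(.data$peptide_sequence, pka = pka),
      charge_ph7 = round_half_away(.data$charge_ph7_raw, 1)
    )
}

validate_coordinates <- function(records, db) {
  m <- match(records$protein_id, db$protein_id)
  known <- !is.na(m)
  seqs <- db$sequence[m[known]]
  sub <- records[known, ]
  bad <- sub$start < 1 | sub$end > nchar(seqs) | sub$end < sub$start |
    substring(seqs, sub$start, sub$end) != sub$peptide_sequence
  if (any(bad)) {
    rlang::abort(sprintf(
      "record coordinates inconsistent with parent sequence for: %s",
      paste(utils::head(sub$peptide_sequence[bad], 5), collapse = ", ")))
  }
  invisible(records)
}

#' Apply class-specific prediction score thresholds
#'
#' Retains records strictly above the class threshold: emulsifier classes
#' (`alpha`, `beta`, `gamma`) use a z-normalized score > 2 (scoring higher
#' than 97.5% of random peptides of the same length), radical scavenging
#' SCA > 0.43 and metal chelation CHE > 0.3 (more likely antioxidant than
#' not). Inequalities are strict: a score exactly at the threshold is
#' removed.
#'
#' @param records Prediction tibble with `class` and `score`.
#' @param thresholds Named vector of per-class thresholds.
#' @return A list with `kept` (records above threshold) and `counts`
#'   (per-class rows in/kept).
#' @export
apply_score_thresholds <- function(records,
                                   thresholds = c(alpha = 2, beta = 2,
                                                  gamma = 2, SCA = 0.43,
                                                  CHE = 0.3)) {
  assert_columns(records, c("class", "score"), "records")
  unknown <- setdiff(unique(records$class), names(thresholds))
  if (length(unknown) > 0) {
    rlang::abort(sprintf("no threshold for class(es): %s",
                         paste(unknown, collapse = ", ")))
  }
  kept <- dplyr::filter(records,
                        .data$score > thresholds[.data$class])
  counts <- records |>
    dplyr::count(.data$class, name = "n_in") |>
    dplyr::left_join(dplyr::count(kept, .data$class, name = "n_kept"),
                     by = "class") |>
    dplyr::mutate(n_kept = dplyr::coalesce(.data$n_kept, 0L))
  list(kept = kept, counts = counts)
}

#' Advisory length flags for emulsifier classes
#'
#' Flags, without removing, peptides outside the length ranges considered
#' favourable for interfacial function: amphiphilic helices (`alpha`)
#' should preferably be 15 residues or longer; interfacial sheet formers
#' (`beta`) 9--16 residues. `gamma` and the antioxidant classes carry no
#' length rule.
#'
#' @param records Prediction tibble with `class` and `length` (run
#'   [annotate_predictions()] first).
#' @return The records with logical column `length_flag` and explanatory
#'   `length_note`.
#' @export
apply_length_rules <- function(records) {
  assert_columns(records, c("class", "length"), "records")
  records |>
    dplyr::mutate(
      length_flag = dplyr::case_when(
        .data$class == "alpha" & .data$length < 15 ~ TRUE,
        .data$class == "beta" & (.data$length < 9 | .data$length > 16) ~ TRUE,
        TRUE ~ FALSE),
      length_note = dplyr::case_when(
        .data$class == "alpha" & .data$length < 15 ~
          "shorter than the preferred >=15 residues for amphiphilic helices",
        .data$class == "beta" & (.data$length < 9 | .data$length > 16) ~
          "outside the suggested 9-16 residue range for interfacial sheets",
        TRUE ~ NA_character_)
    )
}

# Interval-overlap connected components per parent protein: records sharing
# >= 1 residue on the same parent are linked; components found by sweeping
# sorted intervals (equivalent to transitive closure of pairwise overlap).
overlap_components <- function(records) {
  records |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::arrange(.data$start, .data$end, .by_group = TRUE) |>
    dplyr::mutate(
      chain = cumsum(c(TRUE, .data$start[-1] >
                         cummax(.data$end)[-dplyr::n()]))) |>
    dplyr::ungroup() |>
    dplyr::mutate(component = paste(.data$protein_id, .data$chain,
                                    sep = "#")) |>
    dplyr::select(-"chain")
}

#' Cluster predicted peptides by sequence overlap
#'
#' Within each prediction class, links two records when they come from the
#' same parent protein and their coordinate intervals share at least one
#' residue; clusters are the connected components under transitive closure.
#' Overlap is defined in parent coordinates, not by substring identity:
#' identical sequences at different loci do not overlap. The cluster
#' representative is the highest-scoring record (ties broken by longer
#' peptide, then smaller start).
#'
#' @param records Prediction tibble with `protein_id`, `start`, `end`,
#'   `class`, `score`.
#' @param db Optional protein database for coordinate validation.
#' @return The records with columns `cluster_id` and `is_representative`.
#' @export
cluster_by_overlap <- function(records, db = NULL) {
  assert_columns(records, c("peptide_sequence", "protein_id", "start",
                            "end", "class", "score"), "records")
  if (!is.null(db)) validate_coordinates(records, db)
  if (any(records$end - records$start + 1 !=
          nchar(records$peptide_sequence))) {
    rlang::abort("start/end extent must equal the sequence length")
  }
  out <- records |>
    dplyr::group_by(.data$class) |>
    dplyr::group_modify(function(d, key) {
      d <- overlap_components(d)
      d$cluster_id <- paste(key$class, d$component, sep = "/")
      dplyr::select(d, -"component")
    }) |>
    dplyr::ungroup()
  out |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::arrange(dplyr::desc(.data$score),
                   dplyr::desc(.data$end - .data$start), .data$start,
                   .by_group = TRUE) |>
    dplyr::mutate(is_representative = dplyr::row_number() == 1L) |>
    dplyr::ungroup()
}

#' Select top non-overlapping representative peptides
#'
#' Within each class, sorts records by score (descending) and greedily
#' accepts a record if it overlaps (same parent protein, intersecting
#' coordinates) no already-accepted record, stopping at `k` representatives
#' per class. This reproduces the "top five scoring showing no sequence
#' overlap with a higher-scoring peptide" selection rule.
#'
#' @param records Prediction tibble with `protein_id`, `start`, `end`,
#'   `class`, `score`.
#' @param k Maximum representatives per class (default 5).
#' @return The accepted records, score-sorted within class, with their
#'   overall score `rank` within the class.
#' @export
select_top_nonoverlapping <- function(records, k = 5) {
  assert_columns(records, c("protein_id", "start", "end", "class", "score"),
                 "records")
  records |>
    dplyr::group_by(.data$class) |>
    dplyr::group_modify(function(d, key) {
      d <- dplyr::arrange(d, dplyr::desc(.data$score),
                          dplyr::desc(.data$end - .data$start), .data$start)
      d$rank <- seq_len(nrow(d))
      acc <- integer(0)
      for (i in seq_len(nrow(d))) {
        if (length(acc) >= k) break
        clash <- any(d$protein_id[acc] == d$protein_id[i] &
                       d$start[acc] <= d$end[i] &
                       d$end[acc] >= d$start[i])
        if (!clash) acc <- c(acc, i)
      }
      d[acc, , drop = FALSE]
    }) |>
    dplyr::ungroup()
}

#' Cross-reference verified functional peptides against a protein database
#'
#' Locates each verified peptide in the member proteins of the database by
#' exact substring match and reports all match loci; when a quantification
#' tibble is supplied, the parent protein's relative abundance in each
#' extract is attached.
#'
#' @param verified Tibble with `peptide_sequence` (duplicated rows are
#'   deduplicated) and optionally annotation columns carried through.
#' @param db Protein database tibble.
#' @param quant Optional quantification tibble whose `il_rel` (per
#'   sample/unit) is attached to matched parents.
#' @return A tibble of matches: verified columns, `protein_id`, `start`,
#'   `end`, plus abundance columns when `quant` is given.
#' @export
crossref_verified <- function(verified, db, quant = NULL) {
  assert_columns(verified, "peptide_sequence", "verified")
  assert_columns(db, c("protein_id", "sequence"), "protein database")
  verified <- dplyr::distinct(verified)
  hits <- purrr::pmap_dfr(
    list(seq_len(nrow(verified))),
    function(i) {
      pep <- verified$peptide_sequence[i]
      loc <- stringr::str_locate_all(db$sequence, stringr::fixed(pep))
      found <- which(vapply(loc, nrow, integer(1)) > 0)
      if (length(found) == 0) return(tibble::tibble())
      purrr::map_dfr(found, function(j) {
        dplyr::bind_cols(
          verified[rep(i, nrow(loc[[j]])), , drop = FALSE],
          tibble::tibble(protein_id = db$protein_id[j],
                         start = unname(loc[[j]][, 1]),
                         end = unname(loc[[j]][, 2])))
      })
    })
  if (nrow(hits) > 0 && !is.null(quant)) {
    key <- if ("representative" %in% names(quant)) "representative" else "group_id"
    ab <- quant |>
      dplyr::group_by(.data$sample_id,
                      protein_id = .data[[key]]) |>
      dplyr::summarise(il_rel = mean(.data$il_rel), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "sample_id", values_from = "il_rel",
                         names_prefix = "il_rel_", values_fill = 0)
    hits <- dplyr::left_join(hits, ab, by = "protein_id")
  }
  hits
}
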