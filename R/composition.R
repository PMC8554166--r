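# Amino-acid composition estimation from MS1 quantification and conversion
# of amino-acid analysis (mg/g) data to relative molar abundance.

new_aa_composition <- function(freq, source, pooled_keys = character(),
                               check_sum = TRUE) {
  stopifnot(!check_sum || abs(sum(freq$frequency) - 1) < 1e-6 ||
              nrow(freq) == 0)
  out <- tibble::as_tibble(freq)
  class(out) <- c("aa_composition", class(out))
  attr(out, "source") <- source
  attr(out, "pooled_keys") <- pooled_keys
  out
}

#' Relative amino-acid frequency of one peptide or protein sequence
#'
#' Counts of each residue divided by sequence length, over the 20-letter
#' alphabet (absent residues appear with frequency 0).
#'
#' @param sequence A single amino-acid sequence.
#' @return A tibble with columns `aa` and `frequency`, summing to 1.
#' @examples
#' peptide_aa_frequency("HP")
#' @export
peptide_aa_frequency <- function(sequence) {
  counts <- aa_counts(assert_valid_sequence(sequence))
  tibble::tibble(aa = names(counts),
                 frequency = unname(counts / sum(counts)))
}

# residue-frequency matrix (sequences x 20) -- shared by both estimators
frequency_matrix <- function(sequences) {
  t(vapply(sequences, function(s) {
    cts <- aa_counts(s)
    cts / sum(cts)
  }, numeric(20L)))
}

#' Amino-acid composition from intensity-weighted peptide-level data
#'
#' The peptide-level estimator of sample amino-acid composition: each
#' observed peptide contributes its residue frequencies weighted by its
#' relative MS1 intensity within the supplied observation set,
#' `f_AA = sum_p f_AA(p) * I_rel(p)`. Decoys and contaminants are expected
#' to have been removed upstream.
#'
#' @param observations Peptide observation tibble with `peptide_sequence`
#'   and `intensity`; rows of the same peptide are summed first.
#' @return An `aa_composition` tibble (`aa`, `frequency`) summing to 1, with
#'   attribute `source = "peptide_level"`.
#' @export
composition_from_peptides <- function(observations) {
  assert_columns(observations, c("peptide_sequence", "intensity"),
                 "observations")
  obs <- observations |>
    dplyr::group_by(.data$peptide_sequence) |>
    dplyr::summarise(intensity = sum(.data$intensity), .groups = "drop")
  tot <- sum(obs$intensity)
  if (tot <= 0) rlang::abort("all intensities are zero")
  assert_valid_sequence(obs$peptide_sequence, "peptide_sequence")
  fm <- frequency_matrix(obs$peptide_sequence)
  freq <- colSums(fm * (obs$intensity / tot))
  new_aa_composition(
    tibble::tibble(aa = names(freq), frequency = unname(freq)),
    source = "peptide_level")
}

#' Amino-acid composition from protein-level quantification
#'
#' The protein-level estimator: full-length residue frequencies of each
#' quantified protein weighted by its length-normalized relative abundance,
#' `f_AA = sum_q f_AA(q) * I_L^rel(q)`.
#'
#' @param quant A quantification tibble with `group_id` and `il_rel`
#'   (one quantification unit; `il_rel` should sum to 1).
#' @param db Protein database tibble; the representative sequence of each
#'   group is looked up here (column `representative` of `quant` if
#'   present, else `group_id` as protein ID).
#' @return An `aa_composition` tibble with attribute
#'   `source = "protein_level"`.
#' @export
composition_from_proteins <- function(quant, db) {
  assert_columns(quant, c("group_id", "il_rel"), "quant")
  assert_columns(db, c("protein_id", "sequence"), "protein database")
  key <- if ("representative" %in% names(quant)) {
    quant$representative
  } else {
    quant$group_id
  }
  idx <- match(key, db$protein_id)
  if (anyNA(idx)) {
    rlang::abort(sprintf(
      "representative protein(s) missing from the database: %s",
      paste(utils::head(unique(key[is.na(idx)]), 5), collapse = ", ")))
  }
  w <- quant$il_rel
  tot <- sum(w)
  if (tot <= 0) rlang::abort("all il_rel weights are zero")
  fm <- frequency_matrix(db$sequence[idx])
  freq <- colSums(fm * (w / tot))
  new_aa_composition(
    tibble::tibble(aa = colnames(fm) %||% aa_alphabet(),
                   frequency = unname(freq)),
    source = "protein_level")
}

#' Convert amino-acid analysis data to relative molar abundance
#'
#' Converts mg AA per g extract to relative molar fractions: the weight
#' share of each amino acid is divided by its free molecular weight and
#' multiplied by the mean amino-acid molecular weight including water
#' (128 g/mol). The raw converted values sum to
#' `128 * sum(w_i / MW_i)` -- not necessarily 1 -- so a renormalized
#' composition is returned by default with the raw values kept in the
#' `raw_molar` column.
#'
#' @param aaa A tibble from [read_aaa_table()] (`aa`, `mg_per_g`) or a named
#'   numeric vector of mg/g values. Pooled keys `Asx`/`Glx` are carried
#'   through using the mean of their constituent molecular weights.
#' @param renormalize Divide by the sum so frequencies total 1 (default).
#' @return An `aa_composition` tibble (`aa`, `frequency`, `raw_molar`) with
#'   attribute `source = "aaa"`; pooled keys recorded in the `pooled_keys`
#'   attribute.
#' @export
aaa_to_molar <- function(aaa, renormalize = TRUE) {
  if (is.numeric(aaa) && !is.null(names(aaa))) {
    aaa <- tibble::tibble(aa = names(aaa), mg_per_g = unname(aaa))
  }
  assert_columns(aaa, c("aa", "mg_per_g"), "AAA data")
  mw <- aa_molecular_weights()
  unknown <- setdiff(aaa$aa, names(mw))
  if (length(unknown) > 0) {
    rlang::abort(sprintf("no molecular weight for amino-acid key(s): %s",
                         paste(unknown, collapse = ", ")))
  }
  if (sum(aaa$mg_per_g) <= 0) rlang::abort("AAA data contain no positive value")
  wfrac <- aaa$mg_per_g / sum(aaa$mg_per_g)
  raw <- wfrac / mw[aaa$aa] * mean_aa_weight()
  freq <- if (renormalize) raw / sum(raw) else raw
  new_aa_composition(
    tibble::tibble(aa = aaa$aa, frequency = unname(freq),
                   raw_molar = unname(raw)),
    source = "aaa",
    pooled_keys = intersect(aaa$aa, c("Asx", "Glx")),
    check_sum = renormalize)
}

#' Essential to non-essential amino-acid ratio
#'
#' The nutritional quality index `sum(EAA) / sum(NEAA)` on molar fractions.
#'
#' @param comp An `aa_composition` tibble (or any tibble with `aa` and
#'   `frequency`).
#' @param eaa The essential set; defaults to [essential_aas()]. The pooled
#'   keys `Asx` and `Glx` count as non-essential.
#' @return A single number.
#' @export
eaa_neaa_ratio <- function(comp, eaa = essential_aas()) {
  assert_columns(comp, c("aa", "frequency"), "composition")
  e <- sum(comp$frequency[comp$aa %in% eaa])
  ne <- sum(comp$frequency[!comp$aa %in% eaa])
  if (ne <= 0) rlang::abort("non-essential sum is zero; ratio undefined")
  e / ne
}

#' Pool Asp/Asn and Glu/Gln into Asx and Glx
#'
#' Acid hydrolysis deamidates Asn and Gln, so amino-acid analysis reports
#' only the pooled forms. This helper puts sequence-derived compositions on
#' the same 18-key alphabet for comparison.
#'
#' @param comp An `aa_composition` tibble over the 20-letter alphabet.
#' @return An `aa_composition` with `D`+`N` summed into `Asx` and `E`+`Q`
#'   into `Glx`.
#' @export
pool_asx_glx <- function(comp) {
  assert_columns(comp, c("aa", "frequency"), "composition")
  pooled <- comp |>
    dplyr::mutate(aa = dplyr::case_match(.data$aa,
                                         c("D", "N") ~ "Asx",
                                         c("E", "Q") ~ "Glx",
                                         .default = .data$aa)) |>
    dplyr::group_by(.data$aa) |>
    dplyr::summarise(frequency = sum(.data$frequency), .groups = "drop")
  new_aa_composition(pooled, source = attr(comp, "source") %||% "pooled",
                     pooled_keys = c("Asx", "Glx"))
}

#' Compare amino-acid compositions across sources
#'
#' Aligns several compositions (peptide-level, protein-level, AAA,
#' reference tables) on a shared alphabet and returns a long-format
#' comparison. If any composition carries pooled `Asx`/`Glx` keys, the
#' others are pooled with [pool_asx_glx()] before comparison.
#'
#' @param comps A named list of `aa_composition` tibbles; names label the
#'   sources.
#' @param reference Optional name of the composition differences are taken
#'   against (defaults to the first).
#' @return A long tibble (`aa`, `source`, `frequency`, `diff_vs_reference`).
#' @export
compare_compositions <- function(comps, reference = NULL) {
  stopifnot(is.list(comps), length(comps) >= 1, !is.null(names(comps)))
  any_pooled <- any(purrr::map_lgl(
    comps, function(x) any(c("Asx", "Glx") %in% x$aa)))
  if (any_pooled) {
    comps <- purrr::map(comps, function(x) {
      if (any(c("Asx", "Glx") %in% x$aa)) x else pool_asx_glx(x)
    })
  }
  alphabet <- sort(unique(unlist(purrr::map(comps, "aa"))))
  long <- purrr::imap_dfr(comps, function(x, nm) {
    full <- tibble::tibble(aa = alphabet) |>
      dplyr::left_join(x[, c("aa", "frequency")], by = "aa")
    missing_keys <- setdiff(x$aa, alphabet)
    if (length(missing_keys) > 0) {
      rlang::abort(sprintf("incompatible alphabets after pooling (%s)", nm))
    }
    full$source <- nm
    full
  })
  reference <- reference %||% names(comps)[1]
  if (!reference %in% names(comps)) {
    rlang::abort(sprintf("reference '%s' is not among the sources", reference))
  }
  ref <- dplyr::filter(long, .data$source == reference)
  long |>
    dplyr::left_join(ref[, c("aa", "frequency")], by = "aa",
                     suffix = c("", "_ref")) |>
    dplyr::mutate(diff_vs_reference = .data$frequency - .data$frequency_ref) |>
    dplyr::select(-"frequency_ref")
}
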