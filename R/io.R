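#' Read a protein reference database from FASTA
#'
#' Reads a FASTA file of protein sequences into a tibble, marking decoy and
#' contaminant entries by their header prefix (the MaxQuant convention of
#' `REV_` for reversed decoys and `CON_` for common contaminants).
#'
#' @param path Path to a FASTA file.
#' @param decoy_prefix,contaminant_prefix Header prefixes flagging decoy and
#'   contaminant entries.
#' @return A tibble with columns `protein_id`, `sequence`, `is_decoy`,
#'   `is_contaminant`.
#' @seealso [write_protein_fasta()]
#' @export
read_protein_fasta <- function(path, decoy_prefix = "REV_",
                               contaminant_prefix = "CON_") {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  aas <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aas))
  seqs <- as.character(aas)
  if (anyDuplicated(ids)) {
    rlang::abort(sprintf("duplicated protein IDs in %s: %s", path,
                         paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  ok <- grepl(paste0("^[", paste(aa_alphabet(), collapse = ""), "]+$"), seqs)
  if (!all(ok)) {
    # locate the offending record's header line for a useful parse error
    lines <- readLines(path)
    bad_id <- ids[which(!ok)[1]]
    line_no <- grep(paste0("^>", bad_id), lines)[1]
    rlang::abort(sprintf(
      "illegal residue in sequence of '%s' (header at line %d of %s)",
      bad_id, line_no, path
    ))
  }
  tibble::tibble(
    protein_id = ids,
    sequence = unname(seqs),
    is_decoy = startsWith(ids, decoy_prefix),
    is_contaminant = startsWith(ids, contaminant_prefix)
  )
}

#' Write a protein tibble to FASTA
#'
#' @param proteins A tibble with columns `protein_id` and `sequence`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(proteins, path) {
  assert_columns(proteins, c("protein_id", "sequence"), "proteins")
  set <- Biostrings::AAStringSet(proteins$sequence)
  names(set) <- proteins$protein_id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# canonical column set of a peptide observation table
peptide_table_cols <- function() {
  c("peptide_sequence", "group_id", "sample_id", "replicate_id",
    "method", "intensity", "psm_score")
}

#' Read a peptide-level quantification table
#'
#' Reads a TSV of identified peptides with per-sample MS1 intensities, in a
#' MaxQuant-evidence-like dialect. The expected columns (after applying
#' `columns` renaming) are `peptide_sequence`, `group_id`, `sample_id`,
#' `replicate_id`, `method`, `intensity` and `psm_score`. Because the column
#' subset emitted by search engines varies between versions, the mapping from
#' file columns to canonical names is configurable rather than fixed.
#'
#' Modified-residue notation (`_PEPT(ox)IDE_` style underscores and
#' parenthesised annotations) is stripped with a warning: downstream
#' arithmetic uses plain sequences. Rows with zero or missing intensity are
#' retained and flagged in `flagged_zero_intensity`; rows whose stripped
#' sequence still contains non-canonical characters are rejected and returned
#' in the `rejected` attribute, so that rows in = rows kept + rows rejected.
#'
#' @param path Path to a tab- (or comma-) separated file with a header.
#' @param columns Optional named character vector mapping canonical names to
#'   file column names, e.g. `c(peptide_sequence = "Sequence")`.
#' @param delim Field delimiter, `"\t"` by default.
#' @return A tibble of peptide observations; attribute `rejected` holds
#'   rejected rows.
#' @export
read_peptide_table <- function(path, columns = NULL, delim = "\t") {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (!is.null(columns)) {
    for (canon in names(columns)) {
      if (!columns[[canon]] %in% names(raw)) {
        rlang::abort(sprintf(
          "mapped column '%s' (for '%s') not found in %s",
          columns[[canon]], canon, path))
      }
      names(raw)[names(raw) == columns[[canon]]] <- canon
    }
  }
  assert_columns(raw, peptide_table_cols(), sprintf("peptide table %s", path))
  raw <- raw[, union(peptide_table_cols(), names(raw))]

  stripped <- gsub("_", "", gsub("\\([^)]*\\)", "", raw$peptide_sequence))
  if (any(stripped != raw$peptide_sequence)) {
    rlang::warn(sprintf(
      "stripped modification annotations from %d peptide sequence(s)",
      sum(stripped != raw$peptide_sequence)))
    raw$peptide_sequence <- stripped
  }
  valid <- grepl(paste0("^[", paste(aa_alphabet(), collapse = ""), "]+$"),
                 raw$peptide_sequence)
  rejected <- raw[!valid, , drop = FALSE]
  if (nrow(rejected) > 0) {
    rlang::warn(sprintf("rejected %d row(s) with non-canonical sequences",
                        nrow(rejected)))
  }
  out <- raw[valid, , drop = FALSE]
  out$intensity <- as.numeric(out$intensity)
  out$flagged_zero_intensity <- is.na(out$intensity) | out$intensity <= 0
  out$intensity[is.na(out$intensity)] <- 0
  if (any(out$intensity < 0)) {
    rlang::abort("negative intensities are not valid MS1 intensities")
  }
  attr(out, "rejected") <- rejected
  tibble::as_tibble(out)
}

#' Write a peptide observation table to TSV
#'
#' @param observations A peptide observation tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(observations, path) {
  assert_columns(observations, peptide_table_cols(), "observations")
  readr::write_tsv(observations[, peptide_table_cols()], path, progress = FALSE)
  invisible(path)
}

#' Read an amino-acid analysis (AAA) table
#'
#' Reads a two-column table of amino acid (one-letter code, or the pooled
#' keys `Asx`/`Glx` arising from acid hydrolysis where Asp/Asn and Gln/Glu
#' are indistinguishable) against concentration in mg per g extract.
#'
#' @param path Path to a TSV/CSV file with columns `aa` and `mg_per_g`.
#' @param delim Field delimiter; `","` is accepted for CSV input.
#' @return A tibble with columns `aa`, `mg_per_g`, `pooled` (logical, `TRUE`
#'   for Asx/Glx rows).
#' @export
read_aaa_table <- function(path, delim = "\t") {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  assert_columns(raw, c("aa", "mg_per_g"), sprintf("AAA table %s", path))
  known <- c(aa_alphabet(), "Asx", "Glx")
  bad <- setdiff(raw$aa, known)
  if (length(bad) > 0) {
    rlang::abort(sprintf("unknown amino-acid code(s) in %s: %s", path,
                         paste(bad, collapse = ", ")))
  }
  if (any(raw$mg_per_g < 0)) {
    rlang::abort("negative concentrations are not valid AAA values")
  }
  tibble::tibble(
    aa = raw$aa,
    mg_per_g = as.numeric(raw$mg_per_g),
    pooled = raw$aa %in% c("Asx", "Glx")
  )
}

#' Read a per-protein subcellular localization table
#'
#' @param path Path to a TSV with columns `protein_id`, `compartment` and
#'   optionally a predictor confidence column.
#' @return A tibble with at least `protein_id` and `compartment`.
#' @export
read_localization_table <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(raw, c("protein_id", "compartment"),
                 sprintf("localization table %s", path))
  tibble::as_tibble(raw)
}

#' Read a functional-peptide prediction table
#'
#' Reads predictor output for candidate emulsifier (classes `alpha`, `beta`,
#' `gamma`) and antioxidant (`SCA` free-radical scavenging, `CHE` metal
#' chelating) peptides. Scores are consumed, never computed here.
#'
#' @param path Path to a TSV with columns `peptide_sequence`, `protein_id`,
#'   `start`, `end`, `class`, `score`.
#' @return A tibble of prediction records.
#' @export
read_prediction_table <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(raw, c("peptide_sequence", "protein_id", "start", "end",
                        "class", "score"),
                 sprintf("prediction table %s", path))
  bad <- setdiff(raw$class, c("alpha", "beta", "gamma", "SCA", "CHE"))
  if (length(bad) > 0) {
    rlang::abort(sprintf("unknown prediction class(es): %s",
                         paste(bad, collapse = ", ")))
  }
  tibble::as_tibble(raw)
}

#' Literature-reported functional peptides from *Eucheuma denticulatum*
#'
#' Returns the packaged table of previously verified and predicted
#' emulsifier and antioxidant peptides from enzymatic *E. denticulatum*
#' protein extracts, with their published annotation, class, predictor
#' score, parent protein ID(s), sequence, length and net charge at pH 7.
#' This table is the regression reference for [net_charge()] and
#' [annotate_predictions()], and its verified rows feed
#' [crossref_verified()].
#'
#' @param verified_only If `TRUE`, return only the peptides with *in vitro*
#'   verified activity.
#' @return A tibble with columns `annotation`, `class`, `verified`, `score`,
#'   `protein_ids`, `peptide_sequence`, `length`, `charge_ph7`.
#' @export
read_functional_peptides <- function(verified_only = FALSE) {
  path <- system.file("extdata", "edenticulatum_functional_peptides.tsv",
                      package = "phycoprot", mustWork = TRUE)
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  tbl$length <- as.integer(tbl$length)
  if (verified_only) tbl <- dplyr::filter(tbl, .data$verified)
  tbl
}
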