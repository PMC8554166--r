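# Internal helpers shared across modules.

# Round half away from zero (so 1.85 -> 1.9 and -1.85 -> -1.9), matching how
# peptide property calculators print one-decimal net charges. base::round()
# rounds half to even and must not be used for the printed-charge regression.
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Residue counts of one sequence over the canonical alphabet.
aa_counts <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  tab <- table(factor(chars, levels = aa_alphabet()))
  stats::setNames(as.numeric(tab), names(tab))
}

assert_valid_sequence <- function(sequence, what = "sequence") {
  bad <- !grepl(paste0("^[", paste(aa_alphabet(), collapse = ""), "]+$"),
                sequence)
  if (any(bad)) {
    rlang::abort(sprintf(
      "%s contains characters outside the 20 canonical amino-acid codes: %s",
      what, paste(utils::head(sequence[bad], 3), collapse = ", ")
    ))
  }
  invisible(sequence)
}

assert_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    rlang::abort(sprintf(
      "%s is missing required column(s): %s (found: %s)",
      what, paste(missing, collapse = ", "), paste(names(df), collapse = ", ")
    ))
  }
  invisible(df)
}

# Quantification "unit": the within-sample normalization scope.
quant_unit_cols <- function() c("sample_id", "replicate_id", "method")
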