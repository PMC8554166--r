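#' In-silico proteolytic digestion
#'
#' Digest a protein sequence under one of three specificity modes used in
#' database searching of bottom-up proteomics data:
#'
#' * `"tryptic"`: cleavage C-terminal of K or R, but not when the next
#'   residue is P, allowing up to `missed_cleavages` skipped sites;
#' * `"semi"`: peptides with at least one tryptic terminus (every prefix and
#'   suffix of each fully tryptic peptide);
#' * `"unspecific"`: every substring within the length bounds.
#'
#' Coordinates are 1-based and inclusive within the parent sequence.
#'
#' @param sequence A single protein sequence (uppercase, 20 canonical codes).
#' @param mode One of `"tryptic"`, `"semi"`, `"unspecific"`.
#' @param missed_cleavages Maximum number of missed cleavage sites
#'   (tryptic and semi modes).
#' @param min_len,max_len Inclusive peptide length bounds. The conventional
#'   bound for unspecific searches is 5--65 residues.
#' @return A tibble with columns `peptide`, `start`, `end`. Distinct
#'   (peptide, start, end) triples; the same sequence may occur at several
#'   loci.
#' @examples
#' digest("AAAKCCCR", "tryptic", missed_cleavages = 0)
#' digest("AKPR", "tryptic")  # no cleavage before proline
#' @export
digest <- function(sequence,
                   mode = c("tryptic", "semi", "unspecific"),
                   missed_cleavages = 2,
                   min_len = 1,
                   max_len = Inf) {
  mode <- match.arg(mode)
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    rlang::abort("`sequence` must be a single non-empty string")
  }
  assert_valid_sequence(sequence)
  stopifnot(missed_cleavages >= 0, min_len <= max_len, min_len >= 1)
  n <- nchar(sequence)

  if (mode == "unspecific") {
    lo <- max(min_len, 1)
    hi <- min(max_len, n)
    if (lo > hi) {
      return(tibble::tibble(peptide = character(), start = integer(),
                            end = integer()))
    }
    pieces <- purrr::map(lo:hi, function(L) {
      starts <- seq_len(n - L + 1L)
      tibble::tibble(
        peptide = substring(sequence, starts, starts + L - 1L),
        start = as.integer(starts),
        end = as.integer(starts + L - 1L)
      )
    })
    return(dplyr::distinct(dplyr::bind_rows(pieces)))
  }

  # Fully tryptic fragments: cleavage after K/R not followed by P.
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  cut_after <- which(chars %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & chars[cut_after + 1L] != "P"]
  bounds <- c(0L, cut_after, n)  # fragment i spans (bounds[i]+1) : bounds[i+1]
  nfrag <- length(bounds) - 1L

  out <- vector("list", 0L)
  for (i in seq_len(nfrag)) {
    jmax <- min(nfrag, i + missed_cleavages)
    for (j in i:jmax) {
      s <- bounds[i] + 1L
      e <- bounds[j + 1L]
      if (mode == "tryptic") {
        L <- e - s + 1L
        if (L >= min_len && L <= max_len) {
          out[[length(out) + 1L]] <- tibble::tibble(
            peptide = substr(sequence, s, e),
            start = s, end = e
          )
        }
      } else {
        # semi: one terminus must remain tryptic -> all prefixes plus all
        # suffixes of the fully tryptic stretch.
        L <- e - s + 1L
        ends <- s:e
        pref <- tibble::tibble(start = s, end = ends)
        suf <- tibble::tibble(start = ends, end = e)
        both <- dplyr::distinct(dplyr::bind_rows(pref, suf))
        both <- dplyr::filter(both,
                              .data$end - .data$start + 1L >= min_len,
                              .data$end - .data$start + 1L <= max_len)
        if (nrow(both) > 0) {
          both$peptide <- substring(sequence, both$start, both$end)
          out[[length(out) + 1L]] <- both[, c("peptide", "start", "end")]
        }
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(peptide = character(), start = integer(),
                          end = integer()))
  }
  res <- dplyr::distinct(dplyr::bind_rows(out))
  res$start <- as.integer(res$start)
  res$end <- as.integer(res$end)
  dplyr::arrange(res, .data$start, .data$end)
}

#' Count theoretically observable tryptic peptides (iBAQ denominator)
#'
#' The iBAQ denominator: the number of distinct fully tryptic peptides of a
#' protein within a length window. The conventional window is 7--30 residues
#' with no missed cleavages. Proteins whose digest yields no in-range peptide
#' are floored at 1 so that iBAQ remains defined.
#'
#' @inheritParams digest
#' @return A positive integer.
#' @examples
#' count_theoretical_peptides("AAAKCCCR", min_len = 2)  # 2
#' count_theoretical_peptides("AAAKCCCR", min_len = 6)  # floored at 1
#' @export
count_theoretical_peptides <- function(sequence,
                                       missed_cleavages = 0,
                                       min_len = 7,
                                       max_len = 30) {
  peps <- digest(sequence, "tryptic", missed_cleavages = missed_cleavages,
                 min_len = min_len, max_len = max_len)
  max(1L, length(unique(peps$peptide)))
}
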