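# Subcellular-distribution summaries: compartment binning, pooled
# intracellular fractions with propagated uncertainty, ANOVA/Tukey.

#' Bin quantified abundance by subcellular compartment
#'
#' Sums relative abundances over the predicted compartment of each group's
#' representative protein. Labels outside the ten-compartment vocabulary
#' ([deeploc_compartments()]) map to `"unknown"` with a warning; groups with
#' no label at all also fall into `"unknown"`. All non-extracellular known
#' compartments are additionally pooled as `"intracellular"` in
#' [compartment_distribution()].
#'
#' @param quant Quantification tibble (per unit, `il_rel` summing to 1).
#' @param localization Tibble (`protein_id`, `compartment`).
#' @param value Abundance column to sum.
#' @return A tibble with one row per unit x compartment: unit columns,
#'   `compartment`, `fraction`; fractions sum to 1 within each unit.
#' @export
bin_by_compartment <- function(quant, localization, value = "il_rel") {
  assert_columns(quant, c("group_id", value, quant_unit_cols()), "quant")
  assert_columns(localization, c("protein_id", "compartment"), "localization")
  key <- if ("representative" %in% names(quant)) "representative" else "group_id"
  loc <- dplyr::rename(dplyr::distinct(localization[, c("protein_id",
                                                        "compartment")]),
                       !!key := "protein_id")
  joined <- dplyr::left_join(quant, loc, by = key)
  known <- c(deeploc_compartments(), "unknown")
  odd <- setdiff(stats::na.omit(unique(joined$compartment)), known)
  if (length(odd) > 0) {
    rlang::warn(sprintf("compartment label(s) outside the vocabulary mapped to 'unknown': %s",
                        paste(odd, collapse = ", ")))
  }
  joined$compartment[is.na(joined$compartment) |
                       !joined$compartment %in% known] <- "unknown"
  joined |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c(quant_unit_cols(), "compartment")))) |>
    dplyr::summarise(fraction = sum(.data[[value]]), .groups = "drop")
}

#' Standard deviation of a sum of independent variables
#'
#' The square root of the sum of squared standard deviations, used to
#' propagate replicate uncertainty onto pooled quantities such as the
#' intracellular fraction.
#'
#' @param sds Non-negative standard deviations.
#' @return A single number.
#' @examples
#' propagate_sum_sd(c(3, 4))  # 5
#' @export
propagate_sum_sd <- function(sds) {
  stopifnot(is.numeric(sds), all(sds >= 0))
  sqrt(sum(sds^2))
}

#' Per-extract compartment distribution with pooled intracellular fraction
#'
#' Summarises binned compartment fractions over technical replicates: mean
#' and standard deviation per compartment, plus the pooled
#' `"intracellular"` fraction (sum of all non-extracellular known
#' compartments), with its standard deviation propagated as the root of the
#' summed variances under independence.
#'
#' @param binned Output of [bin_by_compartment()].
#' @return A tibble with one row per sample x method x compartment (mean
#'   and sd over replicates), the pooled rows carrying
#'   `compartment = "intracellular"`.
#' @export
compartment_distribution <- function(binned) {
  assert_columns(binned, c(quant_unit_cols(), "compartment", "fraction"),
                 "binned")
  per_comp <- binned |>
    tidyr::complete(
      tidyr::nesting(!!!rlang::syms(quant_unit_cols())),
      !!rlang::sym("compartment"), fill = list(fraction = 0)) |>
    dplyr::group_by(.data$sample_id, .data$method, .data$compartment) |>
    dplyr::summarise(
      mean_fraction = mean(.data$fraction),
      sd_fraction = if (dplyr::n() > 1) stats::sd(.data$fraction) else 0,
      n_replicates = dplyr::n(),
      .groups = "drop"
    )
  intra <- per_comp |>
    dplyr::filter(!.data$compartment %in% c("Extracellular", "unknown")) |>
    dplyr::group_by(.data$sample_id, .data$method) |>
    dplyr::summarise(
      compartment = "intracellular",
      mean_fraction = sum(.data$mean_fraction),
      sd_fraction = propagate_sum_sd(.data$sd_fraction),
      n_replicates = .data$n_replicates[1],
      .groups = "drop"
    )
  dplyr::bind_rows(per_comp, intra)
}

# Compact letter display from a logical "significantly different" matrix:
# the standard insert-and-absorb algorithm, groups ordered by mean.
compact_letters <- function(sig, means) {
  labs <- names(means)[order(-means)]
  letters_list <- list(labs)  # start with one letter containing everything
  for (i in seq_along(labs)) {
    for (j in seq_along(labs)) {
      if (j <= i) next
      a <- labs[i]; b <- labs[j]
      if (!sig[a, b]) next
      # a and b must not share a letter; split any letter containing both
      k <- 1
      while (k <= length(letters_list)) {
        set <- letters_list[[k]]
        if (a %in% set && b %in% set) {
          letters_list[[k]] <- setdiff(set, b)
          new_set <- setdiff(set, a)
          dup <- any(vapply(letters_list,
                            function(s) all(new_set %in% s), logical(1)))
          if (!dup) letters_list[[length(letters_list) + 1]] <- new_set
        }
        k <- k + 1
      }
    }
  }
  # drop empty sets, exact duplicates, and sets absorbed by a superset
  letters_list <- unique(letters_list[lengths(letters_list) > 0])
  absorbed <- vapply(seq_along(letters_list), function(k) {
    any(vapply(seq_along(letters_list), function(m) {
      m != k && all(letters_list[[k]] %in% letters_list[[m]]) &&
        length(letters_list[[k]]) < length(letters_list[[m]])
    }, logical(1)))
  }, logical(1))
  letters_list <- letters_list[!absorbed]
  vapply(names(means), function(g) {
    paste(letters[which(vapply(letters_list, function(s) g %in% s,
                               logical(1)))], collapse = "")
  }, character(1))
}

#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' Fits a one-way ANOVA across groups (e.g. intracellular fraction per
#' extraction method, replicates as observations) and performs Tukey's
#' honestly-significant-difference test at the given confidence level.
#' Pairwise results carry significance marks (`*` p < 0.05, `**` p < 0.01,
#' `ns` otherwise) and group means a compact letter display. When every
#' observation is identical the F statistic is undefined; all comparisons
#' are reported `ns` with a note.
#'
#' @param data A tibble with a grouping column and a value column.
#' @param group,value Column names (strings) of the grouping label and the
#'   response.
#' @param alpha Significance level for the letter display (default 0.05).
#' @return An object of class `tukey_anova`: a list with `anova`
#'   (F statistic, degrees of freedom, p value), `comparisons` (pairwise
#'   tibble with adjusted p values and marks), `letters` (tibble of group
#'   means, sds and letters) and `note`. Supports [tidy()] and [glance()].
#' @export
anova_tukey <- function(data, group = "group", value = "value",
                        alpha = 0.05) {
  assert_columns(data, c(group, value), "data")
  df <- tibble::tibble(g = factor(data[[group]]), y = data[[value]])
  counts <- table(df$g)
  if (length(counts) < 2) rlang::abort("need at least two groups")
  if (any(counts < 2)) {
    rlang::abort("every group needs at least two replicates")
  }
  means <- tapply(df$y, df$g, mean)
  sds <- tapply(df$y, df$g, stats::sd)
  pairs_mat <- utils::combn(levels(df$g), 2)

  degenerate <- stats::var(df$y) == 0
  if (degenerate) {
    comparisons <- tibble::tibble(
      a = pairs_mat[1, ], b = pairs_mat[2, ],
      diff = 0, lwr = 0, upr = 0, p_adj = 1, mark = "ns")
    sig <- matrix(FALSE, length(means), length(means),
                  dimnames = list(names(means), names(means)))
    out <- list(
      anova = tibble::tibble(f_statistic = NA_real_,
                             df_between = length(counts) - 1L,
                             df_within = nrow(df) - length(counts),
                             p_value = NA_real_),
      comparisons = comparisons,
      letters = tibble::tibble(group = names(means), mean = as.numeric(means),
                               sd = as.numeric(sds),
                               letters = compact_letters(sig, means)),
      note = "zero variance: F undefined, all comparisons reported ns")
    class(out) <- "tukey_anova"
    return(out)
  }

  fit <- stats::aov(y ~ g, data = df)
  anova_tab <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  pair_names <- rownames(tk)
  comparisons <- tibble::tibble(
    a = sub("-.*$", "", pair_names),
    b = sub("^.*-", "", pair_names),
    diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
    p_adj = tk[, "p adj"]
  ) |>
    dplyr::mutate(mark = dplyr::case_when(
      .data$p_adj < 0.01 ~ "**",
      .data$p_adj < 0.05 ~ "*",
      TRUE ~ "ns"))
  sig <- matrix(FALSE, length(means), length(means),
                dimnames = list(names(means), names(means)))
  for (i in seq_len(nrow(comparisons))) {
    sig[comparisons$a[i], comparisons$b[i]] <-
      sig[comparisons$b[i], comparisons$a[i]] <-
      comparisons$p_adj[i] < alpha
  }
  out <- list(
    anova = tibble::tibble(
      f_statistic = anova_tab[["F value"]][1],
      df_between = anova_tab[["Df"]][1],
      df_within = anova_tab[["Df"]][2],
      p_value = anova_tab[["Pr(>F)"]][1]),
    comparisons = comparisons,
    letters = tibble::tibble(group = names(means), mean = as.numeric(means),
                             sd = as.numeric(sds),
                             letters = compact_letters(sig, means)),
    note = NA_character_)
  class(out) <- "tukey_anova"
  out
}

#' @export
print.tukey_anova <- function(x, ...) {
  cat("One-way ANOVA with Tukey HSD\n")
  if (!is.na(x$note)) cat("note:", x$note, "\n")
  print(x$anova)
  print(x$comparisons)
  invisible(x)
}

#' Tidy a Tukey ANOVA fit
#'
#' @param x A `tukey_anova` object from [anova_tukey()].
#' @param ... Unused.
#' @return `tidy()` returns the pairwise comparison tibble; `glance()` the
#'   one-row ANOVA summary.
#' @export
tidy.tukey_anova <- function(x, ...) x$comparisons

#' @rdname tidy.tukey_anova
#' @export
glance.tukey_anova <- function(x, ...) x$anova
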