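# ggplot2 views of the main result types.

#' Plot amino-acid compositions
#'
#' Grouped bar chart of relative molar amino-acid frequencies, one fill per
#' source, in the style used to compare proteomics-derived compositions
#' with amino-acid analysis and dietary reference profiles.
#'
#' @param comparison A long comparison tibble from [compare_compositions()],
#'   or a single `aa_composition`.
#' @return A ggplot object.
#' @export
plot_aa_composition <- function(comparison) {
  if (inherits(comparison, "aa_composition")) {
    comparison <- dplyr::mutate(
      comparison, source = attr(comparison, "source") %||% "composition")
  }
  assert_columns(comparison, c("aa", "frequency", "source"), "comparison")
  ggplot2::ggplot(comparison,
                  ggplot2::aes(x = .data$aa, y = .data$frequency,
                               fill = .data$source)) +
    ggplot2::geom_col(position = ggplot2::position_dodge2(preserve = "single")) +
    ggplot2::labs(x = "amino acid", y = "relative molar frequency",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.aa_composition <- function(object, ...) plot_aa_composition(object)

#' Plot subcellular compartment distributions
#'
#' Stacked bars of mean compartment fractions per extract (the pooled
#' `intracellular` rows are omitted; they duplicate their constituents).
#'
#' @param distribution Output of [compartment_distribution()].
#' @return A ggplot object.
#' @export
plot_compartment_distribution <- function(distribution) {
  assert_columns(distribution,
                 c("sample_id", "compartment", "mean_fraction"),
                 "distribution")
  d <- dplyr::filter(distribution, .data$compartment != "intracellular")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sample_id,
                                  y = .data$mean_fraction,
                                  fill = .data$compartment)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "extract", y = "relative abundance", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a pairwise correlation report
#'
#' Tile map of Pearson correlation coefficients from [pairwise_pcc()].
#'
#' @param report A correlation report tibble.
#' @return A ggplot object.
#' @export
plot_correlation <- function(report) {
  assert_columns(report, c("a", "b", "pcc"), "report")
  facets <- intersect(c("sample_id", "method", "replicate_id"),
                      names(report))
  p <- ggplot2::ggplot(report, ggplot2::aes(x = .data$a, y = .data$b,
                                            fill = .data$pcc)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$pcc)),
                       size = 3) +
    ggplot2::scale_fill_gradient(limits = c(-1, 1), low = "white",
                                 high = "steelblue") +
    ggplot2::labs(x = NULL, y = NULL, fill = "PCC") +
    ggplot2::theme_minimal()
  if (length(facets) > 0) {
    p <- p + ggplot2::facet_wrap(facets)
  }
  p
}
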