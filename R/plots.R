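#' Plot a permutation null with its observed statistic
#'
#' Histogram of the permutation (or matched-subset) null distribution with
#' the observed statistic as a vertical line — the standard display for the
#' modality-specificity test.
#'
#' @param object A `cpm_permutation`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cpm_permutation <- function(object, bins = 40, ...) {
  df <- tibble::tibble(null = object$null_diffs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed_diff,
                        linewidth = 1, colour = "black") +
    ggplot2::labs(
      x = "null statistic",
      y = "permutations",
      title = sprintf("observed = %.3f, one-tailed p = %.3g",
                      object$observed_diff, object$p)
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of canonical-network contributions
#'
#' Tile plot of the contribution matrix: red cells are over-represented in
#' the high-attention network, blue in the low-attention network; cells
#' significant at the uncorrected threshold are starred.
#'
#' @param object A `cpm_contribution`.
#' @param p_star Significance threshold for the star annotation.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cpm_contribution <- function(object, p_star = 0.05, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$network_a, y = .data$network_b,
                                   fill = .data$contribution)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(
      ggplot2::aes(label = ifelse(!is.na(.data$p) & .data$p < p_star,
                                  "*", "")),
      size = 5) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = "high - low\n(normalized)") +
    ggplot2::theme_minimal()
}

#' Scatter of predicted strength against observed behavior
#'
#' The external-validation display: per-run network strength against the
#' observed behavioral score, with the partial Spearman rho (controlling
#' for motion if given) in the title.
#'
#' @param strength Per-run network strength.
#' @param behavior Observed per-run behavior.
#' @param motion Optional motion covariate for the annotated partial rho.
#' @return A ggplot object.
#' @export
plot_prediction <- function(strength, behavior, motion = NULL) {
  res <- partial_spearman(strength, behavior, motion)
  df <- tibble::tibble(strength = strength, behavior = behavior)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$strength, y = .data$behavior)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey40") +
    ggplot2::labs(
      x = "network strength", y = "observed performance",
      title = sprintf("partial rho = %.3f, p = %.3g (n = %d)",
                      res$rho, res$p, res$n)
    ) +
    ggplot2::theme_minimal()
}
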