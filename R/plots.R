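# ggplot2 displays for the result types. Kept deliberately plain: a curve
# per assembly for FRC, a scree with retention guides for PCA, a kurtosis
# bar chart for ICA.

#' @importFrom ggplot2 autoplot ggplot aes geom_step geom_line geom_point
#'   geom_col geom_hline labs theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot a Feature-Response Curve
#'
#' @param object An `frc_curve` or `frc_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.frc_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$phi, y = .data$coverage)) +
    geom_step() +
    labs(
      x = "feature threshold φ", y = "approximate genome coverage",
      title = attr(object, "label")
    ) +
    theme_minimal()
}

#' @rdname autoplot.frc_curve
#' @export
autoplot.frc_comparison <- function(object, ...) {
  ggplot(object, aes(
    x = .data$phi, y = .data$coverage, colour = .data$label
  )) +
    geom_step() +
    labs(
      x = "feature threshold φ", y = "approximate genome coverage",
      colour = "assembly"
    ) +
    theme_minimal()
}

#' Scree plot with retention guides
#'
#' Eigenvalues in decreasing order with the Kaiser line at 1 and, when an
#' `mp_fit` is supplied, the Marchenko-Pastur upper bulk edge.
#'
#' @param object An `assembly_pca`.
#' @param mp_fit Optional `mp_fit` whose `lambda_plus` is drawn.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.assembly_pca <- function(object, mp_fit = NULL, ...) {
  df <- tidy(object)
  p <- ggplot(df, aes(x = .data$PC, y = .data$eigenvalue)) +
    geom_line() +
    geom_point() +
    geom_hline(yintercept = 1, linetype = "dotted") +
    labs(x = "principal component", y = "eigenvalue") +
    theme_minimal()
  if (!is.null(mp_fit)) {
    p <- p + geom_hline(yintercept = mp_fit$lambda_plus, linetype = "dashed")
  }
  p
}

#' Per-IC kurtosis bar chart
#'
#' @param object An `assembly_ica`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.assembly_ica <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = factor(.data$IC), y = abs(.data$kurtosis))) +
    geom_col() +
    labs(x = "independent component", y = "|excess kurtosis|") +
    theme_minimal()
}
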