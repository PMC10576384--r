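# Convenience ggplot2 figures (data export is the contract; these are
# viewing aids).

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    cea_stop("validation", "ggplot2 is required for plotting")
  }
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param curve A [ceac()] result.
#' @return A ggplot object.
#' @export
plot_ceac <- function(curve) {
  need_ggplot()
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$wtp, y = .data$acceptability,
                                      colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Willingness-to-pay (CAD/QALY)",
                  y = "Probability cost-effective", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the incremental cost-effectiveness scatter with its 95% ellipse
#'
#' @param samples A [run_psa()] result.
#' @param target,reference Strategy names for the pairwise increments.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(samples, target, reference) {
  need_ggplot()
  m <- psa_matrices(samples)
  df <- tibble::tibble(dqaly = m$qaly[, target] - m$qaly[, reference],
                       dcost = m$cost[, target] - m$cost[, reference])
  ell <- confidence_ellipse(samples, target, reference)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dqaly, y = .data$dcost)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.4) +
    ggplot2::geom_path(data = ellipse_points(ell), colour = "red") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = sprintf("Incremental QALYs (%s vs %s)", target, reference),
                  y = "Incremental cost (CAD)") +
    ggplot2::theme_minimal()
}
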