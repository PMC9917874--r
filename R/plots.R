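#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the technical-variability model over its calibration bins
#'
#' Shows the per-bin median SD (open circles) and median CV (filled
#' circles, on a secondary axis scale of percent/100) against the bin
#' midpoint, with the fitted SD curve `sqrt(alpha^2 + beta^2 r^2)` and the
#' implied CV curve `SD(r)/r` overlaid. Requires a model carrying bins
#' (from [fit_noise_model()]); a fixed model can be plotted by attaching
#' bins via the `bins` argument.
#'
#' @param object A `noise_model`.
#' @param bins Optional bin table (defaults to the model's own).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.noise_model <- function(object, bins = object$bins, ...) {
  if (is.null(bins)) stop("no bins to plot; pass `bins`", call. = FALSE)
  grid <- tibble::tibble(r = seq(max(min(bins$r_mid), 1e-3),
                                 max(bins$r_mid), length.out = 200))
  grid$sd <- predict_sd(object, grid$r)
  grid$cv <- grid$sd / grid$r
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$r_mid)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$median_sd), shape = 1) +
    ggplot2::geom_point(ggplot2::aes(y = .data$median_cv / 100), shape = 16) +
    ggplot2::geom_line(data = grid, ggplot2::aes(x = .data$r, y = .data$sd)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(x = .data$r, y = .data$cv),
                       linetype = "dashed") +
    ggplot2::labs(x = "H/L ratio r",
                  y = "median SD (open) / median CV fraction (filled)",
                  title = sprintf(
                    "SD(r) = sqrt(%.3g^2 + %.3g^2 r^2), %s",
                    object$alpha, object$beta, object$source)) +
    ggplot2::theme_minimal()
}

#' Histogram of cross-subject mean half-lives
#'
#' @param halflife_summary Output of [summarize_protein()] on half-lives.
#' @param binwidth Histogram bin width in hours (default 10).
#' @return A ggplot object.
#' @export
plot_halflife_distribution <- function(halflife_summary, binwidth = 10) {
  ggplot2::ggplot(halflife_summary, ggplot2::aes(x = .data$mean)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey70", colour = "grey30") +
    ggplot2::labs(x = "mean half-life (h)", y = "proteins") +
    ggplot2::theme_minimal()
}

#' Temporal versus technical variance of protein abundance
#'
#' Scatter of the steady-state diagnostic on log10 axes with the identity
#' line: points below the line have less temporal spread than peptide
#' disagreement explains, consistent with stationary abundance.
#'
#' @param steady Output of [steady_state_check()].
#' @return A ggplot object.
#' @export
plot_steady_state <- function(steady) {
  ggplot2::ggplot(steady, ggplot2::aes(x = .data$temporal_variance,
                                       y = .data$technical_variance)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "variance across time points",
                  y = "technical (across-peptide) variance") +
    ggplot2::theme_minimal()
}

#' Turnover rate versus abundance, coloured by quadrant
#'
#' @param x Output of [quadrant_classify()] carrying `quadrant` and the
#'   two coordinate columns.
#' @param abundance,k Coordinate columns (tidy-select, unquoted).
#' @return A ggplot object.
#' @export
plot_turnover_quadrants <- function(x, abundance, k) {
  ggplot2::ggplot(x, ggplot2::aes(x = {{ abundance }}, y = {{ k }},
                                  colour = .data$quadrant)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.9) +
    ggplot2::scale_colour_manual(
      values = c("low-k/high-A" = "red", "high-k/high-A" = "blue",
                 "high-k/low-A" = "darkgreen", "low-k/low-A" = "violet"),
      na.value = "grey70") +
    ggplot2::labs(x = "abundance", y = "turnover rate k (1/h)") +
    ggplot2::theme_minimal()
}
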