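#' Plot a fitted greenness spline
#'
#' Observations, the AIC-selected smoothing spline, and the pointwise 90%
#' confidence envelope.
#'
#' @param object A `greenness_spline`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.greenness_spline <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "darkgreen", alpha = 0.15) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed),
                        colour = "grey40", size = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "darkgreen") +
    ggplot2::labs(x = "day", y = "Gcc",
                  title = sprintf("Smoothing spline (edf = %.1f)", object$edf)) +
    ggplot2::theme_minimal()
}

#' Plot a Deming regression fit
#'
#' Scatter of the paired dates with the errors-in-variables regression line
#' and the 1:1 line.
#'
#' @param object A `deming` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.deming <- function(object, ...) {
  b <- object$coefficients
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_abline(slope = b["slope"], intercept = b["intercept"],
                         colour = "firebrick") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "camera transition date (DOY)",
                  y = "satellite transition date (DOY)",
                  title = sprintf(
                    "Deming fit: slope %.2f +/- %.2f (lambda = %g, n = %d)",
                    b["slope"], object$se["slope"], object$lambda, object$n)) +
    ggplot2::theme_minimal()
}

#' Paired-dates scatter by vegetation type and phase
#'
#' A small-multiple scatter of satellite versus camera transition dates,
#' faceted by vegetation type and direction, on the wrapped DOY axis, with
#' the 1:1 line. Points are coloured by apples/oranges representativeness.
#'
#' @param pairs Paired-transition tibble (see [pair_transitions()]); a
#'   `comparison` column is added if missing.
#' @param wrap Wrap DOY values across the year boundary (default TRUE).
#' @return A ggplot object.
#' @export
plot_paired_transitions <- function(pairs, wrap = TRUE) {
  if (!"comparison" %in% names(pairs)) {
    pairs$comparison <- classify_comparison(pairs$roi_veg_type,
                                            pairs$igbp_code)
  }
  if (wrap) {
    pairs$phenocam_doy <- wrap_doy(pairs$phenocam_doy, pairs$direction)
    pairs$modis_doy <- wrap_doy(pairs$modis_doy, pairs$direction)
  }
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$phenocam_doy,
                                      y = .data$modis_doy,
                                      colour = .data$comparison)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_grid(ggplot2::vars(.data$roi_veg_type),
                        ggplot2::vars(.data$direction)) +
    ggplot2::labs(x = "camera transition date (DOY, wrapped)",
                  y = "satellite transition date (DOY, wrapped)",
                  colour = "comparison") +
    ggplot2::theme_minimal()
}
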