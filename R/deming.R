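#' Bias statistics for paired transition dates
#'
#' Mean and sample SD of the camera-satellite date differences, plus the
#' per-source date SDs. The difference is defined as satellite minus camera
#' (`delta = modis_doy - phenocam_doy`): a negative mean bias means the
#' satellite date falls earlier than the camera date.
#'
#' @param pairs Data frame with `phenocam_doy` and `modis_doy` columns
#'   (wrapped or unwrapped; the caller chooses the axis).
#' @return A one-row tibble: `n`, `bias_mean`, `bias_sd`, `sd_phenocam`,
#'   `sd_modis`. SDs use the n-1 divisor and are `NA` when `n < 2`.
#' @export
bias_stats <- function(pairs) {
  d <- pairs$modis_doy - pairs$phenocam_doy
  n <- length(d)
  tibble(n = n,
         bias_mean = if (n) mean(d) else NA_real_,
         bias_sd = if (n >= 2) sd(d) else NA_real_,
         sd_phenocam = if (n >= 2) sd(pairs$phenocam_doy) else NA_real_,
         sd_modis = if (n >= 2) sd(pairs$modis_doy) else NA_real_)
}

# Closed-form Deming slope. lambda is the x:y error-variance ratio
# (sigma_x^2 / sigma_y^2): lambda -> 0 recovers the OLS slope of y on x,
# lambda -> Inf the reciprocal OLS slope of x on y, and the slope increases
# monotonically with lambda in between.
deming_slope <- function(x, y, lambda) {
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  if (sxy == 0) return(NA_real_)
  a <- syy - sxx / lambda
  disc <- sqrt(a^2 + 4 * sxy^2 / lambda)
  if (a >= 0) {
    (a + disc) / (2 * sxy)
  } else {
    # conjugate form avoids cancellation when a is large and negative
    # (extreme lambda): (a + disc) = 4 sxy^2/lambda / (disc - a)
    2 * sxy / (lambda * (disc - a))
  }
}

#' Errors-in-variables (Deming) regression of satellite on camera dates
#'
#' Fits the line relating two measurements that are both subject to error,
#' assuming a known ratio \eqn{\lambda = \sigma_x^2 / \sigma_y^2} of the
#' x to y error variances. With \eqn{\lambda = 1} the fit is orthogonal
#' regression, minimising the summed perpendicular (squared) distances of
#' the points to the line. Slope and intercept standard errors are
#' leave-one-out jackknife estimates; slope t tests against 0 and 1 use
#' those SEs with n - 2 degrees of freedom. Alongside the fit, the Pearson
#' correlation (which does not depend on \eqn{\lambda}), the mean bias, and
#' the RMS perpendicular regression distance with n - 2 degrees of freedom
#' are reported. The fit is flagged `reportable` when the slope differs
#' from 0 at p < 0.05 and n >= 10.
#'
#' @param data Data frame of pairs.
#' @param x,y Column names (unquoted) of the camera and satellite dates;
#'   default `phenocam_doy` and `modis_doy`.
#' @param lambda Error-variance ratio \eqn{\sigma_x^2/\sigma_y^2} (> 0),
#'   default 1.
#' @return An object of class `deming` with components `coefficients`
#'   (`intercept`, `slope`), `se`, `lambda`, `n`, `pearson_r`, `bias`,
#'   `rms_distance`, test statistics, and the data used.
#' @export
#' @examples
#' d <- data.frame(phenocam_doy = c(100, 120, 130),
#'                 modis_doy = c(110, 118, 140))
#' deming_fit(d)
deming_fit <- function(data, x = phenocam_doy, y = modis_doy, lambda = 1) {
  if (lambda <= 0) abort("`lambda` must be > 0")
  xv <- rlang::eval_tidy(rlang::enquo(x), data)
  yv <- rlang::eval_tidy(rlang::enquo(y), data)
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  n <- length(xv)
  if (n < 3L) abort("Deming regression needs at least 3 pairs")
  b1 <- deming_slope(xv, yv, lambda)
  if (is.na(b1)) abort("degenerate input: zero covariance between x and y")
  b0 <- mean(yv) - b1 * mean(xv)

  # leave-one-out jackknife SEs
  jack <- vapply(seq_len(n), function(i) {
    s <- deming_slope(xv[-i], yv[-i], lambda)
    c(s, mean(yv[-i]) - s * mean(xv[-i]))
  }, numeric(2))
  se_slope <- sqrt((n - 1) / n * sum((jack[1, ] - mean(jack[1, ]))^2))
  se_int <- sqrt((n - 1) / n * sum((jack[2, ] - mean(jack[2, ]))^2))

  t0 <- b1 / se_slope
  t1 <- (b1 - 1) / se_slope
  p0 <- 2 * pt(-abs(t0), df = n - 2)
  p1 <- 2 * pt(-abs(t1), df = n - 2)

  structure(
    list(coefficients = c(intercept = b0, slope = b1),
         se = c(intercept = se_int, slope = se_slope),
         lambda = lambda, n = n,
         pearson_r = cor(xv, yv),
         bias = bias_stats(tibble(phenocam_doy = xv, modis_doy = yv)),
         rms_distance = rms_distance(xv, yv, b0, b1),
         t_slope_vs0 = t0, p_slope_vs0 = p0,
         t_slope_vs1 = t1, p_slope_vs1 = p1,
         reportable = (p0 < 0.05) && (n >= 10),
         data = tibble(x = xv, y = yv)),
    class = "deming")
}

#' @export
print.deming <- function(x, ...) {
  cat(sprintf("Deming regression (lambda = %g), n = %d\n", x$lambda, x$n))
  cat(sprintf("  slope     %7.3f +/- %.3f  (p vs 0: %.3g, p vs 1: %.3g)\n",
              x$coefficients["slope"], x$se["slope"],
              x$p_slope_vs0, x$p_slope_vs1))
  cat(sprintf("  intercept %7.3f +/- %.3f\n",
              x$coefficients["intercept"], x$se["intercept"]))
  cat(sprintf("  Pearson r = %.3f, RMS distance = %.2f d, bias = %.2f +/- %.2f d\n",
              x$pearson_r, x$rms_distance,
              x$bias$bias_mean, x$bias$bias_sd))
  if (!x$reportable) {
    cat("  [slope not significantly different from 0 at p < 0.05 with n >= 10;\n")
    cat("   fit would be left blank in a summary table]\n")
  }
  invisible(x)
}

#' Squared perpendicular distance from points to a regression line
#'
#' \deqn{d = (y - (b_0 + b_1 x))^2 / (1 + b_1^2)}
#' — the squared perpendicular distance (units days^2) of each point from
#' the line with intercept `b0` and slope `b1`. Its square root is the
#' geometric point-to-line distance.
#'
#' @param x,y Coordinates (days). Vectorised.
#' @param b0,b1 Line intercept and slope; `b1` must be finite.
#' @return Numeric vector of squared distances.
#' @export
perpendicular_distance <- function(x, y, b0, b1) {
  if (!is.finite(b1)) abort("`b1` must be finite")
  (y - (b0 + b1 * x))^2 / (1 + b1^2)
}

#' RMS perpendicular regression distance
#'
#' Root-mean-square of the perpendicular distances from the points to the
#' regression line, with n - 2 degrees of freedom:
#' \deqn{\sqrt{\sum_i d_i / (n - 2)}}
#' where \eqn{d_i} are the squared distances of
#' [perpendicular_distance()]. The overall regression-error metric reported
#' alongside a Deming fit, in days.
#'
#' @inheritParams perpendicular_distance
#' @return RMS distance in days; `NA` when n <= 2.
#' @export
rms_distance <- function(x, y, b0, b1) {
  n <- length(x)
  if (n <= 2L) return(NA_real_)
  sqrt(sum(perpendicular_distance(x, y, b0, b1)) / (n - 2))
}

#' Tidiers for phenomatch model objects
#'
#' [generics::tidy()] and [generics::glance()] methods in the broom style:
#' `tidy()` returns per-term (or per-observation) rows, `glance()` a
#' one-row model summary.
#'
#' @param x A fitted object (`deming` or `greenness_spline`).
#' @param ... Unused.
#' @name tidiers
NULL

#' @export
#' @rdname tidiers
tidy.deming <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = unname(x$coefficients),
         std.error = unname(x$se),
         statistic = c(x$coefficients["intercept"] / x$se["intercept"],
                       x$t_slope_vs0),
         p.value = c(2 * pt(-abs(x$coefficients["intercept"] / x$se["intercept"]),
                            df = x$n - 2),
                     x$p_slope_vs0))
}

#' @export
#' @rdname tidiers
glance.deming <- function(x, ...) {
  tibble(n = x$n, lambda = x$lambda,
         slope = unname(x$coefficients["slope"]),
         intercept = unname(x$coefficients["intercept"]),
         pearson_r = x$pearson_r, rms_distance = x$rms_distance,
         bias_mean = x$bias$bias_mean, bias_sd = x$bias$bias_sd,
         p_slope_vs0 = x$p_slope_vs0, p_slope_vs1 = x$p_slope_vs1,
         reportable = x$reportable)
}
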