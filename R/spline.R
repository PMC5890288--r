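series_axis <- function(data) {
  if ("date" %in% names(data)) {
    as.numeric(as.Date(data$date))
  } else if ("doy" %in% names(data)) {
    as.numeric(data$doy)
  } else if ("t" %in% names(data)) {
    as.numeric(data$t)
  } else {
    abort("series needs a `date`, `doy`, or `t` column")
  }
}

#' Fit an AIC-selected cubic smoothing spline to a greenness series
#'
#' Fits `stats::smooth.spline` over a declared grid of target equivalent
#' degrees of freedom and keeps the fit minimising
#' \deqn{AIC = n \log(RSS/n) + 2\,edf,}
#' where `edf` is the trace of the smoother matrix. This is the "optimally
#' flexible" spline used for outlier screening and transition-date
#' extraction: flexible enough to track the seasonal trajectory, penalised
#' enough not to chase day-to-day noise.
#'
#' A pointwise 90% confidence envelope is attached, computed from the
#' residual variance and the smoother leverages:
#' `fitted +/- z_0.95 * sqrt(sigma2 * leverage)`.
#'
#' A constant series (zero variance) returns a degenerate fit equal to the
#' constant with a zero-width envelope.
#'
#' @param data Data frame with a `gcc` column and a time axis (`date`,
#'   `doy`, or numeric `t`). At least 10 non-missing observations.
#' @param df_grid Numeric vector of candidate equivalent degrees of freedom;
#'   default `seq(4, min(n_unique - 2, 45), by = 3)`.
#' @return An object of class `greenness_spline`.
#' @export
fit_greenness_spline <- function(data, df_grid = NULL) {
  x <- series_axis(data)
  y <- data$gcc
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  o <- order(x)
  x <- x[o]; y <- y[o]
  n <- length(y)
  if (n < 10L) abort("need at least 10 non-missing observations")
  nx <- length(unique(x))

  if (var(y) < 1e-20) {
    return(new_greenness_spline(
      x = x, y = y, fitted = rep(y[1], n), edf = 1, sigma2 = 0,
      df_selected = 1, aic = -Inf, aic_grid = tibble(),
      lev = rep(1 / n, n), spline = NULL))
  }

  # the candidate flexibility must scale with the span: a seasonal cycle
  # needs roughly the same equivalent dof every year
  span_years <- max(1, (max(x) - min(x)) / 365)
  if (is.null(df_grid)) {
    df_max <- max(6, min(nx - 2, 48 * span_years))
    df_grid <- round(exp(seq(log(4), log(df_max), length.out = 14)))
  }
  df_grid <- sort(unique(pmin(pmax(df_grid, 2), nx - 1)))
  # smooth.spline's default knot count saturates the achievable dof on
  # long series; give it at least twice the largest candidate dof
  nknots <- min(nx, max(ceiling(2.5 * max(df_grid)), 30))

  fits <- lapply(df_grid, function(d) {
    f <- try(smooth.spline(x, y, df = d, keep.data = FALSE,
                           nknots = nknots),
             silent = TRUE)
    if (inherits(f, "try-error")) NULL else f
  })
  keep <- !vapply(fits, is.null, TRUE)
  fits <- fits[keep]; df_grid <- df_grid[keep]
  if (!length(fits)) abort("smoothing spline failed for every candidate df")

  stats_tbl <- dplyr::bind_rows(lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    fit_x <- predict(f, x)$y
    rss <- sum((y - fit_x)^2)
    edf <- f$df
    tibble(df_target = df_grid[i], edf = edf,
           rss = rss, aic = n * log(max(rss, 1e-300) / n) + 2 * edf)
  }))
  best <- which.min(stats_tbl$aic)
  f <- fits[[best]]
  fitted_x <- predict(f, x)$y
  edf <- f$df
  rss <- stats_tbl$rss[best]
  sigma2 <- rss / max(n - edf, 1)
  # leverages on the unique-x grid mapped back to observations
  lev <- f$lev[match(x, f$x)]
  lev[!is.finite(lev)] <- mean(f$lev)

  new_greenness_spline(
    x = x, y = y, fitted = fitted_x, edf = edf, sigma2 = sigma2,
    df_selected = df_grid[best], aic = stats_tbl$aic[best],
    aic_grid = stats_tbl, lev = lev, spline = f)
}

new_greenness_spline <- function(x, y, fitted, edf, sigma2, df_selected,
                                 aic, aic_grid, lev, spline) {
  z <- qnorm(0.95)
  se <- sqrt(pmax(sigma2 * lev, 0))
  structure(
    list(x = x, y = y, fitted = fitted, residuals = y - fitted,
         edf = edf, sigma2 = sigma2, df_selected = df_selected, aic = aic,
         aic_grid = aic_grid, lev = lev, se = se,
         lower = fitted - z * se, upper = fitted + z * se,
         spline = spline, n = length(y)),
    class = "greenness_spline")
}

#' @export
print.greenness_spline <- function(x, ...) {
  cat(sprintf(
    "<greenness_spline> n = %d, edf = %.2f, residual variance = %.3g, AIC = %.2f\n",
    x$n, x$edf, x$sigma2, x$aic))
  invisible(x)
}

#' Predict a fitted greenness spline on a new time axis
#'
#' @param object A `greenness_spline`.
#' @param x Numeric time axis (same units as the fitting axis). Default:
#'   daily grid spanning the fit.
#' @param ... Unused.
#' @return A tibble with `x`, `fitted`, `se`, `lower`, `upper` (pointwise
#'   90% envelope; `se` is interpolated between observation days).
#' @export
predict.greenness_spline <- function(object, x = NULL, ...) {
  if (is.null(x)) x <- seq(min(object$x), max(object$x), by = 1)
  if (is.null(object$spline)) {
    fit <- rep(object$fitted[1], length(x))
    se <- rep(0, length(x))
  } else {
    fit <- predict(object$spline, x)$y
    se <- stats::approx(object$x, object$se, xout = x, rule = 2)$y
  }
  z <- qnorm(0.95)
  tibble(x = x, fitted = fit, se = se,
         lower = fit - z * se, upper = fit + z * se)
}

#' @export
#' @rdname tidiers
tidy.greenness_spline <- function(x, ...) {
  tibble(t = x$x, observed = x$y, fitted = x$fitted,
         residual = x$residuals, se = x$se,
         lower = x$lower, upper = x$upper)
}

#' @export
#' @rdname tidiers
glance.greenness_spline <- function(x, ...) {
  tibble(n = x$n, edf = x$edf, sigma2 = x$sigma2,
         df_selected = x$df_selected, aic = x$aic)
}

#' Iterative spline-based outlier rejection
#'
#' Flags observations whose residual from the current spline exceeds
#' `k` robust standard deviations (1.4826 x median absolute deviation),
#' refits the spline on the retained points, and repeats until no new flags
#' or `max_iter` refits. An absolute deadband `min_abs` prevents flagging
#' in near-noiseless series where the robust scale collapses. If a single
#' pass would flag more than 30% of the points the procedure aborts
#' flagging with a warning — such a fit is considered degenerate, not the
#' data.
#'
#' @param data Series data frame (as for [fit_greenness_spline()]).
#' @param fit Optional initial `greenness_spline`; fitted if omitted.
#' @param k Sigma multiplier (default 3).
#' @param max_iter Maximum refit iterations (default 5).
#' @param min_abs Absolute residual floor below which points are never
#'   flagged (index units, default 0.005).
#' @param df_grid Passed to [fit_greenness_spline()] on refits.
#' @return A list with `series` (cleaned tibble `t`, `gcc`), `fit` (final
#'   spline on the cleaned series), `flags` (tibble `t`, `gcc`, `flagged`),
#'   and `n_iter`.
#' @export
reject_outliers <- function(data, fit = NULL, k = 3, max_iter = 5,
                            min_abs = 0.005, df_grid = NULL) {
  x <- series_axis(data)
  y <- data$gcc
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  o <- order(x); x <- x[o]; y <- y[o]
  cur <- tibble(t = x, gcc = y)
  if (is.null(fit)) fit <- fit_greenness_spline(cur, df_grid = df_grid)
  flagged <- rep(FALSE, length(x))

  for (iter in seq_len(max_iter)) {
    keep_idx <- which(!flagged)
    res <- cur$gcc[keep_idx] - predict(fit, cur$t[keep_idx])$fitted
    sigma <- mad(res)
    if (!is.finite(sigma) || sigma == 0) sigma <- sd(res)
    if (!is.finite(sigma) || sigma == 0) break
    new_flags <- abs(res) > pmax(k * sigma, min_abs)
    if (iter == 1L && mean(new_flags) > 0.30) {
      warn("more than 30% of points would be flagged; aborting outlier rejection")
      flagged[] <- FALSE
      break
    }
    if (!any(new_flags)) break
    flagged[keep_idx[new_flags]] <- TRUE
    fit <- fit_greenness_spline(cur[!flagged, ], df_grid = df_grid)
  }
  list(series = cur[!flagged, ], fit = fit,
       flags = tibble(t = cur$t, gcc = cur$gcc, flagged = flagged),
       n_iter = iter)
}

#' Pick the greenness statistic with the lowest residual variance
#'
#' Given spline fits of the candidate aggregation statistics (mean and the
#' 50th/75th/90th percentiles) for one site x ROI, returns the label of the
#' fit with the smallest residual variance around its spline — the "best"
#' series used for transition-date extraction. Ties are broken by the fixed
#' preference order mean, p90, p75, p50.
#'
#' @param fits Named list of `greenness_spline` objects (>= 2), names being
#'   statistic labels.
#' @return The winning label, with the residual variances attached as the
#'   `"variances"` attribute.
#' @export
select_best_statistic <- function(fits) {
  if (length(fits) < 2L) abort("need at least 2 candidate fits")
  if (is.null(names(fits)) || any(!nzchar(names(fits)))) {
    abort("`fits` must be a named list")
  }
  v <- vapply(fits, function(f) f$sigma2, numeric(1))
  pref <- c("mean", "p90", "p75", "p50")
  ord <- order(v, match(names(fits), pref, nomatch = length(pref) + 1L))
  structure(names(fits)[ord[1L]], variances = v)
}
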