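#' Parse greenness-rising and greenness-falling phases from a spline
#'
#' Applies the in-package PELT changepoint detector to the first differences
#' of the fitted curve on a daily grid, using a Gaussian mean-shift cost;
#' segments are labelled `"rising"`/`"falling"` by the sign of their mean
#' first difference and adjacent same-direction segments are merged. Each
#' phase carries the minimum, maximum and seasonal amplitude of the fitted
#' curve within it.
#'
#' @param fit A `greenness_spline`.
#' @param penalty PELT per-changepoint penalty; default `3 * log(n_diff)`.
#'   The cost is scale-dependent, so the differences are standardised by
#'   their overall SD before segmentation (this leaves transition dates
#'   invariant under affine rescaling of the greenness axis).
#' @param min_seg_len Minimum phase length in days (default 5).
#' @return A tibble with `segment`, `direction`, `start_t`, `end_t`
#'   (time-axis units of the fit), `min`, `max`, `amplitude`.
#' @export
segment_phases <- function(fit, penalty = NULL, min_seg_len = 5L) {
  grid <- predict(fit)
  d <- diff(grid$fitted)
  scale <- sd(d)
  if (!is.finite(scale) || scale == 0) {
    # flat series: a single segment, no transitions
    return(tibble(segment = 1L, direction = "rising",
                  start_t = grid$x[1], end_t = grid$x[length(grid$x)],
                  min = min(grid$fitted), max = max(grid$fitted),
                  amplitude = max(grid$fitted) - min(grid$fitted)))
  }
  if (is.null(penalty)) penalty <- 3 * log(length(d))
  cps <- pelt_changepoints(d / scale, penalty = penalty,
                           min_seg_len = min_seg_len)
  bounds <- c(0L, cps, length(d))
  segs <- dplyr::bind_rows(lapply(seq_len(length(bounds) - 1L), function(i) {
    a <- bounds[i] + 1L; b <- bounds[i + 1L]
    tibble(dir_sign = sign(mean(d[a:b])), day_a = a, day_b = b + 1L)
  }))
  # merge adjacent segments with the same direction label
  segs$direction <- ifelse(segs$dir_sign >= 0, "rising", "falling")
  merged <- list()
  for (i in seq_len(nrow(segs))) {
    m <- length(merged)
    if (m && merged[[m]]$direction == segs$direction[i]) {
      merged[[m]]$day_b <- segs$day_b[i]
    } else {
      merged[[m + 1L]] <- list(direction = segs$direction[i],
                               day_a = segs$day_a[i], day_b = segs$day_b[i])
    }
  }
  # refine each phase boundary to the local extremum of the fitted curve:
  # a rising->falling boundary belongs at the seasonal peak, a
  # falling->rising boundary at the trough. PELT places it where the mean
  # first difference shifts, which can sit a few days down-slope.
  if (length(merged) > 1L) {
    for (i in seq_len(length(merged) - 1L)) {
      a <- (merged[[i]]$day_a + merged[[i]]$day_b) %/% 2L
      b <- (merged[[i + 1L]]$day_a + merged[[i + 1L]]$day_b) %/% 2L
      window <- a:b
      ext <- if (merged[[i]]$direction == "rising") {
        window[which.max(grid$fitted[window])]
      } else {
        window[which.min(grid$fitted[window])]
      }
      merged[[i]]$day_b <- ext
      merged[[i + 1L]]$day_a <- ext
    }
  }
  dplyr::bind_rows(lapply(seq_along(merged), function(i) {
    s <- merged[[i]]
    idx <- s$day_a:s$day_b
    f <- grid$fitted[idx]
    tibble(segment = i, direction = s$direction,
           start_t = grid$x[s$day_a], end_t = grid$x[s$day_b],
           min = min(f), max = max(f), amplitude = max(f) - min(f))
  }))
}

# First threshold crossing within [t_a, t_b] on a daily grid, linear
# interpolation between days. direction "rising" looks for an upcrossing,
# "falling" for a downcrossing. Returns NA if never crossed.
first_crossing <- function(tt, value, level, direction,
                           crossing = c("first", "last")) {
  crossing <- match.arg(crossing)
  if (direction == "rising") {
    hit <- which(value[-length(value)] < level & value[-1] >= level)
  } else {
    hit <- which(value[-length(value)] > level & value[-1] <= level)
  }
  # exact boundary starts: the curve may already sit on the level
  if (!length(hit)) {
    eq <- which(value == level)
    if (length(eq)) return(tt[eq[1]])
    return(NA_real_)
  }
  i <- if (crossing == "first") hit[1] else hit[length(hit)]
  frac <- (level - value[i]) / (value[i + 1] - value[i])
  tt[i] + frac * (tt[i + 1] - tt[i])
}

#' Extract amplitude-threshold transition dates from one phase
#'
#' Within a rising or falling phase, computes the seasonal amplitude as the
#' difference between the phase's plateau and dormant levels of the fitted
#' curve and finds the dates at which the spline crosses
#' `dormant + fraction * amplitude` for each requested fraction, by linear
#' interpolation between daily fitted values. The dormant and plateau
#' levels are robust versions of the phase minimum and maximum: medians of
#' the fitted curve over the lowest and highest tenth of its range within
#' the phase, which do not ride the wiggle extremes of the spline.
#' Phases whose amplitude falls below `min_amplitude` yield no dates — the
#' gate that keeps low-amplitude fluctuations (e.g. a drought year) from
#' producing spurious transitions. 90% confidence bounds come from the
#' crossing dates of the spline's confidence envelope with the same level.
#'
#' @param fit A `greenness_spline`.
#' @param segments Output of [segment_phases()] (or a subset of its rows).
#' @param fractions Amplitude fractions (default `c(0.10, 0.25, 0.50)`).
#' @param min_amplitude Minimum phase amplitude in index units (default
#'   0.02); smaller phases are skipped.
#' @param crossing `"first"` (default) or `"last"` crossing rule.
#' @return A tibble with `segment`, `direction`, `fraction`, `t`,
#'   `ci_lower`, `ci_upper`, `amplitude`, `ci_clipped`.
#' @export
extract_transition_dates <- function(fit, segments,
                                     fractions = c(0.10, 0.25, 0.50),
                                     min_amplitude = 0.02,
                                     crossing = c("first", "last")) {
  crossing <- match.arg(crossing)
  if (any(fractions <= 0 | fractions >= 1)) {
    abort("`fractions` must lie strictly between 0 and 1")
  }
  out <- lapply(seq_len(nrow(segments)), function(i) {
    seg <- segments[i, ]
    grid <- predict(fit, seq(seg$start_t, seg$end_t, by = 1))
    # robust phase levels: the dormant and plateau levels are taken as the
    # median of the fitted curve over the lowest / highest tenth of its
    # range within the phase. The raw pointwise extremes ride the spline's
    # wiggle minima and bias low-threshold dates outward by 1-2 days; the
    # medians are unbiased for curves with flat tails and leave the
    # extraction equivariant under affine rescaling of the greenness axis.
    rng <- seg$max - seg$min
    lo <- median(grid$fitted[grid$fitted <= seg$min + 0.1 * rng])
    hi <- median(grid$fitted[grid$fitted >= seg$max - 0.1 * rng])
    amp <- hi - lo
    if (amp < min_amplitude) return(NULL)
    rows <- lapply(fractions, function(fr) {
      level <- lo + fr * amp
      t0 <- first_crossing(grid$x, grid$fitted, level, seg$direction, crossing)
      if (is.na(t0)) {
        inform(sprintf(
          "threshold %.0f%% never crossed in %s segment %d; omitted",
          100 * fr, seg$direction, seg$segment))
        return(NULL)
      }
      # envelope crossings: the upper curve reaches a rising threshold
      # earlier, the lower curve later (and vice versa when falling)
      c1 <- first_crossing(grid$x, grid$upper, level, seg$direction, crossing)
      c2 <- first_crossing(grid$x, grid$lower, level, seg$direction, crossing)
      clipped <- FALSE
      if (is.na(c1)) { c1 <- seg$start_t; clipped <- TRUE }
      if (is.na(c2)) { c2 <- seg$end_t; clipped <- TRUE }
      ci_lo <- min(c1, c2, t0)
      ci_hi <- max(c1, c2, t0)
      tibble(segment = seg$segment, direction = seg$direction,
             fraction = fr, t = t0, ci_lower = ci_lo, ci_upper = ci_hi,
             amplitude = amp, ci_clipped = clipped)
    })
    dplyr::bind_rows(rows)
  })
  dplyr::bind_rows(out)
}

#' Full transition-date pipeline for one greenness series
#'
#' Convenience wrapper chaining spline fitting with AIC smoothing selection,
#' iterative outlier rejection with refit, PELT phase segmentation, and
#' amplitude-threshold transition-date extraction with 90% confidence
#' intervals. Input with a `date` column is handled on a continuous day
#' axis, so multi-year series and cross-year phases are supported; output
#' dates are reported as real-valued day of year with the year alongside.
#'
#' @param data Series data frame with `gcc` and a `date` (or `doy`/`t`)
#'   column.
#' @param fractions,min_amplitude,crossing Passed to
#'   [extract_transition_dates()].
#' @param k,max_iter Passed to [reject_outliers()].
#' @param penalty,min_seg_len Passed to [segment_phases()].
#' @param df_grid Passed to [fit_greenness_spline()].
#' @param statistic Statistic label recorded in the output (default taken
#'   from a `statistic` column if present, else `"mean"`).
#' @return A tibble with `statistic`, `year`, `direction`, `fraction`,
#'   `doy`, `ci_lower`, `ci_upper`, `amplitude` (doy columns are real-valued
#'   days of year; ci bounds are doys in the same year's axis and may fall
#'   outside `[1, 366]` for cross-year phases).
#' @export
extract_transitions <- function(data, fractions = c(0.10, 0.25, 0.50),
                                min_amplitude = 0.02, k = 3, max_iter = 5,
                                penalty = NULL, min_seg_len = 5L,
                                crossing = "first", df_grid = NULL,
                                statistic = NULL) {
  if (is.null(statistic)) {
    statistic <- if ("statistic" %in% names(data)) {
      as.character(data$statistic[[1]])
    } else "mean"
  }
  has_date <- "date" %in% names(data)
  cleaned <- reject_outliers(data, k = k, max_iter = max_iter,
                             df_grid = df_grid)
  segs <- segment_phases(cleaned$fit, penalty = penalty,
                         min_seg_len = min_seg_len)
  tr <- extract_transition_dates(cleaned$fit, segs, fractions = fractions,
                                 min_amplitude = min_amplitude,
                                 crossing = crossing)
  if (!nrow(tr)) {
    return(tibble(statistic = character(), year = integer(),
                  direction = character(), fraction = double(),
                  doy = double(), ci_lower = double(), ci_upper = double(),
                  amplitude = double()))
  }
  if (has_date) {
    dt <- as.Date(floor(tr$t), origin = "1970-01-01")
    yr <- as.integer(format(dt, "%Y"))
    origin <- as.numeric(year_origin(yr))
    tibble(statistic = statistic, year = yr, direction = tr$direction,
           fraction = tr$fraction, doy = tr$t - origin + 1,
           ci_lower = tr$ci_lower - origin + 1,
           ci_upper = tr$ci_upper - origin + 1,
           amplitude = tr$amplitude)
  } else {
    tibble(statistic = statistic, year = NA_integer_,
           direction = tr$direction, fraction = tr$fraction, doy = tr$t,
           ci_lower = tr$ci_lower, ci_upper = tr$ci_upper,
           amplitude = tr$amplitude)
  }
}
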