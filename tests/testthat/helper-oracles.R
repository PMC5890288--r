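# Independent oracles used across the suite. None of these share code with
# the package implementation.

# Solar position by the Spencer (1971) Fourier series for declination and
# the equation of time -- an algorithm family distinct from the package's
# NOAA-style Meeus series. Accuracy ~0.3 degrees.
spencer_solar_elevation <- function(time, latitude, longitude) {
  stopifnot(inherits(time, "POSIXct"))
  lt <- as.POSIXlt(time, tz = "UTC")
  doy <- lt$yday + 1
  frac_hour <- lt$hour + lt$min / 60 + lt$sec / 3600
  gam <- 2 * pi / 365 * (doy - 1 + (frac_hour - 12) / 24)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(gam) - 0.032077 * sin(gam) -
                        0.014615 * cos(2 * gam) - 0.040849 * sin(2 * gam))
  decl <- 0.006918 - 0.399912 * cos(gam) + 0.070257 * sin(gam) -
    0.006758 * cos(2 * gam) + 0.000907 * sin(2 * gam) -
    0.002697 * cos(3 * gam) + 0.00148 * sin(3 * gam)
  tst <- frac_hour * 60 + eqtime + 4 * longitude
  ha <- (tst / 4 - 180) * pi / 180
  lat <- latitude * pi / 180
  asin(sin(lat) * sin(decl) + cos(lat) * cos(decl) * cos(ha)) * 180 / pi
}

# Dense-grid bisection for threshold crossings of a noiseless curve.
bisect_threshold_dates <- function(params, fractions, tol = 1e-4) {
  f <- function(t) seasonal_curve(params, t)
  tt <- seq(1, 365, by = 0.25)
  v <- f(tt)
  peak_i <- which.max(v)
  amp <- v[peak_i] - params$baseline
  out <- NULL
  for (fr in fractions) {
    level <- params$baseline + fr * amp
    for (dir in c("rising", "falling")) {
      if (dir == "rising") {
        rng <- c(1, tt[peak_i])
      } else {
        rng <- c(tt[peak_i], 365)
      }
      lo <- rng[1]; hi <- rng[2]
      while (hi - lo > tol) {
        mid <- (lo + hi) / 2
        below <- f(mid) < level
        if ((dir == "rising") == below) lo <- mid else hi <- mid
      }
      out <- rbind(out, data.frame(direction = dir, fraction = fr,
                                   doy = (lo + hi) / 2))
    }
  }
  out
}

# Type-7 quantile by explicit sorting and interpolation.
sort_quantile_oracle <- function(x, p) {
  xs <- sort(x)
  h <- (length(x) - 1) * p
  lo <- floor(h)
  xs[lo + 1] + (h - lo) * (xs[pmin(lo + 2, length(x))] - xs[lo + 1])
}

# Geometric point-to-line distance (not squared).
point_line_distance <- function(x, y, b0, b1) {
  abs(y - (b0 + b1 * x)) / sqrt(1 + b1^2)
}

ols_slope <- function(x, y) sum((x - mean(x)) * (y - mean(y))) /
  sum((x - mean(x))^2)

# Numeric minimiser of the summed squared perpendicular distances. For any
# slope the optimal intercept is the OLS one (the 1/(1+b1^2) factor does
# not involve b0), so the search is one-dimensional in the slope.
orthogonal_fit_optim <- function(x, y) {
  obj <- function(b1) {
    b0 <- mean(y) - b1 * mean(x)
    sum((y - (b0 + b1 * x))^2 / (1 + b1^2))
  }
  b1s <- ols_slope(x, y)
  o <- stats::optimize(obj, c(b1s - 2 * abs(b1s) - 1, b1s + 2 * abs(b1s) + 1),
                       tol = 1e-12)
  list(intercept = mean(y) - o$minimum * mean(x), slope = o$minimum,
       value = o$objective)
}

# Shared fixture: one clean synthetic site-year and its truth.
make_test_scene <- function(years = 2018L, ...) {
  scene_truth(cycles = cycle_params(...), years = years)
}

# Camera/satellite paired cohort at the generator's study conditions.
run_intercomparison_cohort <- function(seed, n_sites = 10, years = 2014:2018) {
  truths <- cohort_scene_truths(n_sites, years, seed = seed)
  cam <- dplyr::bind_rows(lapply(truths, function(tr) {
    ser <- simulate_camera_series(tr, noise_sd = 0.005, outlier_rate = 0.02,
                                  seed = seed + 7919L)
    out <- suppressMessages(extract_transitions(ser))
    out$site_id <- tr$site_id
    out$roi_veg_type <- tr$roi_veg_type
    out[out$fraction == 0.1, ]
  }))
  sat <- dplyr::bind_rows(lapply(seq_along(truths), function(i) {
    tr <- truths[[i]]
    sim <- simulate_satellite_series(tr, date_jitter_sd = 5,
                                     seed = seed + 104729L + i)
    sim$transitions$site_id <- tr$site_id
    sim$transitions
  }))
  suppressMessages(pair_transitions(cam, sat))
}
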