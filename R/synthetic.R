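#' Seasonal cycle parameters for a double-logistic greenness curve
#'
#' A seasonal greenness (or NDVI) trajectory is modelled as a product of two
#' logistic transitions on top of a dormant-season baseline:
#' \deqn{g(t) = b + A \cdot \sigma(r_u (t - m_u)) \cdot \sigma(-r_d (t - m_d))}
#' where \eqn{\sigma} is the logistic function, \eqn{m_u < m_d} are the
#' rising and falling midpoints (day of year) and \eqn{r_u, r_d > 0} the
#' corresponding rates. This double-sigmoid is the standard generative shape
#' for land-surface phenology simulation: flat dormancy, a spring rise, a
#' midsummer plateau near \eqn{b + A}, and an autumn decline.
#'
#' @param baseline Dormant-season index value (dimensionless, typically
#'   0.30--0.35 for camera greenness).
#' @param amplitude Seasonal amplitude in index units; must be positive.
#' @param rising_midpoint Day of year of the spring inflection (50% rise).
#' @param rising_rate Logistic rate of the spring rise, 1/day, positive.
#' @param falling_midpoint Day of year of the autumn inflection; must exceed
#'   `rising_midpoint`.
#' @param falling_rate Logistic rate of the autumn decline, 1/day, positive.
#'
#' @return An object of class `cycle_params` (a named list).
#' @export
#' @examples
#' cp <- cycle_params()
#' seasonal_curve(cp, c(1, 130, 200, 365))
cycle_params <- function(baseline = 0.33, amplitude = 0.12,
                         rising_midpoint = 130, rising_rate = 0.12,
                         falling_midpoint = 270, falling_rate = 0.10) {
  vals <- c(baseline, amplitude, rising_midpoint, rising_rate,
            falling_midpoint, falling_rate)
  if (!all(is.finite(vals))) {
    abort("all cycle parameters must be finite numbers")
  }
  if (amplitude <= 0) abort("`amplitude` must be > 0")
  if (rising_rate <= 0 || falling_rate <= 0) abort("rates must be > 0")
  if (rising_midpoint >= falling_midpoint) {
    abort("`rising_midpoint` must precede `falling_midpoint`")
  }
  structure(
    list(baseline = baseline, amplitude = amplitude,
         rising_midpoint = rising_midpoint, rising_rate = rising_rate,
         falling_midpoint = falling_midpoint, falling_rate = falling_rate),
    class = "cycle_params"
  )
}

#' @export
print.cycle_params <- function(x, ...) {
  cat(sprintf(
    "<cycle_params> baseline %.3f, amplitude %.3f, rise %.1f (rate %.3f), fall %.1f (rate %.3f)\n",
    x$baseline, x$amplitude, x$rising_midpoint, x$rising_rate,
    x$falling_midpoint, x$falling_rate))
  invisible(x)
}

# Amplitude term of one cycle (no baseline), vectorised over t.
cycle_term <- function(params, t) {
  params$amplitude *
    stats::plogis(params$rising_rate * (t - params$rising_midpoint)) *
    stats::plogis(-params$falling_rate * (t - params$falling_midpoint))
}

as_cycle_list <- function(cycles) {
  if (inherits(cycles, "cycle_params")) cycles <- list(cycles)
  if (!length(cycles) || !all(vapply(cycles, inherits, TRUE, "cycle_params"))) {
    abort("`cycles` must be a cycle_params object or a list of them")
  }
  base <- vapply(cycles, `[[`, numeric(1), "baseline")
  if (length(cycles) > 1L) {
    if (max(base) - min(base) > 1e-12) {
      abort("multiple cycles within one season must share a baseline")
    }
    # refuse overlapping cycles: each cycle's support is taken as the span
    # where its logistic factors are materially away from 0
    lo <- vapply(cycles, function(p) p$rising_midpoint - 8 / p$rising_rate, 0)
    hi <- vapply(cycles, function(p) p$falling_midpoint + 8 / p$falling_rate, 0)
    o <- order(lo)
    if (any(hi[o][-length(o)] > lo[o][-1L])) {
      abort("cycles overlap; supply non-overlapping cycle_params")
    }
  }
  cycles
}

#' Evaluate a seasonal double-sigmoid greenness curve
#'
#' Evaluates the noiseless seasonal trajectory defined by one or more
#' [cycle_params()] at days `t`. Several cycles (e.g. a bimodal grassland
#' season) are summed over a shared baseline; overlapping cycles are refused.
#'
#' @param cycles A `cycle_params` object or a list of non-overlapping ones
#'   sharing a baseline.
#' @param t Numeric vector of (fractional) days of year.
#' @return Numeric vector of index values in `[baseline, baseline + amplitude]`.
#' @export
seasonal_curve <- function(cycles, t) {
  cycles <- as_cycle_list(cycles)
  if (!is.numeric(t) || !all(is.finite(t))) abort("`t` must be finite numeric")
  cycles[[1L]]$baseline +
    Reduce(`+`, lapply(cycles, cycle_term, t = t))
}

# Peak value and location of a curve function over [lo, hi].
curve_peak <- function(f, lo, hi) {
  opt <- optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-8)
  list(t = opt$maximum, value = opt$objective)
}

# Threshold-crossing dates of an arbitrary unimodal pulse via root finding.
# f: function of t; searched between t_lo < t_peak < t_hi.
pulse_threshold_dates <- function(f, t_lo, t_hi, baseline, fractions) {
  pk <- curve_peak(f, t_lo, t_hi)
  amp <- pk$value - baseline
  out <- lapply(fractions, function(fr) {
    level <- baseline + fr * amp
    g <- function(t) f(t) - level
    rising <- uniroot(g, c(t_lo, pk$t), tol = 1e-9)$root
    falling <- uniroot(g, c(pk$t, t_hi), tol = 1e-9)$root
    tibble(direction = c("rising", "falling"),
           fraction = fr, doy = c(rising, falling))
  })
  dplyr::bind_rows(out)
}

#' Analytic threshold-crossing dates of a noiseless seasonal curve
#'
#' For each amplitude fraction, finds the day the noiseless curve first rises
#' through `baseline + fraction * amplitude` (rising) and later falls back
#' through it (falling), by root finding on the exact curve. The amplitude is
#' the curve's realised peak minus the baseline (for steep cycles this equals
#' the nominal amplitude to numerical precision).
#'
#' @inheritParams seasonal_curve
#' @param fractions Amplitude fractions strictly between 0 and 1.
#' @return A tibble with columns `cycle`, `direction` (`"rising"`/`"falling"`),
#'   `fraction`, and real-valued `doy`.
#' @export
#' @examples
#' true_threshold_dates(cycle_params(), fractions = c(0.1, 0.25, 0.5))
true_threshold_dates <- function(cycles, fractions = c(0.10, 0.25, 0.50)) {
  cycles <- as_cycle_list(cycles)
  if (any(fractions <= 0 | fractions >= 1)) {
    abort("`fractions` must lie strictly between 0 and 1")
  }
  out <- lapply(seq_along(cycles), function(i) {
    p <- cycles[[i]]
    f <- function(t) p$baseline + cycle_term(p, t)
    d <- pulse_threshold_dates(
      f,
      t_lo = p$rising_midpoint - 15 / p$rising_rate,
      t_hi = p$falling_midpoint + 15 / p$falling_rate,
      baseline = p$baseline, fractions = fractions)
    d$cycle <- i
    d
  })
  dplyr::bind_rows(out)[, c("cycle", "direction", "fraction", "doy")]
}

# Default NDVI cycle for a vegetation component, loosely keyed to habit:
# deciduous types have large NDVI amplitude, evergreen a high baseline.
default_ndvi_cycle <- function(veg_type, gcc_cycle) {
  switch(veg_type,
    EN = cycle_params(baseline = 0.55, amplitude = 0.25,
                      rising_midpoint = gcc_cycle$rising_midpoint,
                      rising_rate = gcc_cycle$rising_rate,
                      falling_midpoint = gcc_cycle$falling_midpoint,
                      falling_rate = gcc_cycle$falling_rate),
    cycle_params(baseline = 0.30, amplitude = 0.45,
                 rising_midpoint = gcc_cycle$rising_midpoint,
                 rising_rate = gcc_cycle$rising_rate,
                 falling_midpoint = gcc_cycle$falling_midpoint,
                 falling_rate = gcc_cycle$falling_rate)
  )
}

default_igbp <- function(veg_type) {
  switch(veg_type, AG = 12L, DB = 4L, EN = 1L, GR = 10L, SH = 7L,
         abort(sprintf("unknown vegetation type '%s'", veg_type)))
}

#' Ground truth for one synthetic camera scene
#'
#' Bundles everything needed to simulate a coupled camera/satellite scene
#' with known answers: the camera-greenness seasonal cycles per year, the
#' per-component satellite NDVI cycles, sub-pixel mixture weights for a
#' 3x3 satellite pixel window, IGBP landcover codes, and the analytic
#' threshold-crossing dates of the noiseless curves.
#'
#' The 3x3 window is stored row-major, pixel 5 being the centre (camera)
#' pixel. `mixture_weights` is a 9 x K matrix: each row gives the convex
#' weights with which the K component vegetation signals mix within that
#' pixel; component 1 is the camera's own vegetation.
#'
#' @param site_id Site identifier string.
#' @param latitude,longitude Site coordinates in degrees.
#' @param roi_veg_type Camera ROI vegetation code: one of
#'   `"AG"`, `"DB"`, `"EN"`, `"GR"`, `"SH"`.
#' @param years Integer vector of simulated calendar years.
#' @param cycles Camera Gcc cycles: a single `cycle_params` (recycled across
#'   years), or a list of per-year entries, each a `cycle_params` or a list
#'   of non-overlapping ones.
#' @param ndvi_cycles Either a list of K per-component NDVI `cycle_params`
#'   (recycled across years) or a per-year list of such component lists.
#'   Default: one component per year tracking that year's camera cycle.
#' @param mixture_weights 9 x K matrix of convex weights; default is a pure
#'   single-component landscape.
#' @param igbp_codes Integer vector of 9 IGBP codes (NA = masked); default is
#'   the ROI type's canonical code everywhere.
#' @param fractions Amplitude fractions for the stored true dates.
#' @return An object of class `scene_truth`.
#' @export
scene_truth <- function(site_id = "synthsite", latitude = 45, longitude = -72,
                        roi_veg_type = c("DB", "AG", "EN", "GR", "SH"),
                        years = 2018L,
                        cycles = cycle_params(),
                        ndvi_cycles = NULL,
                        mixture_weights = NULL,
                        igbp_codes = NULL,
                        fractions = c(0.10, 0.25, 0.50)) {
  roi_veg_type <- match.arg(roi_veg_type)
  years <- as.integer(years)
  if (inherits(cycles, "cycle_params") ||
      all(vapply(cycles, inherits, TRUE, "cycle_params"))) {
    if (inherits(cycles, "cycle_params")) {
      cycles <- rep(list(cycles), length(years))
    } else if (length(cycles) != length(years)) {
      cycles <- rep(cycles, length.out = length(years))
    }
  }
  if (length(cycles) != length(years)) {
    abort("`cycles` must supply one entry per year")
  }
  cycles <- lapply(cycles, as_cycle_list)
  names(cycles) <- as.character(years)

  # NDVI components per year: each year's satellite signal tracks that
  # year's camera phenology unless the caller supplies explicit cycles
  if (is.null(ndvi_cycles)) {
    ndvi_cycles <- lapply(cycles, function(cyc) {
      list(default_ndvi_cycle(roi_veg_type, cyc[[1L]]))
    })
  } else if (all(vapply(ndvi_cycles, inherits, TRUE, "cycle_params"))) {
    ndvi_cycles <- stats::setNames(
      rep(list(ndvi_cycles), length(years)), as.character(years))
  }
  if (length(ndvi_cycles) != length(years)) {
    abort("`ndvi_cycles` must be K cycle_params or one component list per year")
  }
  names(ndvi_cycles) <- as.character(years)
  k <- length(ndvi_cycles[[1L]])
  if (is.null(mixture_weights)) {
    mixture_weights <- matrix(0, 9, k)
    mixture_weights[, 1L] <- 1
  }
  mixture_weights <- as.matrix(mixture_weights)
  if (!identical(dim(mixture_weights), c(9L, k))) {
    abort("`mixture_weights` must be a 9 x K matrix matching `ndvi_cycles`")
  }
  if (any(mixture_weights < 0) ||
      any(abs(rowSums(mixture_weights) - 1) > 1e-8)) {
    abort("each pixel's mixture weights must be >= 0 and sum to 1")
  }
  if (is.null(igbp_codes)) igbp_codes <- rep(default_igbp(roi_veg_type), 9L)
  if (length(igbp_codes) != 9L) abort("`igbp_codes` must have length 9")

  true_dates <- dplyr::bind_rows(lapply(as.character(years), function(yr) {
    d <- true_threshold_dates(cycles[[yr]], fractions)
    d$year <- as.integer(yr)
    d
  }))

  structure(
    list(site_id = site_id, latitude = latitude, longitude = longitude,
         roi_veg_type = roi_veg_type, igbp_center = igbp_codes[[5L]],
         years = years, cycles = cycles, ndvi_cycles = ndvi_cycles,
         mixture_weights = mixture_weights, igbp_codes = as.integer(igbp_codes),
         fractions = fractions,
         true_dates = true_dates[, c("year", "cycle", "direction",
                                     "fraction", "doy")]),
    class = "scene_truth"
  )
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("<scene_truth> %s (%s), %d year(s), %d NDVI component(s)\n",
              x$site_id, x$roi_veg_type, length(x$years),
              length(x$ndvi_cycles)))
  invisible(x)
}

year_origin <- function(year) as.Date(sprintf("%d-01-01", year))

#' Simulate a daily camera greenness series
#'
#' Evaluates the scene's noiseless Gcc curve daily, adds iid Gaussian noise,
#' and injects sparse negative-biased outliers emulating cloud-, fog- or
#' snow-contaminated images (downward spikes of uniform magnitude
#' 0.02--0.10 index units). Reproducible under a fixed seed.
#'
#' @param truth A [scene_truth()] object.
#' @param noise_sd Gaussian noise SD in index units (>= 0).
#' @param outlier_rate Per-day outlier probability in `[0, 0.2)`.
#' @param seed Integer seed; the generator restores the RNG state afterwards.
#' @return A tibble with columns `site_id`, `date`, `year`, `doy`,
#'   `statistic` (`"mean"`), `gcc`, and the truth flag `is_outlier`.
#' @export
simulate_camera_series <- function(truth, noise_sd = 0.005,
                                   outlier_rate = 0.02, seed = 1L) {
  stopifnot(inherits(truth, "scene_truth"))
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  if (outlier_rate < 0 || outlier_rate >= 0.2) {
    abort("`outlier_rate` must be in [0, 0.2)")
  }
  withr::with_seed(seed, {
    dplyr::bind_rows(lapply(truth$years, function(yr) {
      ndays <- if (is_leap(yr)) 366L else 365L
      doy <- seq_len(ndays)
      g <- seasonal_curve(truth$cycles[[as.character(yr)]], doy)
      g <- g + rnorm(ndays, 0, noise_sd)
      out <- runif(ndays) < outlier_rate
      g[out] <- g[out] - runif(sum(out), 0.02, 0.10)
      tibble(site_id = truth$site_id,
             date = year_origin(yr) + doy - 1L,
             year = yr, doy = doy, statistic = "mean",
             gcc = g, is_outlier = out)
    }))
  })
}

is_leap <- function(year) {
  (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
}

# NDVI mixture signal of one pixel as a function of doy, for a given year.
pixel_mixture_fun <- function(truth, pixel, year) {
  w <- truth$mixture_weights[pixel, ]
  comps <- truth$ndvi_cycles[[as.character(year)]]
  function(t) {
    Reduce(`+`, Map(function(wk, p) {
      wk * (p$baseline + cycle_term(p, t))
    }, w, comps))
  }
}

#' Simulate a 3x3-window satellite NDVI record with known transition dates
#'
#' Each pixel's NDVI is the convex mixture of the scene's component NDVI
#' signals (sub-pixel landscape heterogeneity), sampled every `step` days as
#' 16-day-composite-style values, with Gaussian noise. Red/NIR reflectances
#' consistent with each NDVI value are synthesised under a fixed band sum.
#' Satellite transition dates are the analytic threshold crossings of the
#' noiseless centre-pixel mixture plus Gaussian jitter, emulating an
#' MCD12Q2-style greenup-onset / dormancy-onset product.
#'
#' @param truth A [scene_truth()] object.
#' @param step Composite interval in days (default 16); each value carries
#'   the date of its period's first day.
#' @param noise_sd NDVI noise SD.
#' @param date_jitter_sd SD (days) of the jitter added to the true dates.
#' @param fractions Named amplitude fractions defining the satellite dates,
#'   `c(rising = ..., falling = ...)`.
#' @param band_sum Red + NIR reflectance total used to synthesise bands.
#' @param seed Integer seed.
#' @return A list with `series` (tibble: `pixel_row`, `pixel_col`, `date`,
#'   `year`, `doy`, `band1`, `band2`, `ndvi`) and `transitions` (tibble:
#'   `year`, `direction`, `doy`, `igbp_code`).
#' @export
simulate_satellite_series <- function(truth, step = 16L, noise_sd = 0.02,
                                      date_jitter_sd = 5,
                                      fractions = c(rising = 0.1, falling = 0.1),
                                      band_sum = 0.6, seed = 1L) {
  stopifnot(inherits(truth, "scene_truth"))
  pix <- expand.grid(pixel_row = 1:3, pixel_col = 1:3)
  withr::with_seed(seed, {
    series <- dplyr::bind_rows(lapply(truth$years, function(yr) {
      doy <- seq(1L, 365L, by = step)
      dplyr::bind_rows(lapply(seq_len(9L), function(p) {
        f <- pixel_mixture_fun(truth, p, yr)
        nd <- f(doy) + rnorm(length(doy), 0, noise_sd)
        nd <- pmin(pmax(nd, -1), 1)
        tibble(pixel_row = pix$pixel_row[p], pixel_col = pix$pixel_col[p],
               date = year_origin(yr) + doy - 1L, year = yr, doy = doy,
               band1 = band_sum * (1 - nd) / 2,
               band2 = band_sum * (1 + nd) / 2,
               ndvi = nd)
      }))
    }))
    transitions <- dplyr::bind_rows(lapply(truth$years, function(yr) {
      ctr <- pixel_mixture_fun(truth, 5L, yr)
      comps <- truth$ndvi_cycles[[as.character(yr)]]
      base <- ctr(1)  # dormant-season mixture level
      d <- pulse_threshold_dates(
        ctr,
        t_lo = min(vapply(comps, function(p)
          p$rising_midpoint - 15 / p$rising_rate, 0)),
        t_hi = max(vapply(comps, function(p)
          p$falling_midpoint + 15 / p$falling_rate, 0)),
        baseline = base,
        fractions = unique(unname(fractions)))
      d <- d[(d$direction == "rising" &
                d$fraction == fractions[["rising"]]) |
             (d$direction == "falling" &
                d$fraction == fractions[["falling"]]), ]
      tibble(year = yr, direction = d$direction,
             doy = d$doy + rnorm(nrow(d), 0, date_jitter_sd),
             igbp_code = truth$igbp_center)
    }))
    list(series = series, transitions = transitions)
  })
}

#' Generate a cohort of synthetic scenes with realistic phenology spread
#'
#' Draws `n_sites` scene truths whose seasonal cycles vary the way a
#' continental camera network's do: site mean spring midpoints spread with
#' SD ~20 d around day 130 and autumn midpoints around day 270, seasonal
#' amplitudes between 0.08 and 0.15 index units, logistic rates between
#' 0.06 and 0.15 per day, and year-to-year anomalies of SD 8 d within each
#' site. Vegetation types rotate through AG, DB, EN, GR. The spread matters
#' for intercomparison statistics: correlations between camera and
#' satellite dates are driven by the across-site-year date variance
#' relative to the per-date errors.
#'
#' @param n_sites Number of sites.
#' @param years Integer vector of years simulated at every site.
#' @param seed Integer seed (RNG state restored afterwards).
#' @return A list of [scene_truth()] objects.
#' @export
cohort_scene_truths <- function(n_sites = 10, years = 2014:2018, seed = 1L) {
  withr::with_seed(seed, {
    lapply(seq_len(n_sites), function(i) {
      veg <- c("AG", "DB", "EN", "GR")[(i - 1L) %% 4L + 1L]
      rise_mu <- rnorm(1, 130, 20)
      fall_mu <- rnorm(1, 270, 20)
      if (fall_mu - rise_mu < 60) fall_mu <- rise_mu + 60
      site_baseline <- runif(1, 0.30, 0.35)  # a camera property, not a year's
      cyc <- lapply(years, function(yr) {
        shift <- rnorm(1, 0, 8)
        cycle_params(
          baseline = site_baseline,
          amplitude = runif(1, 0.08, 0.15),
          rising_midpoint = rise_mu + shift,
          rising_rate = runif(1, 0.08, 0.15),
          falling_midpoint = fall_mu + shift,
          falling_rate = runif(1, 0.06, 0.12))
      })
      scene_truth(site_id = sprintf("synthsite%02d", i),
                  latitude = runif(1, 30, 55), longitude = runif(1, -120, -65),
                  roi_veg_type = veg, years = years, cycles = cyc)
    })
  })
}

#' Render a flat-colour PNG and ROI mask to exercise the image reader
#'
#' Writes a `width` x `height` image of a single RGB colour, and optionally
#' a binary ROI mask (non-zero = inside ROI), as PNG files. This is a
#' test fixture generator, not a scene renderer.
#'
#' @param path Output PNG path.
#' @param rgb Numeric length-3 colour as digital numbers in `[0, 255]`.
#' @param width,height Image dimensions in pixels.
#' @return `path`, invisibly.
#' @export
render_flat_image <- function(path, rgb = c(92, 118, 70),
                              width = 16L, height = 12L) {
  arr <- array(rep(rgb / 255, each = width * height),
               dim = c(height, width, 3L))
  png::writePNG(arr, path)
  invisible(path)
}
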