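daily_series <- function(cp, years = 2018L, noise_sd = 0, outlier_rate = 0,
                         seed = 1L) {
  simulate_camera_series(scene_truth(cycles = cp, years = years),
                         noise_sd = noise_sd, outlier_rate = outlier_rate,
                         seed = seed)
}

test_that("the AIC spline tracks a noiseless seasonal curve to 1e-3", {
  cp <- cycle_params()
  ser <- daily_series(cp)
  fit <- fit_greenness_spline(ser)
  expect_lt(max(abs(fit$fitted - ser$gcc)), 1e-3)
  # winner's AIC is the grid minimum, by exhaustive comparison
  expect_true(all(min(fit$aic_grid$aic) == fit$aic))
  expect_true(all(fit$aic >= min(fit$aic_grid$aic)))
  # envelope contains the fit and edf lies in (1, n)
  expect_true(all(fit$lower <= fit$fitted & fit$fitted <= fit$upper))
  expect_gt(fit$edf, 1); expect_lt(fit$edf, fit$n)
})

test_that("a constant series yields a constant fit with zero residual variance", {
  const <- tibble::tibble(t = 1:50, gcc = 0.35)
  fit <- fit_greenness_spline(const)
  expect_equal(fit$fitted, rep(0.35, 50))
  expect_equal(fit$sigma2, 0)
  expect_equal(predict(fit, c(10.5, 20.5))$fitted, c(0.35, 0.35))
  expect_error(fit_greenness_spline(tibble::tibble(t = 1:5, gcc = runif(5))),
               "at least 10")
})

test_that("outlier rejection flags an injected spike and is idempotent", {
  cp <- cycle_params()
  ser <- daily_series(cp, noise_sd = 0.003, seed = 4L)
  # clean series: nothing flagged
  clean <- reject_outliers(ser)
  expect_equal(sum(clean$flags$flagged), 0)
  # one 10x-noise-SD spike is flagged, and only it
  spiked <- ser
  spiked$gcc[180] <- spiked$gcc[180] - 0.03
  res <- reject_outliers(spiked)
  expect_equal(which(res$flags$flagged), 180L)
  # fixed point: rerunning on the cleaned output flags nothing
  again <- reject_outliers(res$series)
  expect_equal(sum(again$flags$flagged), 0)
})

test_that("outlier rejection refuses to flag more than 30% of a series", {
  set.seed(5)
  wild <- tibble::tibble(t = 1:60, gcc = runif(60, 0, 1))
  expect_warning(res <- reject_outliers(wild, k = 0.1, min_abs = 0),
                 "30%")
  expect_equal(sum(res$flags$flagged), 0)
})

test_that("PELT finds no changepoint in a monotone series and the apex of a triangle", {
  fit <- fit_greenness_spline(tibble::tibble(t = 1:60,
                                             gcc = 0.3 + 0.002 * (1:60)))
  segs <- segment_phases(fit)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$direction, "rising")
  tri <- c(seq(0.30, 0.40, length.out = 50), seq(0.40, 0.30, length.out = 50)[-1])
  cps <- pelt_changepoints(diff(tri) / sd(diff(tri)))
  expect_length(cps, 1)
  expect_lte(abs(cps - 49), 1)
})

test_that("PELT equals the exhaustive dynamic-programming oracle on random series", {
  set.seed(17)
  for (i in 1:30) {
    n <- sample(8:30, 1)
    ncp <- sample(0:2, 1)
    breaks <- sort(c(0, sample(seq(2, n - 2), ncp), n))
    mu <- unlist(lapply(seq_len(length(breaks) - 1), function(j) {
      rep(rnorm(1, 0, 3), breaks[j + 1] - breaks[j])
    }))
    x <- mu + rnorm(n)
    pen <- runif(1, 1, 8)
    expect_identical(pelt_changepoints(x, penalty = pen),
                     optimal_partition_dp(x, penalty = pen))
  }
})

test_that("PELT pruning stays exact under a minimum segment length", {
  # regression case: immediate pruning discards a candidate whose dominator
  # is not yet usable as a changepoint, returning a suboptimal segmentation
  x <- c(1.80266723311299, 1.463647731249, 2.06510071218959,
         3.38905414239213, 2.3220405670971, 0.346570583067181,
         2.13604855570663, 2.93923899660528, 0.868975126464683,
         -0.662943778581762, -0.648208972995362, 1.14887041732942,
         1.26079319520571, 1.85512115385382, -1.30509169095929,
         -1.74474067542176, 0.366677621630981, -0.364404941119553,
         -2.51210115657106, 0.690866202144745, 1.5981071174331,
         -0.0521827476457273, 0.81173988138651, 1.19119105531097,
         1.50089162361991, 1.39919027740062)
  pen <- 1.02171073469799
  expect_identical(pelt_changepoints(x, penalty = pen),
                   optimal_partition_dp(x, penalty = pen))
  # and across minimum segment lengths on random inputs
  set.seed(61)
  for (i in 1:40) {
    n <- sample(8:28, 1)
    msl <- sample(2:4, 1)
    if (n < 2 * msl) next
    x <- rnorm(n, rep(rnorm(2, 0, 3), each = ceiling(n / 2))[1:n])
    pen <- runif(1, 0.3, 10)
    expect_identical(pelt_changepoints(x, penalty = pen, min_seg_len = msl),
                     optimal_partition_dp(x, penalty = pen, min_seg_len = msl))
  }
})

test_that("transition dates recover generator truth on a noiseless cycle", {
  cp <- cycle_params()
  truth <- scene_truth(cycles = cp, years = 2018L)
  ser <- simulate_camera_series(truth, noise_sd = 0, outlier_rate = 0)
  tr <- extract_transitions(ser)
  m <- merge(tr, truth$true_dates, by = c("direction", "fraction"))
  expect_equal(nrow(m), 6L)
  expect_lt(max(abs(m$doy.x - m$doy.y)), 1)
  # rising dates ordered 10 < 25 < 50; confidence interval contains the date
  r <- tr[tr$direction == "rising", ]
  expect_true(all(diff(r$doy[order(r$fraction)]) > 0))
  expect_true(all(tr$ci_lower <= tr$doy & tr$doy <= tr$ci_upper))
  # zero-noise envelope collapses: interval width below a day
  expect_lt(max(tr$ci_upper - tr$ci_lower), 1)
})

test_that("phases below the minimum amplitude yield no transition dates", {
  cp <- cycle_params(amplitude = 0.015)  # drought-like muted season
  ser <- daily_series(cp)
  tr <- extract_transitions(ser, min_amplitude = 0.02)
  expect_equal(nrow(tr), 0L)
  # the same series passes once the gate is relaxed below its amplitude
  tr2 <- extract_transitions(ser, min_amplitude = 0.01)
  expect_gt(nrow(tr2), 0L)
})

test_that("transition dates are equivariant under affine greenness rescaling", {
  cp <- cycle_params()
  ser <- daily_series(cp, noise_sd = 0.003, seed = 9L)
  tr1 <- extract_transitions(ser)
  resc <- ser
  resc$gcc <- 2.5 * ser$gcc + 0.1
  tr2 <- extract_transitions(resc, min_amplitude = 0.02 * 2.5)
  m <- merge(tr1, tr2, by = c("direction", "fraction"))
  expect_equal(nrow(m), 6L)
  expect_equal(m$doy.x, m$doy.y, tolerance = 1e-6)
})

test_that("confidence interval width grows with noise", {
  cp <- cycle_params()
  width_at <- function(noise_sd) {
    mean(vapply(1:15, function(s) {
      ser <- daily_series(cp, noise_sd = noise_sd, seed = s)
      tr <- suppressMessages(extract_transitions(ser))
      mean(tr$ci_upper - tr$ci_lower)
    }, numeric(1)))
  }
  w <- vapply(c(0.002, 0.005, 0.01), width_at, numeric(1))
  expect_true(all(diff(w) > 0))
})

test_that("the lowest-residual-variance statistic wins, order-independently", {
  cp <- cycle_params()
  curve <- seasonal_curve(cp, 1:365)
  set.seed(12)
  noisy <- tibble::tibble(t = 1:365, gcc = curve + rnorm(365, 0, 0.01))
  clean <- tibble::tibble(t = 1:365, gcc = curve)
  fits <- list(mean = fit_greenness_spline(noisy),
               p90 = fit_greenness_spline(clean))
  expect_equal(as.character(select_best_statistic(fits)), "p90")
  expect_equal(as.character(select_best_statistic(rev(fits))), "p90")
  # asymmetric negative outliers: the p90-style series (which damps them)
  # has lower residual variance than the contaminated mean series
  spikes <- rbinom(365, 1, 0.1) * runif(365, 0.02, 0.1)
  fits2 <- list(
    mean = fit_greenness_spline(
      tibble::tibble(t = 1:365, gcc = curve + rnorm(365, 0, 0.004) - spikes)),
    p90 = fit_greenness_spline(
      tibble::tibble(t = 1:365, gcc = curve + rnorm(365, 0, 0.004))))
  expect_equal(as.character(select_best_statistic(fits2)), "p90")
  expect_error(select_best_statistic(fits[1]), "at least 2")
})

test_that("tidy and glance methods expose fit internals", {
  fit <- fit_greenness_spline(daily_series(cycle_params()))
  td <- tidy(fit)
  expect_true(all(c("observed", "fitted", "residual", "lower", "upper")
                  %in% names(td)))
  expect_equal(nrow(td), fit$n)
  g <- glance(fit)
  expect_equal(g$edf, fit$edf)
})
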