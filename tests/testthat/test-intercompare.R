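toy_pairs <- function() {
  tibble::tibble(site_id = "s", year = 2018L, direction = "rising",
                 fraction = 0.1,
                 phenocam_doy = c(100, 120, 130),
                 modis_doy = c(110, 118, 140),
                 delta = c(10, -2, 10),
                 roi_veg_type = "DB", igbp_code = 4L)
}

test_that("pairing applies the 90-day same-direction rule one-to-one", {
  cam <- tibble::tibble(site_id = "s", year = 2018L, direction = "rising",
                        fraction = 0.1, doy = 100, roi_veg_type = "DB")
  sat <- tibble::tibble(site_id = "s", year = 2018L, direction = "rising",
                        doy = 120, igbp_code = 4L)
  p <- pair_transitions(cam, sat)
  expect_equal(nrow(p), 1L)
  expect_equal(abs(p$delta), 20)
  expect_equal(p$modis_doy - p$phenocam_doy, p$delta)  # documented sign
  # separation of 95 days: no pair
  sat95 <- sat; sat95$doy <- 195
  expect_equal(nrow(suppressMessages(pair_transitions(cam, sat95))), 0L)
  # opposite directions never pair, however close
  satd <- sat; satd$direction <- "falling"; satd$doy <- 105
  expect_equal(nrow(suppressMessages(pair_transitions(cam, satd))), 0L)
  # greedy one-to-one: two camera dates, one satellite date -> one pair,
  # and it is the closer one
  cam2 <- dplyr::bind_rows(cam, dplyr::mutate(cam, doy = 135))
  p2 <- suppressMessages(pair_transitions(cam2, sat))
  expect_equal(nrow(p2), 1L)
  expect_equal(p2$phenocam_doy, 135)
  # pairs can straddle a year boundary on the continuous calendar axis
  camw <- tibble::tibble(site_id = "s", year = 2018L, direction = "falling",
                         fraction = 0.1, doy = 360, roi_veg_type = "DB")
  satw <- tibble::tibble(site_id = "s", year = 2019L, direction = "falling",
                         doy = 10, igbp_code = 4L)
  pw <- pair_transitions(camw, satw)
  expect_equal(nrow(pw), 1L)
  expect_equal(pw$delta, 15)
})

test_that("DOY wrapping follows the cross-year display rule", {
  expect_equal(wrap_doy(300, "rising"), -65)
  expect_equal(wrap_doy(50, "falling"), 415)
  expect_equal(wrap_doy(120, "rising"), 120)
  expect_equal(wrap_doy(250, "falling"), 250)
  expect_equal(wrap_doy(c(300, 120), c("rising", "rising")), c(-65, 120))
})

test_that("apples/oranges classification follows the vegetation-IGBP table", {
  expect_equal(classify_comparison("DB", 4), "apples")
  expect_equal(classify_comparison("DB", 13), "oranges")
  expect_equal(classify_comparison("EN", 5), "apples")
  expect_equal(classify_comparison("AG", c(12, 14, 5)),
               c("apples", "apples", "oranges"))
  expect_equal(classify_comparison("GR", c(10, 12, 14, 7)),
               c("apples", "apples", "apples", "oranges"))
  expect_warning(out <- classify_comparison("SH", 7), "oranges")
  expect_equal(out, "oranges")
})

test_that("bias statistics match hand computation", {
  b <- bias_stats(toy_pairs())
  expect_equal(b$bias_mean, 6)
  expect_equal(b$bias_sd, sqrt(48))  # deviations 4, -8, 4
  expect_equal(b$sd_phenocam, sd(c(100, 120, 130)))
  ident <- tibble::tibble(phenocam_doy = c(100, 150), modis_doy = c(100, 150))
  bi <- bias_stats(ident)
  expect_equal(c(bi$bias_mean, bi$bias_sd), c(0, 0))
  shift <- tibble::tibble(phenocam_doy = c(100, 150, 200),
                          modis_doy = c(105, 155, 205))
  bs <- bias_stats(shift)
  expect_equal(c(bs$bias_mean, bs$bias_sd), c(5, 0))
  # swapping roles negates the bias
  sw <- tibble::tibble(phenocam_doy = toy_pairs()$modis_doy,
                       modis_doy = toy_pairs()$phenocam_doy)
  expect_equal(bias_stats(sw)$bias_mean, -6)
})

test_that("Pearson correlation matches the textbook formula and ignores lambda", {
  tp <- toy_pairs()
  x <- tp$phenocam_doy; y <- tp$modis_doy
  want <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(deming_fit(tp)$pearson_r, want, tolerance = 1e-12)
  expect_equal(deming_fit(tp, lambda = 4)$pearson_r, want, tolerance = 1e-12)
  line <- tibble::tibble(phenocam_doy = c(1, 2, 3), modis_doy = c(8, 9, 10))
  expect_equal(deming_fit(line)$pearson_r, 1)
  anti <- tibble::tibble(phenocam_doy = c(1, 2, 3), modis_doy = -c(1, 2, 3))
  expect_equal(deming_fit(anti)$pearson_r, -1)
})

test_that("orthogonal Deming regression matches a numeric distance minimiser", {
  # exact line y = 2x: slope 2, intercept 0
  line <- tibble::tibble(phenocam_doy = c(1, 2, 3, 4),
                         modis_doy = c(2, 4, 6, 8))
  fit <- deming_fit(line)
  expect_equal(unname(fit$coefficients), c(0, 2), tolerance = 1e-12)
  # noisy 20-point fixture: closed form equals brute-force optimiser
  set.seed(19)
  x <- runif(20, 80, 160)
  y <- 5 + 1.2 * x + rnorm(20, 0, 6)
  d <- tibble::tibble(phenocam_doy = x, modis_doy = y)
  fit <- deming_fit(d)
  opt <- orthogonal_fit_optim(x, y)
  expect_equal(unname(fit$coefficients["slope"]), opt$slope,
               tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["intercept"]), opt$intercept,
               tolerance = 1e-5)
})

test_that("Deming slope obeys swap-reciprocity, OLS limits, and lambda monotonicity", {
  set.seed(23)
  x <- runif(25, 50, 200)
  y <- -10 + 0.9 * x + rnorm(25, 0, 8)
  d <- tibble::tibble(phenocam_doy = x, modis_doy = y)
  dsw <- tibble::tibble(phenocam_doy = y, modis_doy = x)
  for (lam in c(0.25, 1, 3)) {
    b <- unname(deming_fit(d, lambda = lam)$coefficients["slope"])
    bsw <- unname(deming_fit(dsw, lambda = 1 / lam)$coefficients["slope"])
    expect_equal(bsw, 1 / b, tolerance = 1e-9)
  }
  # lambda -> 0: OLS of y on x; lambda -> Inf: reciprocal OLS of x on y
  b_lo <- unname(deming_fit(d, lambda = 1e-12)$coefficients["slope"])
  b_hi <- unname(deming_fit(d, lambda = 1e12)$coefficients["slope"])
  expect_equal(b_lo, ols_slope(x, y), tolerance = 1e-9)
  expect_equal(b_hi, 1 / ols_slope(y, x), tolerance = 1e-9)
  # slope is monotone increasing in lambda (x:y error-variance ratio)
  slopes <- vapply(c(0.25, 0.5, 1, 2, 4), function(l) {
    unname(deming_fit(d, lambda = l)$coefficients["slope"])
  }, numeric(1))
  expect_true(all(diff(slopes) > 0))
  expect_error(deming_fit(d, lambda = 0), "lambda")
})

test_that("perpendicular distances follow the printed squared form and geometry", {
  # point on the line: zero
  expect_equal(perpendicular_distance(5, 10, 0, 2), 0)
  # zero slope reduces to the squared residual
  expect_equal(perpendicular_distance(3, 7, 2, 0), 25)
  # 45-degree line through origin, point (0, 1): squared distance 1/2, and
  # its square root is the geometric point-line distance
  d <- perpendicular_distance(0, 1, 0, 1)
  expect_equal(d, 0.5, tolerance = 1e-15)
  expect_equal(sqrt(d), point_line_distance(0, 1, 0, 1), tolerance = 1e-15)
  set.seed(29)
  x <- rnorm(50); y <- rnorm(50); b0 <- 0.7; b1 <- -1.3
  expect_equal(sqrt(perpendicular_distance(x, y, b0, b1)),
               point_line_distance(x, y, b0, b1), tolerance = 1e-12)
})

test_that("RMS distance uses n - 2 degrees of freedom", {
  # all points on the line: zero
  expect_equal(rms_distance(c(1, 2, 3), c(2, 4, 6), 0, 2), 0)
  # n = 3 with one off-line point of squared distance 2: sqrt(2 / 1)
  x <- c(0, 1, 2)
  y <- c(0, 1, 2 + sqrt(2 * (1 + 1)))  # d = (offset)^2/(1+1) = 2
  expect_equal(rms_distance(x, y, 0, 1), sqrt(2), tolerance = 1e-12)
  expect_true(is.na(rms_distance(c(1, 2), c(1, 2), 0, 1)))
  # matches independent recomputation from raw coordinates
  set.seed(31)
  x <- runif(15); y <- runif(15)
  want <- sqrt(sum((y - (0.2 + 0.8 * x))^2 / (1 + 0.8^2)) / 13)
  expect_equal(rms_distance(x, y, 0.2, 0.8), want, tolerance = 1e-12)
})

test_that("deming_fit enforces preconditions and reportability", {
  expect_error(deming_fit(toy_pairs()[1:2, ]), "at least 3")
  degen <- tibble::tibble(phenocam_doy = c(1, 1, 1), modis_doy = c(1, 2, 3))
  expect_error(deming_fit(degen), "degenerate")
  # a 3-point fit can be estimated but is below the n >= 10 reporting bar
  expect_false(deming_fit(toy_pairs())$reportable)
  td <- tidy(deming_fit(toy_pairs()))
  expect_equal(td$term, c("intercept", "slope"))
  g <- glance(deming_fit(toy_pairs()))
  expect_equal(g$n, 3L)
})

test_that("the summary table composes the individual statistics", {
  tp <- toy_pairs()
  tab <- agreement_summary(tp, min_n = 2)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$comparison, "apples")
  b <- bias_stats(tp)
  expect_equal(tab$bias_mean, b$bias_mean)
  expect_equal(tab$sd_modis, b$sd_modis)
  fit <- deming_fit(tp)
  expect_equal(tab$rms_distance, fit$rms_distance)
  expect_equal(tab$pearson_r, fit$pearson_r)
  # n = 3 < 10: Deming columns blanked under the reporting rule
  expect_true(is.na(tab$slope))
  # one headline-eligibility flag per veg x comparison (needs both phases)
  expect_false(tab$meets_min_n)
})

test_that("apples/oranges split counts always partition the pairs", {
  set.seed(37)
  n <- 60
  pairs <- tibble::tibble(
    site_id = "s", year = 2018L,
    direction = sample(c("rising", "falling"), n, TRUE),
    fraction = 0.1,
    phenocam_doy = runif(n, 80, 160),
    modis_doy = runif(n, 80, 160),
    roi_veg_type = sample(c("AG", "DB", "EN", "GR"), n, TRUE),
    igbp_code = sample(c(1L, 4L, 5L, 10L, 12L, 13L, 14L), n, TRUE))
  pairs$comparison <- classify_comparison(pairs$roi_veg_type, pairs$igbp_code)
  tab <- agreement_summary(pairs, min_n = 1)
  expect_equal(sum(tab$n), n)
  agg <- stats::aggregate(n ~ comparison, as.data.frame(tab), sum)
  expect_equal(sum(agg$n), n)
})
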