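#' Green chromatic coordinate from an RGB digital-number triplet
#'
#' Computes the canopy-greenness index
#' \deqn{G_{cc} = G_{DN} / (R_{DN} + G_{DN} + B_{DN})}
#' from mean red/green/blue digital numbers over an image region of interest.
#' The three chromatic coordinates (`rcc`, `gcc`, `bcc`) of any valid triplet
#' sum to 1. A non-positive channel sum yields `NA` (a flagged missing value),
#' never an error.
#'
#' @param r,g,b Mean digital numbers per channel, each >= 0. Vectorised.
#' @return Numeric vector of Gcc values in `[0, 1]`, `NA` where `r+g+b <= 0`.
#' @export
#' @examples
#' gcc(92, 118, 70)  # 118/280
gcc <- function(r, g, b) {
  s <- r + g + b
  ifelse(is.finite(s) & s > 0, g / s, NA_real_)
}

#' @rdname gcc
#' @export
rcc <- function(r, g, b) {
  s <- r + g + b
  ifelse(is.finite(s) & s > 0, r / s, NA_real_)
}

#' @rdname gcc
#' @export
bcc <- function(r, g, b) {
  s <- r + g + b
  ifelse(is.finite(s) & s > 0, b / s, NA_real_)
}

#' Screen image samples by solar elevation and image brightness
#'
#' Retains rows of a per-image sample table whose solar elevation at the
#' site is at least `min_elevation` degrees (the daylight rule; geometric,
#' not refraction-corrected) and whose mean digital number
#' `mean(r_dn, g_dn, b_dn)` lies within `brightness_bounds` (neither too dark
#' nor too bright). The screen is a pure row predicate: order is preserved
#' and no values are altered.
#'
#' @param data Data frame with columns `timestamp` (POSIXct with an explicit
#'   time zone), `latitude`, `longitude`, `r_dn`, `g_dn`, `b_dn`.
#' @param min_elevation Minimum solar elevation in degrees (default 10).
#' @param brightness_bounds Length-2 numeric `(low, high)` on the mean DN;
#'   default `c(30, 230)`.
#' @return The retained rows as a tibble, with `solar_elevation` and
#'   `mean_dn` columns appended.
#' @export
filter_samples <- function(data, min_elevation = 10,
                           brightness_bounds = c(30, 230)) {
  req <- c("timestamp", "latitude", "longitude", "r_dn", "g_dn", "b_dn")
  miss <- setdiff(req, names(data))
  if (length(miss)) abort(paste("missing columns:", toString(miss)))
  if (brightness_bounds[1] >= brightness_bounds[2]) {
    abort("`brightness_bounds` must satisfy low < high")
  }
  out <- as_tibble(data)
  out$solar_elevation <- solar_elevation(out$timestamp, out$latitude,
                                         out$longitude)
  out$mean_dn <- (out$r_dn + out$g_dn + out$b_dn) / 3
  keep <- out$solar_elevation >= min_elevation &
    out$mean_dn >= brightness_bounds[1] &
    out$mean_dn <= brightness_bounds[2]
  res <- out[which(keep), , drop = FALSE]
  if (!nrow(res)) inform("no samples survive the elevation/brightness screen")
  res
}

window_stat <- function(x, statistic) {
  switch(statistic,
    mean = mean(x),
    p50 = unname(quantile(x, 0.50, type = 7)),
    p75 = unname(quantile(x, 0.75, type = 7)),
    p90 = unname(quantile(x, 0.90, type = 7)),
    abort(sprintf("unknown statistic '%s'", statistic)))
}

#' Aggregate per-image greenness to a daily moving-window product
#'
#' Collapses screened per-image Gcc values to one value per calendar day,
#' taking a summary statistic over all samples whose date falls within a
#' centred window (default 3 days). `mode = "sliding"` steps the centred
#' window one day at a time; `mode = "binned"` uses fixed consecutive
#' `window_days` bins (each value assigned to the bin's centre day), the
#' convention of released 3-day camera products. Percentiles use linear
#' interpolation between order statistics (`stats::quantile` type 7). Days
#' whose window holds no samples are absent from the output.
#'
#' @param data Data frame with a `date` (or POSIXct `timestamp`) column and
#'   a `gcc` column; other columns are ignored.
#' @param statistic One of `"mean"`, `"p50"`, `"p75"`, `"p90"`.
#' @param window_days Odd window width in days (default 3).
#' @param mode `"sliding"` (default) or `"binned"`.
#' @return A tibble with `date`, `year`, `doy`, `statistic`, `gcc`,
#'   `n_samples`.
#' @export
aggregate_gcc <- function(data, statistic = c("mean", "p50", "p75", "p90"),
                          window_days = 3L, mode = c("sliding", "binned")) {
  statistic <- match.arg(statistic)
  mode <- match.arg(mode)
  if (window_days < 1 || window_days %% 2 == 0) {
    abort("`window_days` must be odd and >= 1")
  }
  if (!"date" %in% names(data)) {
    if (!"timestamp" %in% names(data)) abort("need a `date` or `timestamp` column")
    data$date <- as.Date(data$timestamp, tz = tz_of(data$timestamp))
  }
  obs <- data[!is.na(data$gcc), c("date", "gcc")]
  if (!nrow(obs)) return(tibble(date = as.Date(character()), year = integer(),
                                doy = integer(), statistic = character(),
                                gcc = double(), n_samples = integer()))
  obs$date <- as.Date(obs$date)
  half <- (window_days - 1L) / 2L
  if (mode == "sliding") {
    days <- seq(min(obs$date), max(obs$date), by = "day")
  } else {
    days <- seq(min(obs$date) + half, max(obs$date), by = window_days)
  }
  rows <- lapply(days, function(d) {
    sel <- obs$gcc[obs$date >= d - half & obs$date <= d + half]
    if (!length(sel)) return(NULL)
    tibble(date = d, gcc = window_stat(sel, statistic),
           n_samples = length(sel))
  })
  out <- dplyr::bind_rows(rows)
  out$year <- as.integer(format(out$date, "%Y"))
  out$doy <- as.integer(format(out$date, "%j"))
  out$statistic <- statistic
  out[, c("date", "year", "doy", "statistic", "gcc", "n_samples")]
}

tz_of <- function(x) {
  tz <- attr(x, "tzone")
  if (is.null(tz) || !nzchar(tz[1])) "UTC" else tz[1]
}

#' Mean ROI digital numbers from an image and a binary mask
#'
#' Reads a PNG image and a same-sized PNG mask (non-zero = inside the region
#' of interest) and returns the mean red/green/blue digital numbers (0--255
#' scale) over the masked pixels.
#'
#' @param image_path Path to an RGB (or greyscale) PNG.
#' @param mask_path Optional path to a binary mask PNG; `NULL` uses the
#'   whole frame.
#' @return A tibble with one row: `r_dn`, `g_dn`, `b_dn`, `n_pixels`.
#' @export
read_roi_triplet <- function(image_path, mask_path = NULL) {
  img <- png::readPNG(image_path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (is.null(mask_path)) {
    roi <- matrix(TRUE, dim(img)[1], dim(img)[2])
  } else {
    m <- png::readPNG(mask_path)
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    if (!identical(dim(m), dim(img)[1:2])) {
      abort("mask dimensions do not match the image")
    }
    roi <- m > 0
  }
  if (!any(roi)) abort("empty ROI mask")
  tibble(r_dn = mean(img[, , 1L][roi]) * 255,
         g_dn = mean(img[, , 2L][roi]) * 255,
         b_dn = mean(img[, , 3L][roi]) * 255,
         n_pixels = sum(roi))
}
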