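#' Read and write the flat CSV formats used by the pipeline
#'
#' Thin readr wrappers fixing the column layouts the pipeline exchanges:
#'
#' * camera series: `site_id, date, statistic, gcc`
#' * per-image samples: `timestamp, r_dn, g_dn, b_dn` (plus `latitude`,
#'   `longitude`)
#' * satellite window reflectances: `pixel_row, pixel_col, date, band1,
#'   band2` (`ndvi` added on read)
#' * satellite transition dates: `site_id, year, direction, doy`
#'   (plus optional `igbp_code`, `cycle`; at most two cycles per year per
#'   pixel are accepted, both preserved)
#' * transition-date product: `site_id, roi_veg_type, statistic, year,
#'   direction, threshold_fraction, doy, ci_lower, ci_upper`
#' * scene truth: `year, cycle, direction, fraction, doy`
#'
#' @param data Tibble in the corresponding layout.
#' @param path CSV path.
#' @name phenomatch_io
NULL

#' @rdname phenomatch_io
#' @export
write_camera_csv <- function(data, path) {
  readr::write_csv(data[, intersect(c("site_id", "date", "statistic", "gcc"),
                                    names(data))], path)
  invisible(path)
}

#' @rdname phenomatch_io
#' @export
read_camera_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname phenomatch_io
#' @export
read_image_samples <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  if (!inherits(out$timestamp, "POSIXct")) {
    out$timestamp <- as.POSIXct(out$timestamp, tz = "UTC")
  }
  out
}

#' @rdname phenomatch_io
#' @export
write_satellite_csv <- function(data, path) {
  cols <- intersect(c("pixel_row", "pixel_col", "date", "band1", "band2",
                      "ndvi"), names(data))
  readr::write_csv(data[, cols], path)
  invisible(path)
}

#' @rdname phenomatch_io
#' @export
read_satellite_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  if (!"ndvi" %in% names(out)) out$ndvi <- ndvi(out$band1, out$band2)
  out
}

#' @rdname phenomatch_io
#' @export
read_satellite_transitions <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  if (!"cycle" %in% names(out)) out$cycle <- 1L
  # at most two phenological cycles per pixel-year are accepted; both kept
  key_cols <- intersect(c("site_id", "pixel", "year", "direction"),
                        names(out))
  counts <- dplyr::count(out, dplyr::across(dplyr::all_of(key_cols)))
  if (any(counts$n > 2L)) {
    abort("more than two cycles per pixel-year-direction in satellite dates")
  }
  out
}

#' @rdname phenomatch_io
#' @export
write_transition_csv <- function(data, path) {
  if ("fraction" %in% names(data) && !"threshold_fraction" %in% names(data)) {
    data$threshold_fraction <- data$fraction
  }
  cols <- intersect(c("site_id", "roi_veg_type", "statistic", "year",
                      "direction", "threshold_fraction", "doy",
                      "ci_lower", "ci_upper"), names(data))
  readr::write_csv(data[, cols], path)
  invisible(path)
}

#' @rdname phenomatch_io
#' @export
write_truth_csv <- function(data, path) {
  if (inherits(data, "scene_truth")) data <- data$true_dates
  readr::write_csv(data, path)
  invisible(path)
}
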