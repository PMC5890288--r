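#' Normalized difference vegetation index from red/NIR reflectances
#'
#' \deqn{NDVI = (band2 - band1) / (band1 + band2)}
#' with `band1` the red (620--670 nm) and `band2` the NIR (841--876 nm)
#' nadir reflectance. A non-positive band sum yields `NA` (flagged missing),
#' never an error. NDVI depends only on the band ratio, so it is invariant
#' to uniform scaling of both bands.
#'
#' @param band1,band2 Reflectances in `[0, 1]`. Vectorised.
#' @return NDVI in `[-1, 1]`, `NA` where `band1 + band2 <= 0`.
#' @export
#' @examples
#' ndvi(0.05, 0.45)  # 0.8
ndvi <- function(band1, band2) {
  s <- band1 + band2
  ifelse(is.finite(s) & s > 0, (band2 - band1) / s, NA_real_)
}

#' Per-date NDVI envelope of a 3x3 satellite pixel window
#'
#' For each composite date, the minimum, maximum, and centre-pixel NDVI
#' across the 3x3 window centred on the camera pixel — the spatial-range
#' summary used to display coarse-scale landscape heterogeneity around a
#' site. Missing pixels are excluded; a date with no valid pixel yields a
#' missing envelope.
#'
#' @param data Data frame with columns `pixel_row`, `pixel_col` (1--3;
#'   centre is (2, 2)), `date`, and `ndvi` (or `band1`/`band2`, from which
#'   NDVI is computed).
#' @return A tibble with `date`, `ndvi_min`, `ndvi_max`, `ndvi_center`,
#'   `n_pixels`.
#' @export
window_envelope <- function(data) {
  if (!"ndvi" %in% names(data)) {
    if (!all(c("band1", "band2") %in% names(data))) {
      abort("need `ndvi` or `band1`+`band2` columns")
    }
    data$ndvi <- ndvi(data$band1, data$band2)
  }
  data |>
    dplyr::group_by(date = .data$date) |>
    dplyr::summarise(
      ndvi_min = if (any(is.finite(.data$ndvi)))
        min(.data$ndvi, na.rm = TRUE) else NA_real_,
      ndvi_max = if (any(is.finite(.data$ndvi)))
        max(.data$ndvi, na.rm = TRUE) else NA_real_,
      ndvi_center = {
        ctr <- .data$ndvi[.data$pixel_row == 2L & .data$pixel_col == 2L]
        if (length(ctr) && is.finite(ctr[1])) ctr[1] else NA_real_
      },
      n_pixels = sum(is.finite(.data$ndvi)),
      .groups = "drop")
}

#' Majority IGBP landcover code of a 3x3 pixel window
#'
#' Returns the modal IGBP code among the unmasked cells of the 9-cell
#' window. Ties and all-masked windows are unresolved and return
#' `NA_integer_` — deliberately, so no landcover class is silently
#' favoured; the caller decides how to treat unresolved windows.
#'
#' @param codes Integer vector of 9 IGBP codes; `NA` marks masked cells.
#' @return The majority code, or `NA_integer_` if unresolved. The logical
#'   attribute `"unresolved"` distinguishes a tie/all-masked outcome.
#' @export
#' @examples
#' landcover_majority(c(4, 4, 4, 4, 4, 5, 5, 1, 1))  # 4
landcover_majority <- function(codes) {
  if (length(codes) != 9L) abort("`codes` must have length 9")
  codes <- as.integer(codes)
  present <- codes[!is.na(codes)]
  if (!length(present)) {
    return(structure(NA_integer_, unresolved = TRUE))
  }
  tab <- table(present)
  winners <- as.integer(names(tab)[tab == max(tab)])
  if (length(winners) > 1L) {
    return(structure(NA_integer_, unresolved = TRUE))
  }
  structure(winners, unresolved = FALSE)
}
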