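#' Pair camera transition dates with satellite transition dates
#'
#' Matches each camera transition date to a satellite transition date of the
#' same site and direction ("rising" paired with greenup onset, "falling"
#' with dormancy onset) whose absolute separation is below `max_diff` days.
#' Matching is one-to-one and greedy by smallest absolute separation; dates
#' left unmatched are dropped (counts are reported via a message).
#' Separations are computed on a continuous calendar axis from `year` and
#' `doy`, so pairs may straddle a year boundary.
#'
#' @param camera Data frame of camera dates with columns `site_id`, `year`,
#'   `direction`, `doy`, and optionally `fraction` and `roi_veg_type`.
#' @param satellite Data frame of satellite dates with columns `site_id`
#'   (optional if a single site), `year`, `direction`, `doy`, and optionally
#'   `igbp_code`.
#' @param max_diff Maximum absolute separation in days (default 90,
#'   exclusive).
#' @return A tibble of paired transitions: `site_id`, `year`, `direction`,
#'   `fraction`, `phenocam_doy`, `modis_doy`, `delta` (satellite minus
#'   camera, days), `roi_veg_type`, `igbp_code`.
#' @export
pair_transitions <- function(camera, satellite, max_diff = 90) {
  camera <- as_tibble(camera)
  satellite <- as_tibble(satellite)
  if (!"site_id" %in% names(satellite)) {
    satellite$site_id <- camera$site_id[1] %||% "site"
  }
  if (!"site_id" %in% names(camera)) camera$site_id <- "site"
  if (!"fraction" %in% names(camera)) camera$fraction <- NA_real_
  if (!"roi_veg_type" %in% names(camera)) camera$roi_veg_type <- NA_character_
  if (!"igbp_code" %in% names(satellite)) satellite$igbp_code <- NA_integer_

  day_axis <- function(year, doy) as.numeric(year_origin(year)) + doy - 1
  camera$t <- day_axis(camera$year, camera$doy)
  satellite$t <- day_axis(satellite$year, satellite$doy)

  pairs <- list()
  n_unmatched <- 0L
  for (key in unique(paste(camera$site_id, camera$direction,
                           camera$fraction))) {
    cam <- camera[paste(camera$site_id, camera$direction,
                        camera$fraction) == key, ]
    sat <- satellite[satellite$site_id == cam$site_id[1] &
                       satellite$direction == cam$direction[1], ]
    if (!nrow(sat)) { n_unmatched <- n_unmatched + nrow(cam); next }
    # all candidate pairs within the window, greedily by |delta|
    cand <- expand.grid(i = seq_len(nrow(cam)), j = seq_len(nrow(sat)))
    cand$delta <- sat$t[cand$j] - cam$t[cand$i]
    cand <- cand[abs(cand$delta) < max_diff, , drop = FALSE]
    cand <- cand[order(abs(cand$delta)), , drop = FALSE]
    used_i <- logical(nrow(cam)); used_j <- logical(nrow(sat))
    for (r in seq_len(nrow(cand))) {
      i <- cand$i[r]; j <- cand$j[r]
      if (used_i[i] || used_j[j]) next
      used_i[i] <- TRUE; used_j[j] <- TRUE
      pairs[[length(pairs) + 1L]] <- tibble(
        site_id = cam$site_id[i], year = cam$year[i],
        direction = cam$direction[i], fraction = cam$fraction[i],
        phenocam_doy = cam$doy[i], modis_doy = sat$doy[j],
        delta = cand$delta[r],
        roi_veg_type = cam$roi_veg_type[i],
        igbp_code = sat$igbp_code[j])
    }
    n_unmatched <- n_unmatched + sum(!used_i)
  }
  if (n_unmatched > 0L) {
    inform(sprintf(
      "%d camera date(s) left unmatched (no same-direction satellite date within %g d)",
      n_unmatched, max_diff))
  }
  out <- dplyr::bind_rows(pairs)
  if (!nrow(out)) {
    out <- tibble(site_id = character(), year = integer(),
                  direction = character(), fraction = double(),
                  phenocam_doy = double(), modis_doy = double(),
                  delta = double(), roi_veg_type = character(),
                  igbp_code = integer())
  }
  out
}

#' Wrap day-of-year values for cross-year display and analysis
#'
#' Rising-phase dates after DOY 270 are wrapped to the beginning of the year
#' (negative DOY); falling-phase dates before DOY 90 are wrapped to the end
#' of the year (DOY > 365). This keeps early-winter greenups and mid-winter
#' senescence dates on a continuous axis with the rest of their phase.
#'
#' @param doy Numeric day-of-year vector.
#' @param direction `"rising"` or `"falling"`, recycled.
#' @return Wrapped DOY values.
#' @export
#' @examples
#' wrap_doy(300, "rising")   # -65
#' wrap_doy(50, "falling")   # 415
wrap_doy <- function(doy, direction) {
  direction <- rep_len(direction, length(doy))
  out <- doy
  out[direction == "rising" & doy > 270] <-
    doy[direction == "rising" & doy > 270] - 365
  out[direction == "falling" & doy < 90] <-
    doy[direction == "falling" & doy < 90] + 365
  out
}

#' Default vegetation-type to IGBP "apples" mapping
#'
#' For each camera ROI vegetation type, the set of IGBP landcover codes
#' considered a like-for-like ("apples to apples") satellite comparison:
#' AG (agriculture): 12 croplands, 14 cropland/natural mosaic; DB (deciduous
#' broadleaf): 4 deciduous broadleaf forest, 5 mixed forest; EN (evergreen
#' needleleaf): 1 evergreen needleleaf forest, 5 mixed forest; GR
#' (grassland): 10 grasslands, 12, 14.
#'
#' @return Named list of integer IGBP code sets.
#' @export
apples_table <- function() {
  list(AG = c(12L, 14L), DB = c(4L, 5L), EN = c(1L, 5L),
       GR = c(10L, 12L, 14L))
}

#' Classify a camera-satellite pair as apples or oranges
#'
#' A pair is "apples" when the satellite pixel's IGBP code belongs to the
#' ROI vegetation type's like-for-like set (see [apples_table()]);
#' otherwise "oranges". Vegetation types absent from the table (or missing
#' codes) classify as "oranges" with a warning.
#'
#' @param roi_veg_type Character vector of ROI vegetation codes.
#' @param igbp_code Integer vector of IGBP codes.
#' @param table Mapping list as from [apples_table()].
#' @return Character vector, `"apples"` or `"oranges"`.
#' @export
#' @examples
#' classify_comparison("DB", 4)   # apples
#' classify_comparison("DB", 13)  # oranges
classify_comparison <- function(roi_veg_type, igbp_code,
                                table = apples_table()) {
  n <- max(length(roi_veg_type), length(igbp_code))
  roi_veg_type <- rep_len(roi_veg_type, n)
  igbp_code <- rep_len(igbp_code, n)
  unknown <- !roi_veg_type %in% names(table)
  if (any(unknown, na.rm = TRUE)) {
    warn(sprintf("vegetation type(s) %s not in the apples table; classified as oranges",
                 toString(unique(roi_veg_type[unknown]))))
  }
  vapply(seq_len(n), function(i) {
    if (is.na(roi_veg_type[i]) || unknown[i] || is.na(igbp_code[i])) {
      return("oranges")
    }
    if (igbp_code[i] %in% table[[roi_veg_type[i]]]) "apples" else "oranges"
  }, character(1))
}
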