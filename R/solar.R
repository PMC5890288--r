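deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Solar elevation angle at a time and place
#'
#' Geometric (not refraction-corrected) solar elevation above the horizon,
#' computed with the NOAA general solar-position approximation (Meeus-based
#' low-cost series for solar longitude, declination and the equation of
#' time). Accuracy is about +/- 0.1--0.5 degrees over 1900--2100, ample for
#' daylight screening of imagery.
#'
#' Timestamps must be POSIXct carrying an explicit time zone; naive
#' date-times are rejected because a silently wrong zone shifts the sun by
#' 15 degrees of hour angle per hour.
#'
#' @param time POSIXct vector with a non-empty `tzone` attribute.
#' @param latitude,longitude Degrees; north and east positive. Vectorised.
#' @return Solar elevation in degrees, in `[-90, 90]`.
#' @export
#' @examples
#' t <- as.POSIXct("2020-03-20 12:00", tz = "UTC")
#' solar_elevation(t, latitude = 0, longitude = 0)  # near 90 at equinox noon
solar_elevation <- function(time, latitude, longitude) {
  if (!inherits(time, "POSIXct")) abort("`time` must be POSIXct")
  tz <- attr(time, "tzone")
  if (is.null(tz) || !nzchar(tz[1])) {
    abort("`time` must carry an explicit time zone (naive timestamps rejected)")
  }
  if (any(abs(latitude) > 90, na.rm = TRUE) ||
      any(abs(longitude) > 180, na.rm = TRUE)) {
    abort("|latitude| <= 90 and |longitude| <= 180 required")
  }
  # Julian day from the epoch (POSIXct is UTC internally regardless of tzone)
  jd <- as.numeric(time) / 86400 + 2440587.5
  jc <- (jd - 2451545) / 36525

  gml <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  gma <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  ecc <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  eqc <- sin(deg2rad(gma)) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(deg2rad(2 * gma)) * (0.019993 - 0.000101 * jc) +
    sin(deg2rad(3 * gma)) * 0.000289
  stl <- gml + eqc
  sal <- stl - 0.00569 - 0.00478 * sin(deg2rad(125.04 - 1934.136 * jc))
  moe <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) /
                 60) / 60
  oc <- moe + 0.00256 * cos(deg2rad(125.04 - 1934.136 * jc))
  decl <- rad2deg(asin(sin(deg2rad(oc)) * sin(deg2rad(sal))))

  vy <- tan(deg2rad(oc / 2))^2
  eqtime <- 4 * rad2deg(
    vy * sin(2 * deg2rad(gml)) - 2 * ecc * sin(deg2rad(gma)) +
      4 * ecc * vy * sin(deg2rad(gma)) * cos(2 * deg2rad(gml)) -
      0.5 * vy^2 * sin(4 * deg2rad(gml)) -
      1.25 * ecc^2 * sin(2 * deg2rad(gma)))

  min_utc <- ((jd + 0.5) %% 1) * 1440
  tst <- (min_utc + eqtime + 4 * longitude) %% 1440
  ha <- tst / 4 - 180
  ha <- ifelse(ha < -180, ha + 360, ha)

  elev <- rad2deg(asin(
    sin(deg2rad(latitude)) * sin(deg2rad(decl)) +
      cos(deg2rad(latitude)) * cos(deg2rad(decl)) * cos(deg2rad(ha))))
  pmin(pmax(elev, -90), 90)
}
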