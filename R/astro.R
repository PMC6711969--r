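# Solar and lunar geometry for daily covariates. Photoperiod follows the
# NOAA solar position algorithm (Meeus-derived series, -0.833 deg refraction
# horizon); moon fraction uses a truncated geocentric lunar ephemeris.
# Accuracy targets: day length to well under 2 minutes at mid-latitudes,
# illuminated fraction to ~0.01 — ample for daily ecological covariates.

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# Julian day number of a calendar Date at 00:00 UTC
julian_day <- function(date) as.numeric(date) + 2440587.5

# Solar declination (deg) and equation of time (min) at Julian centuries jc
solar_position <- function(jc) {
  L0 <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  M  <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  e  <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  C  <- sin(deg2rad(M)) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(deg2rad(2 * M)) * (0.019993 - 0.000101 * jc) +
    sin(deg2rad(3 * M)) * 0.000289
  true_long <- L0 + C
  omega <- 125.04 - 1934.136 * jc
  app_long <- true_long - 0.00569 - 0.00478 * sin(deg2rad(omega))
  eps0 <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 -
    jc * 0.001813))) / 60) / 60
  eps <- eps0 + 0.00256 * cos(deg2rad(omega))
  decl <- rad2deg(asin(sin(deg2rad(eps)) * sin(deg2rad(app_long))))
  y <- tan(deg2rad(eps / 2))^2
  eqtime <- 4 * rad2deg(
    y * sin(2 * deg2rad(L0)) - 2 * e * sin(deg2rad(M)) +
      4 * e * y * sin(deg2rad(M)) * cos(2 * deg2rad(L0)) -
      0.5 * y^2 * sin(4 * deg2rad(L0)) - 1.25 * e^2 * sin(2 * deg2rad(M)))
  list(declination = decl, eqtime = eqtime)
}

#' Daily photoperiod (sunrise-to-sunset hours)
#'
#' Day length for a calendar date and location, from the NOAA solar position
#' algorithm with the conventional -0.833 degree refraction-corrected
#' horizon. The declination is evaluated at local solar noon. Polar day and
#' night return 24 and 0 respectively, flagged in the \code{"polar"}
#' attribute.
#'
#' @param date Date vector (or coercible).
#' @param lon,lat location in decimal degrees (WGS84). \code{lon} only
#'   shifts the solar-noon epoch at which declination is evaluated, a
#'   sub-minute effect.
#' @return numeric vector of hours in [0, 24], attribute \code{"polar"}
#'   logical vector marking clamped polar values.
#' @examples
#' photoperiod(as.Date("2017-12-21"), lon = -73.5, lat = 40.5)
#' @export
photoperiod <- function(date, lon = 0, lat = 0) {
  date <- as.Date(date)
  if (any(abs(lat) > 89.5)) stop("latitude beyond polar handling bounds")
  # declination at local solar noon of the date
  jd_noon <- julian_day(date) + 0.5 - lon / 360
  jc <- (jd_noon - 2451545) / 36525
  sp <- solar_position(jc)
  decl <- deg2rad(sp$declination)
  phi <- deg2rad(lat)
  cos_ha <- (cos(deg2rad(90.833)) - sin(phi) * sin(decl)) /
    (cos(phi) * cos(decl))
  polar <- cos_ha < -1 | cos_ha > 1
  cos_ha <- pmin(1, pmax(-1, cos_ha))
  hours <- 2 * rad2deg(acos(cos_ha)) / 15
  attr(hours, "polar") <- polar
  hours
}

#' Moon illuminated fraction
#'
#' Fraction of the lunar disc illuminated at 12:00 UTC of each date, from
#' truncated geocentric solar and lunar ephemerides (largest periodic terms
#' only). Adequate to place full and new moon within a day.
#'
#' @param date Date vector (or coercible).
#' @return numeric vector in [0, 1].
#' @examples
#' moon_fraction(as.Date("2018-01-02"))  # full moon
#' @export
moon_fraction <- function(date) {
  date <- as.Date(date)
  d <- julian_day(date) + 0.5 - 2451545   # days since J2000.0 at 12:00 UTC
  # sun
  Ms <- deg2rad((357.5291 + 0.98560028 * d) %% 360)
  Cs <- 1.9148 * sin(Ms) + 0.02 * sin(2 * Ms) + 0.0003 * sin(3 * Ms)
  lambda_s <- deg2rad((rad2deg(Ms) + Cs + 102.9372 + 180) %% 360)
  sdist <- 149598000
  # moon
  L <- deg2rad((218.316 + 13.176396 * d) %% 360)
  Mm <- deg2rad((134.963 + 13.064993 * d) %% 360)
  F <- deg2rad((93.272 + 13.229350 * d) %% 360)
  l <- L + deg2rad(6.289) * sin(Mm)
  b <- deg2rad(5.128) * sin(F)
  mdist <- 385001 - 20905 * cos(Mm)
  # geocentric elongation -> phase angle -> illuminated fraction
  cos_psi <- cos(b) * cos(l - lambda_s)
  psi <- acos(pmin(1, pmax(-1, cos_psi)))
  inc <- atan2(sdist * sin(psi), mdist - sdist * cos(psi))
  (1 + cos(inc)) / 2
}
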