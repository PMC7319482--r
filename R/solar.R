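#' Solar geometry: declination, equation of time, sunrise/sunset, elevation
#'
#' Implements the NOAA low-precision solar position equations. These anchor
#' everything in the package that depends on the solar day: the dawn hour
#' used to window division- and net-growth-rate calculations, the daylight
#' mask used by the stratification index, and the half-sine within-day light
#' curve of the synthetic-data generator.
#'
#' @name solar
#' @keywords internal
NULL

# fractional year (radians) for year day d (1-based) and decimal hour h (UTC)
.frac_year <- function(yearday, hour = 12) {
  2 * pi / 365 * (yearday - 1 + (hour - 12) / 24)
}

#' Solar declination (radians)
#' @param yearday 1-based day of year.
#' @keywords internal
solar_declination <- function(yearday) {
  g <- .frac_year(yearday)
  0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
}

#' Equation of time (minutes)
#' @param yearday 1-based day of year.
#' @keywords internal
equation_of_time <- function(yearday) {
  g <- .frac_year(yearday)
  229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
              0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
}

#' Sunrise and sunset hours (UTC)
#'
#' @param yearday 1-based day of year.
#' @param lat,lon degrees; longitude positive east.
#' @return list with `sunrise`, `sunset`, `daylength` (decimal hours UTC).
#'   At polar day/night the hour angle is clamped (daylength 24 or 0).
#' @export
sun_times <- function(yearday, lat, lon) {
  decl <- solar_declination(yearday)
  phi <- lat * pi / 180
  cos_ha <- -tan(phi) * tan(decl)
  cos_ha <- pmin(1, pmax(-1, cos_ha))
  ha <- acos(cos_ha) * 180 / pi            # degrees
  noon <- 12 - lon / 15 - equation_of_time(yearday) / 60
  list(sunrise = noon - ha / 15,
       sunset  = noon + ha / 15,
       daylength = 2 * ha / 15)
}

#' Dawn hour for a year day (UTC, rounded to nearest whole hour)
#' @inheritParams sun_times
#' @export
dawn_hour <- function(yearday, lat, lon) {
  round(sun_times(yearday, lat, lon)$sunrise) %% 24
}

#' Solar elevation angle (degrees)
#' @param yearday 1-based day of year.
#' @param hour_utc decimal hour UTC.
#' @inheritParams sun_times
#' @export
solar_elevation <- function(yearday, hour_utc, lat, lon) {
  decl <- solar_declination(yearday)
  phi <- lat * pi / 180
  tst <- hour_utc * 60 + equation_of_time(yearday) + 4 * lon   # true solar time, min
  ha <- (tst / 4 - 180) * pi / 180
  cos_zen <- sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(ha)
  90 - acos(pmin(1, pmax(-1, cos_zen))) * 180 / pi
}

#' Daylight mask for a vector of hours
#'
#' Daylight is defined as solar elevation > 0 at the hour's midpoint.
#' @param yearday 1-based day of year (scalar or vector matching `hours`).
#' @param hours integer hours UTC (0-23).
#' @inheritParams sun_times
#' @return logical vector.
#' @export
is_daylight <- function(yearday, hours, lat, lon) {
  solar_elevation(yearday, hours + 0.5, lat, lon) > 0
}
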