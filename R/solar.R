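#' Solar elevation angle
#'
#' Geometric (unrefracted) solar elevation at given UTC instants and a fixed
#' position, computed with the standard NOAA low-precision solar ephemeris
#' (mean longitude/anomaly, equation of centre, apparent longitude, corrected
#' obliquity, equation of time). Accuracy is a few hundredths of a degree over
#' the satellite-tag era, far below the illuminance noise of a light logger.
#'
#' @param time `POSIXct` vector (UTC).
#' @param lat,lon position in decimal degrees (north/east positive).
#' @return numeric vector of elevations in degrees above the horizon.
#' @examples
#' t <- as.POSIXct("2015-03-20 12:00:00", tz = "UTC")
#' solarElevation(t, 0, 0)  # near 90: local noon at the equinox
#' @export
solarElevation <- function(time, lat, lon) {
  time <- as.POSIXct(time, tz = "UTC")
  jd <- as.numeric(time) / 86400 + 2440587.5
  jc <- (jd - 2451545) / 36525

  meanLong <- (280.46646 + jc * (36000.76983 + jc * 0.0003032)) %% 360
  meanAnom <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  eccent <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  eqCtr <- sin(deg2rad(meanAnom)) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(deg2rad(2 * meanAnom)) * (0.019993 - 0.000101 * jc) +
    sin(deg2rad(3 * meanAnom)) * 0.000289
  trueLong <- meanLong + eqCtr
  omega <- 125.04 - 1934.136 * jc
  appLong <- trueLong - 0.00569 - 0.00478 * sin(deg2rad(omega))
  meanObliq <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  obliqCorr <- meanObliq + 0.00256 * cos(deg2rad(omega))
  declin <- rad2deg(asin(sin(deg2rad(obliqCorr)) * sin(deg2rad(appLong))))

  varY <- tan(deg2rad(obliqCorr / 2))^2
  eqTimeMin <- 4 * rad2deg(
    varY * sin(2 * deg2rad(meanLong)) -
      2 * eccent * sin(deg2rad(meanAnom)) +
      4 * eccent * varY * sin(deg2rad(meanAnom)) * cos(2 * deg2rad(meanLong)) -
      0.5 * varY^2 * sin(4 * deg2rad(meanLong)) -
      1.25 * eccent^2 * sin(2 * deg2rad(meanAnom))
  )

  minutesUTC <- (as.numeric(time) %% 86400) / 60
  trueSolarMin <- (minutesUTC + eqTimeMin + 4 * lon) %% 1440
  hourAngle <- ifelse(trueSolarMin / 4 < 0, trueSolarMin / 4 + 180, trueSolarMin / 4 - 180)

  zenith <- rad2deg(acos(pmin(1, pmax(-1,
    sin(deg2rad(lat)) * sin(deg2rad(declin)) +
      cos(deg2rad(lat)) * cos(deg2rad(declin)) * cos(deg2rad(hourAngle))
  ))))
  90 - zenith
}

# Closed-form day length (hours) between threshold elevations, from the
# sunrise equation at a fixed declination. Used as an independent oracle for
# the light simulator in the test suite; exported because it is also a handy
# sanity check when configuring tag optics.
#' Day length between solar-elevation crossings
#'
#' Hours per day the sun spends above `elevDeg`, from the closed-form sunrise
#' equation evaluated at solar noon's declination for the given date.
#'
#' @param date a `Date`.
#' @param lat latitude in degrees.
#' @param elevDeg threshold elevation in degrees (0 = geometric horizon).
#' @return day length in hours (0 for polar night, 24 for polar day).
#' @export
dayLengthHours <- function(date, lat, elevDeg = 0) {
  noon <- as.POSIXct(paste(format(date), "12:00:00"), tz = "UTC")
  # declination via the same ephemeris, read off at noon
  jd <- as.numeric(noon) / 86400 + 2440587.5
  jc <- (jd - 2451545) / 36525
  meanLong <- (280.46646 + jc * (36000.76983 + jc * 0.0003032)) %% 360
  meanAnom <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  eqCtr <- sin(deg2rad(meanAnom)) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(deg2rad(2 * meanAnom)) * (0.019993 - 0.000101 * jc) +
    sin(deg2rad(3 * meanAnom)) * 0.000289
  omega <- 125.04 - 1934.136 * jc
  appLong <- meanLong + eqCtr - 0.00569 - 0.00478 * sin(deg2rad(omega))
  meanObliq <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  obliqCorr <- meanObliq + 0.00256 * cos(deg2rad(omega))
  declin <- asin(sin(deg2rad(obliqCorr)) * sin(deg2rad(appLong)))

  cosH <- (sin(deg2rad(elevDeg)) - sin(deg2rad(lat)) * sin(declin)) /
    (cos(deg2rad(lat)) * cos(declin))
  ifelse(cosH >= 1, 0, ifelse(cosH <= -1, 24, 2 * rad2deg(acos(cosH)) / 15))
}
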