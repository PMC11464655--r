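#' Simulate a geolocator light series
#'
#' Renders illuminance at the tag's sampling cadence from solar elevation at
#' the bird's breeding position (an exponential mapping from elevation to
#' lux, clipped at the tag ceiling), attenuated to effectively zero during
#' `in_burrow` intervals, with multiplicative log-normal noise. The mapping
#' is anchored so the working threshold (3 lx by default) is crossed at the
#' configured solar elevation (-1 degree by default).
#'
#' @param bird one row of a `birdTruth` cohort.
#' @param schedule a [behaviourSchedule()] covering the rendered span.
#' @param config a [simConfig()].
#' @return data.frame with columns `timestamp` (POSIXct UTC) and `lux`.
#' @export
simulateLightSeries <- function(bird, schedule, config) {
  s <- config$sensors
  sc <- config$schedule
  year <- as.integer(bird$year)
  spanStart <- doyStartUTC(sc$renderStartDoy, year)
  spanEnd <- doyStartUTC(sc$renderEndDoy + 1, year)
  times <- seq(spanStart, spanEnd - 1, by = s$lightIntervalMin * 60)

  elev <- solarElevation(times, bird$colony_lat, bird$colony_lon)
  a <- log(s$lightThresholdLux) - s$lightLogSlope * s$lightElevAt3lx
  lux <- pmin(s$lightMaxLux, exp(a + s$lightLogSlope * elev))

  state <- scheduleStateAt(schedule, times)
  lux[state == "in_burrow"] <- lux[state == "in_burrow"] * s$burrowAttenuation

  if (s$lightLogSigma > 0) {
    set.seed(birdSeed(config$seed, bird$bird_id, "light"))
    lux <- lux * exp(stats::rnorm(length(lux), 0, s$lightLogSigma))
  }
  lux <- pmax(lux, s$darkLux)
  data.frame(timestamp = times, lux = lux)
}

#' Simulate a salt-water immersion series
#'
#' Draws wet/dry states at the conductivity sampling interval (30 s by
#' default) according to the behaviour schedule (`on_water` wet with high
#' probability, `flying` and `in_burrow` dry), then aggregates them into
#' per-bin wet counts (10-min bins of 20 samples, counts 0-20).
#'
#' @inheritParams simulateLightSeries
#' @param keepStates attach the raw 30-s wet states as attribute `states`
#'   (used by recount oracles).
#' @return data.frame with columns `bin_start` (POSIXct UTC) and `wet_count`.
#' @export
simulateImmersionSeries <- function(bird, schedule, config, keepStates = FALSE) {
  s <- config$sensors
  sc <- config$schedule
  year <- as.integer(bird$year)
  spanStart <- doyStartUTC(sc$renderStartDoy, year)
  spanEnd <- doyStartUTC(sc$renderEndDoy + 1, year)
  perBin <- as.integer(s$immersionBinMin * 60 / s$immersionSampleSec)
  nBins <- as.integer(as.numeric(spanEnd - spanStart, units = "secs") /
                        (s$immersionBinMin * 60))
  times <- spanStart + seq(0, length.out = nBins * perBin, by = s$immersionSampleSec)

  state <- scheduleStateAt(schedule, times)
  p <- c(on_water = s$pWetOnWater, flying = s$pWetFlying,
         in_burrow = s$pWetBurrow)[state]
  set.seed(birdSeed(config$seed, bird$bird_id, "wet"))
  wet <- stats::rbinom(length(p), 1L, p)

  counts <- colSums(matrix(wet, nrow = perBin))
  out <- data.frame(bin_start = spanStart +
                      seq(0, length.out = nBins, by = s$immersionBinMin * 60),
                    wet_count = as.integer(counts))
  if (keepStates) attr(out, "states") <- wet
  out
}

#' Simulate daily winter geolocations
#'
#' One fix per day over the configured winter window, drawn around the
#' bird's true winter centroid with the configured geolocation error SD and
#' snapped to 1-degree grid centres (x.5 degrees).
#'
#' @inheritParams simulateLightSeries
#' @return data.frame with columns `bird_id`, `date`, `lat`, `lon`.
#' @export
simulateWinterFixes <- function(bird, config) {
  year <- as.integer(bird$year)
  dates <- seq(as.Date(sprintf("%d-%s", year, config$winterWindow[1])),
               as.Date(sprintf("%d-%s", year, config$winterWindow[2])),
               by = "day")
  set.seed(birdSeed(config$seed, bird$bird_id, "geo"))
  sdDeg <- config$sensors$geoErrorSDdeg
  lat <- bird$true_wintering_lat + stats::rnorm(length(dates), 0, sdDeg)
  lon <- bird$true_wintering_lon + stats::rnorm(length(dates), 0, sdDeg)
  data.frame(bird_id = bird$bird_id, date = dates,
             lat = snapToGrid(lat), lon = snapToGrid(lon),
             stringsAsFactors = FALSE)
}

# nearest centre of the 1-degree grid (..., -0.5, 0.5, 1.5, ...)
snapToGrid <- function(x, res = 1) floor(x / res) * res + res / 2
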