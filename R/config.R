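#' Default study colonies
#'
#' Twelve northeastern Pacific breeding colonies spanning southern California
#' to the Gulf of Alaska, with approximate island coordinates. These are the
#' default colonies of the synthetic cohort; the latitudinal gradient
#' (roughly 37-59 degrees N) is what drives the colony-latitude covariate.
#'
#' @return data.frame with columns `name`, `region`, `latitude`, `longitude`.
#' @export
defaultColonies <- function() {
  data.frame(
    name = c("Middleton", "StLazaria", "Chowiet", "Lucy", "SGangGwaay",
             "Pine", "Triangle", "Cleland", "Protection", "Destruction",
             "Farallones", "AnoNuevo"),
    region = c("AK", "AK", "AK", "BC", "BC", "BC", "BC", "BC", "WA", "WA",
               "CA", "CA"),
    latitude = c(59.43, 56.99, 56.00, 54.29, 52.09, 50.98, 50.87, 49.17,
                 48.13, 47.67, 37.70, 37.11),
    longitude = c(-146.33, -135.70, -156.70, -130.62, -131.22, -127.73,
                  -129.08, -126.09, -122.92, -124.49, -123.00, -122.34),
    stringsAsFactors = FALSE
  )
}

#' Default cohort design
#'
#' Per-colony, per-year, per-sex tag-recovery counts for the default cohort:
#' 109 birds (59 females, 50 males) across 12 colonies and two study years.
#'
#' @return data.frame with columns `colony`, `year`, `n_female`, `n_male`.
#' @export
defaultDesign <- function() {
  d <- rbind(
    c("Middleton",   "2014", 5, 8),
    c("StLazaria",   "2014", 5, 3),
    c("Chowiet",     "2014", 0, 2),
    c("Lucy",        "2014", 5, 3),
    c("Lucy",        "2015", 6, 3),
    c("SGangGwaay",  "2014", 4, 3),
    c("SGangGwaay",  "2015", 6, 7),
    c("Triangle",    "2014", 12, 0),
    c("Triangle",    "2015", 4, 10),
    c("Pine",        "2014", 1, 1),
    c("Pine",        "2015", 2, 2),
    c("Cleland",     "2014", 0, 1),
    c("Protection",  "2015", 1, 2),
    c("Destruction", "2015", 2, 0),
    c("Farallones",  "2014", 3, 2),
    c("AnoNuevo",    "2014", 3, 3)
  )
  data.frame(colony = d[, 1], year = d[, 2],
             n_female = as.integer(d[, 3]), n_male = as.integer(d[, 4]),
             stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Builds the configuration object consumed by [generateCohort()] and the
#' sensor renderers. Defaults encode the study conditions the package is
#' calibrated to: the 12-colony / 109-bird design, the distance-model and
#' lay-date-model coefficients and variance components used as generating
#' truth, tag sampling characteristics (30-s conductivity samples summarised
#' into 10-min wet counts of 0-20; light at a 5-min cadence with a 3-lx
#' working threshold), the 1 Jan - 28 Feb winter window and a 1 Mar - 31 Jul
#' breeding window.
#'
#' The winter-centroid geometry places centroids on a coastline-like
#' southeast-trending axis. With the default wintering-latitude SD (5 deg),
#' axis slope (-1.15 deg E per deg N) and longitude jitter SD (6 deg), the
#' implied latitude-longitude correlation is
#' \eqn{-1.15 \cdot 5 / \sqrt{(1.15 \cdot 5)^2 + 6^2} = -0.69}, and the
#' colony-latitude to centroid-latitude correlation is set by
#' `winterLatColonyCorr` (0.55).
#'
#' @param colonies colony table as from [defaultColonies()].
#' @param design cohort design as from [defaultDesign()].
#' @param seed root RNG seed; per-bird substreams are derived from it by
#'   stable hashing of bird ids.
#' @param distanceModel named list of generating values for the migration
#'   distance model (km): fixed effects `intercept`, `year2`, `sexF`,
#'   `winteringLatScaled`, and SDs `sdColony`, `sdResidual`.
#' @param laydateModel same for the lay-date model (days): `intercept`,
#'   `year2`, `sexF`, `migrationDistScaled`, `colonyLatScaled`, `sdColony`,
#'   `sdResidual`.
#' @param winterLatMean,winterLatSD mean and SD (degrees) of true wintering
#'   latitude across birds.
#' @param winterLatColonyCorr correlation between colony latitude and true
#'   wintering latitude.
#' @param coastAxis list: `refLat`, `refLon` (an anchor on the axis), `slope`
#'   (deg E per deg N) and `lonJitterSD` (degrees).
#' @param sensors list of tag parameters; see Details in the package
#'   vignette. Includes `geoErrorSDdeg`, the geolocation error SD applied
#'   before snapping daily fixes to 1-degree grid centres.
#' @param schedule list of behaviour-schedule parameters: local exchange hour
#'   of incubation shifts, shift-length jitter SD (h), flights per at-sea
#'   day, prospecting-visit settings, incubation length and the rendered
#'   span (DOY).
#' @param winterWindow month-day strings, closed window of winter fixes.
#' @param breedingWindow DOY pair, closed breeding-season window.
#' @return an object of class `simConfig`.
#' @export
simConfig <- function(colonies = defaultColonies(),
                      design = defaultDesign(),
                      seed = 1L,
                      distanceModel = list(
                        intercept = 766.2, year2 = 40.3, sexF = 12.6,
                        winteringLatScaled = -708.0,
                        sdColony = 856, sdResidual = 267),
                      laydateModel = list(
                        intercept = 129.3, year2 = -5.1, sexF = 2.5,
                        migrationDistScaled = 1.6, colonyLatScaled = 5.2,
                        sdColony = 4.2, sdResidual = 7.3),
                      winterLatMean = 45, winterLatSD = 5,
                      winterLatColonyCorr = 0.55,
                      coastAxis = list(refLat = 50, refLon = -135,
                                       slope = -1.15, lonJitterSD = 6.0),
                      sensors = list(
                        lightIntervalMin = 5, lightThresholdLux = 3,
                        lightMaxLux = 300, lightLogSlope = 0.9,
                        lightElevAt3lx = -1, lightLogSigma = 0.15,
                        burrowAttenuation = 1e-4, darkLux = 1e-6,
                        immersionSampleSec = 30, immersionBinMin = 10,
                        pWetOnWater = 0.98, pWetFlying = 0.02,
                        pWetBurrow = 0, geoErrorSDdeg = 1.0),
                      schedule = list(
                        exchangeHourLocal = 2, shiftJitterSDh = 0.75,
                        flightsPerDay = 2, flightMinutes = 30,
                        prospectVisit = TRUE, prospectDaysBefore = 8,
                        incubationDays = 45,
                        renderStartDoy = 84, renderEndDoy = 186),
                      winterWindow = c("01-01", "02-28"),
                      breedingWindow = c(60, 212)) {
  cfg <- list(colonies = colonies, design = design, seed = as.integer(seed),
              distanceModel = distanceModel, laydateModel = laydateModel,
              winterLatMean = winterLatMean, winterLatSD = winterLatSD,
              winterLatColonyCorr = winterLatColonyCorr,
              coastAxis = coastAxis, sensors = sensors, schedule = schedule,
              winterWindow = winterWindow, breedingWindow = breedingWindow)
  class(cfg) <- "simConfig"
  validateSimConfig(cfg)
  cfg
}

#' @export
print.simConfig <- function(x, ...) {
  n <- sum(x$design$n_female + x$design$n_male)
  cat("simConfig:", nrow(x$colonies), "colonies,", n, "birds, seed", x$seed, "\n")
  cat("  distance model (km):  colony SD", x$distanceModel$sdColony,
      "| residual SD", x$distanceModel$sdResidual, "\n")
  cat("  lay-date model (days): colony SD", x$laydateModel$sdColony,
      "| residual SD", x$laydateModel$sdResidual, "\n")
  invisible(x)
}

validateSimConfig <- function(cfg) {
  stopifnot(inherits(cfg, "simConfig"))
  co <- cfg$colonies
  if (any(co$latitude < -90 | co$latitude > 90))
    stop("config error: colony latitude outside [-90, 90]")
  if (any(co$longitude <= -180 | co$longitude > 180))
    stop("config error: colony longitude outside (-180, 180]")
  if (!all(cfg$design$colony %in% co$name))
    stop("config error: design references unknown colonies")
  sds <- c(cfg$distanceModel$sdColony, cfg$distanceModel$sdResidual,
           cfg$laydateModel$sdColony, cfg$laydateModel$sdResidual,
           cfg$winterLatSD, cfg$coastAxis$lonJitterSD,
           cfg$sensors$geoErrorSDdeg, cfg$sensors$lightLogSigma,
           cfg$schedule$shiftJitterSDh)
  if (any(sds < 0)) stop("config error: negative standard deviation")
  s <- cfg$sensors
  if ((s$immersionBinMin * 60) %% s$immersionSampleSec != 0)
    stop("config error: immersion sampling interval must divide the bin width")
  invisible(TRUE)
}

#' Turn off all sensor and schedule noise
#'
#' Convenience modifier producing the "noiseless" rendering regime used to
#' check exact recovery of ground truth: wet probabilities 1/0/0, no light
#' noise, no geolocation error, no shift-length jitter. Model-level SDs
#' (colony and residual) are untouched unless `models = TRUE`.
#'
#' @param cfg a `simConfig`.
#' @param models also zero the mixed-model variance components.
#' @return modified `simConfig`.
#' @export
noiselessConfig <- function(cfg, models = FALSE) {
  cfg$sensors$lightLogSigma <- 0
  cfg$sensors$pWetOnWater <- 1
  cfg$sensors$pWetFlying <- 0
  cfg$sensors$pWetBurrow <- 0
  cfg$sensors$geoErrorSDdeg <- 0
  cfg$schedule$shiftJitterSDh <- 0
  if (models) {
    cfg$distanceModel$sdColony <- 0
    cfg$distanceModel$sdResidual <- 0
    cfg$laydateModel$sdColony <- 0
    cfg$laydateModel$sdResidual <- 0
    cfg$winterLatSD <- cfg$winterLatSD  # latitude spread kept: it is signal
  }
  validateSimConfig(cfg)
  cfg
}

#' Read / write a simulation configuration as YAML
#'
#' @param path file path.
#' @param cfg a `simConfig`.
#' @return `readSimConfig` returns a `simConfig`; `writeSimConfig` the path,
#'   invisibly.
#' @export
readSimConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  colonies <- do.call(rbind.data.frame, c(raw$colonies, stringsAsFactors = FALSE))
  design <- do.call(rbind.data.frame, c(raw$design, stringsAsFactors = FALSE))
  design$n_female <- as.integer(design$n_female)
  design$n_male <- as.integer(design$n_male)
  args <- raw[setdiff(names(raw), c("colonies", "design"))]
  do.call(simConfig, c(list(colonies = colonies, design = design), args))
}

#' @rdname readSimConfig
#' @export
writeSimConfig <- function(cfg, path) {
  out <- unclass(cfg)
  out$colonies <- lapply(seq_len(nrow(cfg$colonies)),
                         function(i) as.list(cfg$colonies[i, ]))
  out$design <- lapply(seq_len(nrow(cfg$design)),
                       function(i) as.list(cfg$design[i, ]))
  yaml::write_yaml(out, path)
  invisible(path)
}
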