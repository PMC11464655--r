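# Fixtures are built in code: small cohorts, hand-made light days and
# immersion series with known structure.

# a three-colony, six-bird design spanning the latitude range
tinyConfig <- function(seed = 1, ...) {
  colonies <- defaultColonies()[c(1, 7, 11), ]
  design <- data.frame(colony = colonies$name,
                       year = c("2014", "2014", "2015"),
                       n_female = c(2L, 2L, 2L), n_male = c(2L, 2L, 2L),
                       stringsAsFactors = FALSE)
  simConfig(colonies = colonies, design = design, seed = seed, ...)
}

# noiseless square-wave light day(s): 0.1 lx at night, 100 lx between
# `riseH` and `setH` (UTC hours), sampled every `stepMin` minutes
squareLightDays <- function(days, riseH = 6, setH = 18, stepMin = 5,
                            origin = as.POSIXct("2015-04-01", tz = "UTC")) {
  ts <- seq(origin, origin + days * 86400 - 1, by = stepMin * 60)
  h <- (as.numeric(ts) %% 86400) / 3600
  data.frame(timestamp = ts, lux = ifelse(h >= riseH & h < setH, 100, 0.1))
}

# immersion bins at 10-min cadence from a wet-count vector
binsFrom <- function(counts, origin = as.POSIXct("2015-04-01", tz = "UTC")) {
  data.frame(bin_start = origin + (seq_along(counts) - 1) * 600,
             wet_count = as.integer(counts))
}

# events table helper
mkEvents <- function(times, kinds) {
  ev <- data.frame(timestamp = as.POSIXct(times, tz = "UTC"), kind = kinds,
                   flagged = FALSE, stringsAsFactors = FALSE)
  class(ev) <- c("twilightEvents", "data.frame")
  ev
}

# run the phenology chain for one simulated bird, returning per-method lay
# estimates alongside the truth
phenologyForBird <- function(bird, cfg) {
  sched <- behaviourSchedule(bird, cfg)
  light <- simulateLightSeries(bird, sched, cfg)
  wet <- simulateImmersionSeries(bird, sched, cfg)
  ev <- suppressMessages(suppressWarnings(
    resolveFlagged(flagShortIntervals(detectTwilights(light)))))
  bd <- detectBurrowDays(ev, bird$colony_lon)
  sp <- findDrySpells(wet)
  est <- function(bouts) {
    on <- inferIncubationStart(bouts, breedingWindow = cfg$breedingWindow)
    estimateLayDate(on$doy, bird$sex, year = as.integer(bird$year))$lay_doy
  }
  c(light = est(mergeEvidence(bd, sp[0, ], bird$colony_lon)),
    immersion = est(mergeEvidence(bd[0, ], sp, bird$colony_lon)),
    combined = est(mergeEvidence(bd, sp, bird$colony_lon)),
    true = bird$lay_day)
}
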