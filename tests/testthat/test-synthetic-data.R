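test_that("default cohort reproduces the multi-colony design exactly", {
  co <- generateCohort(simConfig(seed = 3))
  expect_equal(nrow(co), 109)
  expect_equal(length(unique(co$colony)), 12)
  expect_equal(sum(co$sex == "F"), 59)
  expect_equal(sum(co$sex == "M"), 50)
  # per-colony / per-sex / per-year counts conserved
  des <- defaultDesign()
  got <- as.data.frame(table(co$colony, co$year, co$sex))
  for (i in seq_len(nrow(des))) {
    expect_equal(sum(co$colony == des$colony[i] & co$year == des$year[i] &
                       co$sex == "F"), des$n_female[i])
    expect_equal(sum(co$colony == des$colony[i] & co$year == des$year[i] &
                       co$sex == "M"), des$n_male[i])
  }
})

test_that("cohort generation errors on empty or invalid configs", {
  cfg <- tinyConfig()
  cfg$design$n_female <- cfg$design$n_male <- 0L
  expect_error(generateCohort(cfg), "empty cohort")
  cfg2 <- tinyConfig()
  cfg2$distanceModel$sdResidual <- -1
  expect_error(generateCohort(cfg2), "negative standard deviation")
})

test_that("zero-noise cohorts reproduce the generating equations exactly", {
  cfg <- simConfig(seed = 2)
  cfg$distanceModel$sdColony <- cfg$distanceModel$sdResidual <- 0
  cfg$laydateModel$sdColony <- cfg$laydateModel$sdResidual <- 0
  # wintering latitude keeps its spread: it is a covariate, not noise
  co <- generateCohort(cfg)
  # deterministic linear predictor, recomputed independently
  zW <- scale(co$true_wintering_lat)[, 1]
  zD <- scale(co$true_distance_km)[, 1]
  zC <- scale(co$colony_lat)[, 1]
  dm <- cfg$distanceModel; lm2 <- cfg$laydateModel
  y2 <- as.numeric(co$year == "2015"); fF <- as.numeric(co$sex == "F")
  expect_equal(co$true_distance_km,
               dm$intercept + dm$year2 * y2 + dm$sexF * fF +
                 dm$winteringLatScaled * zW, tolerance = 1e-12)
  expect_equal(co$true_lay_doy,
               lm2$intercept + lm2$year2 * y2 + lm2$sexF * fF +
                 lm2$migrationDistScaled * zD + lm2$colonyLatScaled * zC,
               tolerance = 1e-12)
  # generative consistency: a plain regression returns the coefficients to
  # machine precision
  fit <- lm(co$true_distance_km ~ y2 + fF + zW)
  expect_equal(unname(coef(fit)),
               c(dm$intercept, dm$year2, dm$sexF, dm$winteringLatScaled),
               tolerance = 1e-9)
})

test_that("lay-date residual spread matches the configured SD via stored draws", {
  colonies <- defaultColonies()[1:4, ]
  design <- data.frame(colony = colonies$name, year = "2014",
                       n_female = 125L, n_male = 125L)
  cfg <- simConfig(colonies = colonies, design = design, seed = 9)
  co <- generateCohort(cfg)
  expect_equal(nrow(co), 1000)
  # residual-free twin run isolates the drawn residual term exactly
  cfg0 <- cfg; cfg0$laydateModel$sdResidual <- 0
  co0 <- generateCohort(cfg0)
  resid <- co$true_lay_doy - co0$true_lay_doy
  expect_equal(resid, co$draw_lay * cfg$laydateModel$sdResidual,
               tolerance = 1e-10)
  expect_lt(abs(sd(resid) - cfg$laydateModel$sdResidual),
            0.1 * cfg$laydateModel$sdResidual)
})

test_that("identical config and seed give identical cohorts; extra birds do not reshuffle existing ones", {
  cfg <- tinyConfig(seed = 42)
  expect_identical(generateCohort(cfg), generateCohort(cfg))
  big <- cfg
  big$design$n_female[1] <- 3L  # two more females at the first colony
  co <- generateCohort(cfg)
  cob <- generateCohort(big)
  shared <- match(co$bird_id, cob$bird_id)
  expect_false(any(is.na(shared)))
  # the per-bird residual draws are substream-stable
  expect_equal(co$draw_wlat, cob$draw_wlat[shared])
  expect_equal(co$draw_dist, cob$draw_dist[shared])
  expect_equal(co$draw_lay, cob$draw_lay[shared])
})

test_that("default spatial calibration yields the documented correlations", {
  co <- generateCohort(simConfig(seed = 13))
  r1 <- pearsonCor(co$true_wintering_lat, co$true_wintering_lon)
  expect_lt(r1$r, -0.5)           # coastline axis: south <-> east
  expect_gt(r1$r, -0.85)          # calibrated near -0.69
  r2 <- pearsonCor(co$colony_lat, co$true_wintering_lat)
  expect_gt(r2$r, 0.35)           # calibrated near 0.55
})

test_that("winter fixes: 59 days, grid snapping, and unbiasedness", {
  cfg <- tinyConfig(seed = 5)
  co <- generateCohort(cfg)
  fx <- simulateWinterFixes(co[1, ], cfg)
  expect_equal(nrow(fx), 59)
  expect_true(all(fx$lat %% 1 == 0.5), all(fx$lon %% 1 == 0.5))

  cfg0 <- cfg; cfg0$sensors$geoErrorSDdeg <- 0
  fx0 <- simulateWinterFixes(co[1, ], cfg0)
  expect_equal(unique(fx0$lat), floor(co$true_wintering_lat[1]) + 0.5)
  expect_equal(unique(fx0$lon), floor(co$true_wintering_lon[1]) + 0.5)

  # Monte-Carlo mean over ~10,000 fixes approaches the true centroid
  many <- do.call(rbind, lapply(1:170, function(s) {
    cfgS <- cfg; cfgS$seed <- 1000 + s
    simulateWinterFixes(co[1, ], cfgS)
  }))
  expect_gt(nrow(many), 10000 - 100)
  expect_lt(abs(mean(many$lat) - co$true_wintering_lat[1]), 0.05)
  expect_lt(abs(mean(many$lon) - co$true_wintering_lon[1]), 0.05)
})

test_that("light simulator matches solar geometry at reference positions", {
  cfg <- noiselessConfig(tinyConfig())
  cfg$schedule$renderStartDoy <- 78  # around the March equinox
  cfg$schedule$renderEndDoy <- 80
  bird <- data.frame(bird_id = "eq", colony = "x", colony_lat = 0,
                     colony_lon = 0, sex = "M", year = "2015", lay_day = 999L)
  sched <- data.frame(start = doyStart <- as.POSIXct("2015-03-19", tz = "UTC"),
                      end = as.POSIXct("2015-03-22", tz = "UTC"),
                      state = "on_water")
  light <- simulateLightSeries(bird, sched, cfg)
  ev <- detectTwilights(light, 3)
  day20 <- ev[as.Date(ev$timestamp) == as.Date("2015-03-20"), ]
  gapH <- diff(as.numeric(day20$timestamp)) / 3600
  expect_equal(day20$kind, c("sunrise", "sunset"))
  expect_lt(abs(gapH - 12), 10 / 60)  # equinox symmetry at the equator

  # 60 N on the June solstice: threshold-crossing day length vs the
  # closed-form sunrise-equation oracle
  cfg$schedule$renderStartDoy <- 171; cfg$schedule$renderEndDoy <- 173
  bird60 <- transform(bird, colony_lat = 60)
  sched60 <- data.frame(start = as.POSIXct("2015-06-19", tz = "UTC"),
                        end = as.POSIXct("2015-06-24", tz = "UTC"),
                        state = "on_water")
  light60 <- simulateLightSeries(bird60, sched60, cfg)
  ev60 <- detectTwilights(light60, 3)
  d <- as.Date("2015-06-21")
  rise <- ev60$timestamp[ev60$kind == "sunrise" & as.Date(ev60$timestamp) == d]
  set <- ev60$timestamp[ev60$kind == "sunset" & as.Date(ev60$timestamp) == d]
  measured <- as.numeric(set[1]) - as.numeric(rise[1])
  oracle <- dayLengthHours(d, 60, elevDeg = cfg$sensors$lightElevAt3lx) * 3600
  expect_lt(abs(measured - oracle), 10 * 60)
})

test_that("a burrow interval spanning daylight suppresses all light that day", {
  cfg <- noiselessConfig(tinyConfig())
  bird <- data.frame(bird_id = "b", colony = "x", colony_lat = 50,
                     colony_lon = -128, sex = "F", year = "2015",
                     lay_day = 999L)
  spanStart <- as.POSIXct("2015-05-01", tz = "UTC")
  spanEnd <- as.POSIXct("2015-05-04", tz = "UTC")
  cfg$schedule$renderStartDoy <- 121; cfg$schedule$renderEndDoy <- 123
  burrowFrom <- as.POSIXct("2015-05-02 06:00:00", tz = "UTC")
  burrowTo <- as.POSIXct("2015-05-03 12:00:00", tz = "UTC")
  sched <- data.frame(start = c(spanStart, burrowFrom, burrowTo),
                      end = c(burrowFrom, burrowTo, spanEnd),
                      state = c("on_water", "in_burrow", "on_water"))
  light <- simulateLightSeries(bird, sched, cfg)
  inDay <- as.Date(light$timestamp + bird$colony_lon / 15 * 3600) ==
    as.Date("2015-05-02")
  expect_true(all(light$lux[inDay] < 3))
})

test_that("immersion simulator honours the schedule and the 0-20 bin range", {
  cfg <- noiselessConfig(tinyConfig())
  cfg$schedule$renderStartDoy <- 100; cfg$schedule$renderEndDoy <- 101
  bird <- data.frame(bird_id = "w", colony = "x", colony_lat = 50,
                     colony_lon = -128, sex = "M", year = "2015",
                     lay_day = 999L)
  spanStart <- doyStartUTC <- as.POSIXct("2015-04-10", tz = "UTC")
  spanEnd <- as.POSIXct("2015-04-12", tz = "UTC")
  allWater <- data.frame(start = spanStart, end = spanEnd, state = "on_water")
  wet <- simulateImmersionSeries(bird, allWater, cfg)
  expect_true(all(wet$wet_count == 20))  # saturated: wet probability 1

  # an injected 8-h burrow interval produces >= 48 consecutive zero bins
  b0 <- as.POSIXct("2015-04-10 20:00:00", tz = "UTC")
  sched <- data.frame(start = c(spanStart, b0, b0 + 8 * 3600),
                      end = c(b0, b0 + 8 * 3600, spanEnd),
                      state = c("on_water", "in_burrow", "on_water"))
  wet2 <- simulateImmersionSeries(bird, sched, cfg)
  runs <- rle(wet2$wet_count == 0)
  expect_gte(max(runs$lengths[runs$values]), 48)

  # recount oracle: wet fraction of raw states matches the schedule's
  # on-water time fraction under realistic wet probabilities
  cfgN <- tinyConfig()
  cfgN$schedule$renderStartDoy <- 100; cfgN$schedule$renderEndDoy <- 101
  wet3 <- simulateImmersionSeries(bird, sched, cfgN, keepStates = TRUE)
  states <- attr(wet3, "states")
  waterFrac <- (as.numeric(spanEnd - spanStart, units = "secs") - 8 * 3600) /
    as.numeric(spanEnd - spanStart, units = "secs")
  wetFrac <- sum(wet3$wet_count) / (nrow(wet3) * 20)
  expect_lt(abs(wetFrac - waterFrac * cfgN$sensors$pWetOnWater), 0.02)
  expect_equal(sum(wet3$wet_count), sum(states))  # bins are exact recounts
})

test_that("schedule gaps are detected", {
  cfg <- tinyConfig()
  cfg$schedule$renderStartDoy <- 100; cfg$schedule$renderEndDoy <- 101
  bird <- data.frame(bird_id = "g", colony = "x", colony_lat = 50,
                     colony_lon = -128, sex = "M", year = "2015",
                     lay_day = 999L)
  gappy <- data.frame(start = as.POSIXct("2015-04-10 06:00:00", tz = "UTC"),
                      end = as.POSIXct("2015-04-11", tz = "UTC"),
                      state = "on_water")
  expect_error(simulateLightSeries(bird, gappy, cfg), "schedule gap")
})

test_that("config YAML round-trips", {
  cfg <- tinyConfig(seed = 8)
  path <- tempfile(fileext = ".yaml")
  writeSimConfig(cfg, path)
  cfg2 <- readSimConfig(path)
  expect_equal(cfg2$colonies$latitude, cfg$colonies$latitude)
  expect_equal(cfg2$design$n_male, cfg$design$n_male)
  expect_equal(cfg2$distanceModel, cfg$distanceModel)
  expect_identical(generateCohort(cfg2), generateCohort(cfg))
})
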