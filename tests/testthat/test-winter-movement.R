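test_that("winter window selection keeps the closed 1 Jan - 28 Feb window", {
  dates <- seq(as.Date("2015-01-01"), as.Date("2015-12-31"), by = "day")
  fixes <- data.frame(bird_id = "b", date = dates, lat = 50.5, lon = -130.5)
  win <- selectWinterFixes(fixes)
  expect_equal(nrow(win), 59)
  expect_equal(range(win$date), as.Date(c("2015-01-01", "2015-02-28")))

  expect_equal(nrow(selectWinterFixes(fixes[0, ])), 0)
  march <- fixes[format(fixes$date, "%m") == "03", ]
  expect_equal(nrow(selectWinterFixes(march)), 0)
})

test_that("haversine distance agrees with closed forms and is a metric", {
  expect_equal(haversineKm(50, -130, 50, -130), 0)
  # antipodal points: half the circumference
  expect_equal(haversineKm(0, 0, 0, 180), pi * 6371.0088, tolerance = 1e-9)
  expect_error(haversineKm(95, 0, 0, 0), "latitude")

  # oracle: spherical law of cosines, within 1 m on 100 random pairs
  set.seed(12)
  R <- 6371.0088
  for (i in 1:100) {
    p <- runif(4, c(-80, -179, -80, -179), c(80, 179, 80, 179))
    slc <- R * acos(pmin(1, pmax(-1,
      sin(p[1] * pi / 180) * sin(p[3] * pi / 180) +
        cos(p[1] * pi / 180) * cos(p[3] * pi / 180) *
        cos((p[4] - p[2]) * pi / 180))))
    expect_lt(abs(haversineKm(p[1], p[2], p[3], p[4]) - slc), 1e-3)
  }

  # symmetry, non-negativity, identity, triangle inequality on random triples
  set.seed(13)
  for (i in 1:50) {
    q <- matrix(runif(6, c(-80, -170), c(80, 170)), ncol = 2, byrow = TRUE)
    dab <- haversineKm(q[1, 1], q[1, 2], q[2, 1], q[2, 2])
    dba <- haversineKm(q[2, 1], q[2, 2], q[1, 1], q[1, 2])
    dbc <- haversineKm(q[2, 1], q[2, 2], q[3, 1], q[3, 2])
    dac <- haversineKm(q[1, 1], q[1, 2], q[3, 1], q[3, 2])
    expect_equal(dab, dba)
    expect_gte(dab, 0)
    expect_lte(dac, dab + dbc + 1e-9)
  }
})

test_that("kernel UD normalises mass and handles degenerate tracks", {
  set.seed(41)
  fixes <- data.frame(lat = 45 + rnorm(300, 0, 1.2), lon = -135 + rnorm(300, 0, 1.6))
  ud <- kernelUD(fixes)
  expect_lt(abs(sum(ud$mass) - 1), 1e-9)
  expect_true(all(ud$density >= 0))

  # doubling the grid resolution barely changes the raw (pre-normalisation)
  # integral
  ud2 <- kernelUD(fixes, gridN = 200)
  expect_lt(abs(ud$rawMass - ud2$rawMass), 1e-6)

  # identical fixes: point mass at that location
  same <- data.frame(lat = rep(47.5, 10), lon = rep(-133.5, 10))
  udd <- kernelUD(same)
  ctr <- udCentroid(udd)
  expect_equal(unname(ctr["lat"]), 47.5)
  expect_equal(unname(ctr["lon"]), -133.5)

  expect_error(kernelUD(fixes[1:3, ]), "too few fixes")
})

test_that("the 90% level set holds 90% of the mass on a large Gaussian cloud", {
  set.seed(3)
  n <- 5000
  fixes <- data.frame(lat = 45 + rnorm(n, 0, 1.5), lon = -135 + rnorm(n, 0, 2))
  ud <- kernelUD(fixes, gridN = 100)
  ctr <- udCentroid(ud, level = 0.9)
  # numeric-integration oracle: sum cell masses over the selected set
  enclosed <- attr(ctr, "levelMass")
  expect_gte(enclosed, 0.89)
  expect_lte(enclosed, 0.91)
  expect_lt(abs(unname(ctr["lat"]) - 45), 0.1)
  expect_lt(abs(unname(ctr["lon"]) + 135), 0.1)
})

test_that("level-set centroids behave for symmetric, bimodal and full-mass cases", {
  set.seed(8)
  sym <- data.frame(lat = 50 + rnorm(2000, 0, 1), lon = -130 + rnorm(2000, 0, 1))
  ud <- kernelUD(sym)
  ctr <- udCentroid(ud, 0.9)
  cell <- diff(ud$gy[1:2]) / 111  # one cell, in degrees of latitude
  expect_lt(abs(unname(ctr["lat"]) - 50), max(cell, 0.06))

  # two equal symmetric clusters inside the 90% set: centroid at the midpoint
  bi <- data.frame(lat = c(49 + rnorm(1500, 0, 0.4), 51 + rnorm(1500, 0, 0.4)),
                   lon = -130 + rnorm(3000, 0, 0.4))
  ctr2 <- udCentroid(kernelUD(bi), 0.9)
  expect_lt(abs(unname(ctr2["lat"]) - 50), 0.1)

  # level = 1: the density-weighted mean of the full grid (direct oracle)
  ud3 <- kernelUD(sym, gridN = 60)
  ctr3 <- udCentroid(ud3, 1.0)
  w <- ud3$mass
  mx <- sum(outer(ud3$gx, rep(1, length(ud3$gy))) * w)
  my <- sum(outer(rep(1, length(ud3$gx)), ud3$gy) * w)
  oracle <- burrowclock:::unprojectAeqd(mx, my, ud3$center, ud3$radiusKm)
  expect_equal(unname(ctr3["lat"]), unname(oracle["lat"]), tolerance = 1e-9)
  expect_equal(unname(ctr3["lon"]), unname(oracle["lon"]), tolerance = 1e-9)
})

test_that("dateline-crossing tracks are rejected", {
  fixes <- data.frame(lat = rep(50, 10), lon = c(rep(179.5, 5), rep(-179.5, 5)))
  expect_error(kernelUD(fixes), "dateline")
})

test_that("migration summary chains window, UD, centroid and distance", {
  colony <- list(name = "c", latitude = 50.87, longitude = -129.08)
  dates <- seq(as.Date("2015-01-01"), as.Date("2015-02-28"), by = "day")
  # fixes centred on the colony: distance ~ 0 (within grid/KDE resolution)
  set.seed(5)
  at <- data.frame(bird_id = "b1", date = dates,
                   lat = colony$latitude + rnorm(59, 0, 0.3),
                   lon = colony$longitude + rnorm(59, 0, 0.3))
  ms <- migrationSummary(at, colony)
  expect_lt(ms$migration_distance_km, 30)

  # fixes 1 degree due south: meridian arc oracle R * pi/180
  south <- data.frame(bird_id = "b2", date = dates,
                      lat = colony$latitude - 1, lon = colony$longitude)
  ms2 <- migrationSummary(south, colony)
  expect_lt(abs(ms2$migration_distance_km - 6371.0088 * pi / 180), 1.5)

  # too few winter fixes: NA record with a note, not an error
  few <- at[1:3, ]
  ms3 <- migrationSummary(few, colony)
  expect_true(is.na(ms3$migration_distance_km))
  expect_match(ms3$note, "no-centroid")
})

test_that("recovered distances track generator truth and shrink with fix error", {
  cfg <- tinyConfig(seed = 31)
  co <- generateCohort(cfg)
  disp <- sapply(c(0.25, 1, 3), function(sdDeg) {
    cfgS <- cfg
    cfgS$sensors$geoErrorSDdeg <- sdDeg
    rec <- do.call(rbind, lapply(seq_len(nrow(co)), function(i) {
      b <- co[i, ]
      migrationSummary(simulateWinterFixes(b, cfgS),
                       list(name = b$colony, latitude = b$colony_lat,
                            longitude = b$colony_lon))
    }))
    if (sdDeg == 1) {
      geomTrue <- haversineKm(co$true_wintering_lat, co$true_wintering_lon,
                              co$colony_lat, co$colony_lon)
      expect_gt(cor(rec$migration_distance_km, geomTrue), 0.98)
    }
    median(sqrt((rec$wintering_latitude - co$true_wintering_lat)^2 +
                  (rec$wintering_longitude - co$true_wintering_lon)^2))
  })
  expect_true(all(diff(disp) > 0))  # error SD up, displacement up
})
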