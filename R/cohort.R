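#' Generate a cohort of birds with known ground truth
#'
#' Draws a multi-colony cohort from the configured design and the two
#' generating linear mixed models. Each bird receives a colony random
#' intercept (one draw per colony per model), a true wintering latitude
#' correlated with its colony's latitude, a true migration distance from the
#' distance-model equation, a true lay date (day of year) from the lay-date
#' model equation, and a true winter centroid placed on the coastline-like
#' axis at its wintering latitude.
#'
#' Continuous covariates enter the generating equations after within-cohort
#' z-scaling, the same convention the analysis models use, so a cohort
#' generated with all SDs set to zero reproduces the configured coefficients
#' exactly when refit.
#'
#' Per-bird residual draws come from RNG substreams keyed by a stable hash of
#' the bird id and the root seed, so enlarging the design leaves the draws of
#' existing birds unchanged.
#'
#' @param config a [simConfig()].
#' @return data.frame of class `birdTruth`, one row per bird: identifiers and
#'   design columns (`bird_id`, `colony`, `region`, `colony_lat`,
#'   `colony_lon`, `sex`, `year`), ground truth (`true_wintering_lat`,
#'   `true_wintering_lon`, `true_distance_km`, `true_lay_doy`, `lay_day` --
#'   the integer day the egg is laid, used by the sensor renderers), and the
#'   raw residual draws (`draw_wlat`, `draw_dist`, `draw_lay`) retained for
#'   oracle checks. Colony effects are attached as attribute
#'   `colonyEffects`.
#' @export
generateCohort <- function(config) {
  validateSimConfig(config)
  des <- config$design
  nb <- sum(des$n_female + des$n_male)
  if (nrow(des) == 0 || nb == 0)
    stop("empty cohort: design contains no birds")

  co <- config$colonies
  rows <- do.call(rbind, lapply(seq_len(nrow(des)), function(i) {
    n <- c(des$n_female[i], des$n_male[i])
    if (sum(n) == 0) return(NULL)
    data.frame(colony = des$colony[i], year = des$year[i],
               sex = rep(c("F", "M"), n),
               idx = c(seq_len(n[1]), seq_len(n[2])),
               stringsAsFactors = FALSE)
  }))
  rows$bird_id <- sprintf("%s_%s_%s%02d", rows$colony, rows$year, rows$sex,
                          rows$idx)
  m <- match(rows$colony, co$name)
  rows$region <- co$region[m]
  rows$colony_lat <- co$latitude[m]
  rows$colony_lon <- co$longitude[m]

  # colony-level draws under the root seed, in stable (design) colony order
  colonyNames <- unique(des$colony)
  set.seed(config$seed)
  uDist <- stats::rnorm(length(colonyNames), 0, config$distanceModel$sdColony)
  uLay <- stats::rnorm(length(colonyNames), 0, config$laydateModel$sdColony)
  names(uDist) <- names(uLay) <- colonyNames

  # bird-level draws from per-bird substreams
  draws <- t(vapply(rows$bird_id, function(id) {
    set.seed(birdSeed(config$seed, id, "truth"))
    stats::rnorm(4)
  }, numeric(4)))
  rows$draw_wlat <- draws[, 1]
  rows$draw_dist <- draws[, 2]
  rows$draw_lay <- draws[, 3]
  drawLon <- draws[, 4]

  # true wintering latitude: colony-latitude component + bird-level spread
  rc <- config$winterLatColonyCorr
  sC <- stats::sd(rows$colony_lat)
  latSlope <- if (is.finite(sC) && sC > 0) rc * config$winterLatSD / sC else 0
  rows$true_wintering_lat <- config$winterLatMean +
    latSlope * (rows$colony_lat - mean(rows$colony_lat)) +
    rows$draw_wlat * config$winterLatSD * sqrt(1 - rc^2)

  # migration distance from the distance-model equation
  dm <- config$distanceModel
  yrLevels <- sort(unique(des$year))
  year2 <- if (length(yrLevels) > 1) as.numeric(rows$year == yrLevels[2]) else
    rep(0, nrow(rows))
  isF <- as.numeric(rows$sex == "F")
  zW <- scaleOrZero(rows$true_wintering_lat)
  rows$true_distance_km <- dm$intercept + dm$year2 * year2 + dm$sexF * isF +
    dm$winteringLatScaled * zW + uDist[rows$colony] +
    rows$draw_dist * dm$sdResidual

  # lay date from the lay-date-model equation
  lm2 <- config$laydateModel
  zD <- scaleOrZero(rows$true_distance_km)
  zC <- scaleOrZero(rows$colony_lat)
  rows$true_lay_doy <- lm2$intercept + lm2$year2 * year2 + lm2$sexF * isF +
    lm2$migrationDistScaled * zD + lm2$colonyLatScaled * zC +
    uLay[rows$colony] + rows$draw_lay * lm2$sdResidual
  rows$lay_day <- as.integer(round(rows$true_lay_doy))

  # winter centroid on the coastline axis at the true wintering latitude
  ax <- config$coastAxis
  rows$true_wintering_lon <- ax$refLon +
    ax$slope * (rows$true_wintering_lat - ax$refLat) +
    drawLon * ax$lonJitterSD

  rows$idx <- NULL
  rows <- rows[, c("bird_id", "colony", "region", "colony_lat", "colony_lon",
                   "sex", "year", "true_wintering_lat", "true_wintering_lon",
                   "true_distance_km", "true_lay_doy", "lay_day",
                   "draw_wlat", "draw_dist", "draw_lay")]
  attr(rows, "colonyEffects") <- data.frame(
    colony = colonyNames, dist_intercept = unname(uDist),
    lay_intercept = unname(uLay), stringsAsFactors = FALSE)
  class(rows) <- c("birdTruth", "data.frame")
  rows
}

#' @export
print.birdTruth <- function(x, ...) {
  cat("birdTruth cohort:", nrow(x), "birds,",
      length(unique(x$colony)), "colonies;",
      sum(x$sex == "F"), "F /", sum(x$sex == "M"), "M\n")
  print.data.frame(utils::head(as.data.frame(x), 5), digits = 4)
  if (nrow(x) > 5) cat("...", nrow(x) - 5, "more rows\n")
  invisible(x)
}

#' Analysis records from generator ground truth
#'
#' Maps a `birdTruth` cohort to the one-row-per-bird record table the mixed
#' models consume, using the true (generator) values for migration distance,
#' wintering latitude and lay date. This is the truth-side entry point for
#' simulation-based parameter recovery; the pipeline's estimate-side
#' counterpart is assembled from the sensor-inference outputs.
#'
#' @param cohort a `birdTruth` data.frame from [generateCohort()].
#' @return data.frame with columns `bird_id`, `colony`, `sex`, `year`,
#'   `migration_distance_km`, `wintering_latitude`, `colony_latitude`,
#'   `lay_doy`.
#' @export
recordsFromTruth <- function(cohort) {
  data.frame(bird_id = cohort$bird_id, colony = cohort$colony,
             sex = cohort$sex, year = cohort$year,
             migration_distance_km = cohort$true_distance_km,
             wintering_latitude = cohort$true_wintering_lat,
             colony_latitude = cohort$colony_lat,
             lay_doy = cohort$true_lay_doy,
             stringsAsFactors = FALSE)
}
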