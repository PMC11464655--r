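#' Find dry spells in an immersion series
#'
#' Burrow occupancy is inferred from extended dryness: maximal runs of fully
#' dry bins (wet count at or below `maxWetPerBin`, 0 by default) lasting at
#' least `minHours` (5 h by default) within the breeding-season window.
#'
#' @param bins data.frame with contiguous 10-min columns `bin_start`
#'   (POSIXct UTC) and `wet_count` (0-20).
#' @param minHours minimum spell duration in hours.
#' @param maxWetPerBin wet-count tolerance for a "dry" bin (splash
#'   artifacts).
#' @param window optional POSIXct length-2 vector; bins outside the closed
#'   window are ignored.
#' @return data.frame with columns `start`, `end` (POSIXct), `duration_h`,
#'   `n_bins`.
#' @export
findDrySpells <- function(bins, minHours = 5, maxWetPerBin = 0, window = NULL) {
  if (!is.null(window)) {
    keep <- bins$bin_start >= window[1] & bins$bin_start <= window[2]
    bins <- bins[keep, ]
  }
  empty <- data.frame(start = as.POSIXct(numeric(0), origin = "1970-01-01",
                                         tz = "UTC"),
                      end = as.POSIXct(numeric(0), origin = "1970-01-01",
                                       tz = "UTC"),
                      duration_h = numeric(0), n_bins = integer(0))
  if (nrow(bins) == 0) return(empty)
  dt <- diff(as.numeric(bins$bin_start))
  binSec <- if (length(dt)) min(dt) else 600
  if (length(dt) && any(dt != binSec)) {
    gaps <- which(dt != binSec)
    stop("immersion series has gaps after: ",
         paste(format(bins$bin_start[gaps]), collapse = ", "))
  }
  if (any(bins$wet_count < 0 | bins$wet_count > 20))
    stop("wet_count outside [0, 20]")

  r <- rle(bins$wet_count <= maxWetPerBin)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  dry <- which(r$values & r$lengths * binSec / 3600 >= minHours)
  if (length(dry) == 0) return(empty)
  data.frame(
    start = bins$bin_start[starts[dry]],
    end = bins$bin_start[ends[dry]] + binSec,
    duration_h = r$lengths[dry] * binSec / 3600,
    n_bins = r$lengths[dry])
}

#' Merge light and immersion occupancy evidence
#'
#' Produces calendar-day-resolution burrow-occupancy bouts from the union of
#' light-derived burrow days and immersion-derived dry spells. A dry spell
#' contributes a day when it overlaps that local calendar day by at least
#' `minDryHoursPerDay` hours, so short nocturnal visits (which the light
#' method cannot see either) do not create occupancy days.
#'
#' @param burrowDays data.frame from [detectBurrowDays()] (may have 0 rows).
#' @param drySpells data.frame from [findDrySpells()] (may have 0 rows).
#' @param lon longitude defining the local solar day frame.
#' @param minDryHoursPerDay minimum dry overlap for a day to count.
#' @return data.frame with columns `date` and `source`
#'   (`"light"`, `"immersion"` or `"both"`), one row per occupancy day.
#' @export
mergeEvidence <- function(burrowDays, drySpells, lon = 0,
                          minDryHoursPerDay = 6) {
  immersionDays <- as.Date(character(0))
  if (!is.null(drySpells) && nrow(drySpells) > 0) {
    for (i in seq_len(nrow(drySpells))) {
      d0 <- localDate(drySpells$start[i], lon)
      d1 <- localDate(drySpells$end[i], lon)
      for (d in seq(d0, d1, by = "day")) {
        d <- as.Date(d, origin = "1970-01-01")
        dayStart <- as.POSIXct(paste(format(d), "00:00:00"), tz = "UTC") -
          lon / 15 * 3600
        overlap <- min(as.numeric(drySpells$end[i]), as.numeric(dayStart) + 86400) -
          max(as.numeric(drySpells$start[i]), as.numeric(dayStart))
        if (overlap / 3600 >= minDryHoursPerDay)
          immersionDays <- c(immersionDays, d)
      }
    }
  }
  lightDays <- if (!is.null(burrowDays) && nrow(burrowDays) > 0)
    as.Date(burrowDays$date) else as.Date(character(0))
  allDays <- sort(unique(c(lightDays, immersionDays)))
  data.frame(
    date = allDays,
    source = ifelse(allDays %in% lightDays & allDays %in% immersionDays,
                    "both",
                    ifelse(allDays %in% lightDays, "light", "immersion")),
    stringsAsFactors = FALSE)
}

#' Infer incubation onset from occupancy days
#'
#' Returns the first occupancy day that is followed by at least
#' `persistenceN - 1` further occupancy days within `persistenceWindowDays`.
#' The persistence requirement rejects isolated prospecting visits; the
#' defaults (3 days within 6) reflect the species' ~24-h alternating
#' incubation shifts, under which an incubating bird is underground every
#' other day.
#'
#' @param bouts data.frame with a `date` column ([mergeEvidence()] output).
#' @param persistenceN total occupancy days required (the onset day counts).
#' @param persistenceWindowDays window, in days after the candidate onset.
#' @param breedingWindow optional DOY pair; days outside it are ignored.
#' @return list with `doy` (day of year, `NA` if no sustained occupancy) and
#'   `date` (`NA` likewise).
#' @export
inferIncubationStart <- function(bouts, persistenceN = 3,
                                 persistenceWindowDays = 6,
                                 breedingWindow = NULL) {
  if (is.null(bouts) || nrow(bouts) == 0)
    return(list(doy = NA_integer_, date = as.Date(NA)))
  days <- sort(unique(as.Date(bouts$date)))
  if (!is.null(breedingWindow)) {
    doys <- dateToDoy(days)
    days <- days[doys >= breedingWindow[1] & doys <= breedingWindow[2]]
  }
  dn <- as.numeric(days)
  for (i in seq_along(dn)) {
    later <- dn[dn > dn[i] & dn <= dn[i] + persistenceWindowDays]
    if (length(later) >= persistenceN - 1)
      return(list(doy = dateToDoy(days[i]), date = days[i]))
  }
  list(doy = NA_integer_, date = as.Date(NA))
}

#' Back-calculate the lay date from incubation onset
#'
#' Males take the first incubation shift, so a male's observed onset day is
#' the lay day; a female's first shift follows her mate's, so 1 day is
#' subtracted from her observed onset. A result of day-of-year 0 or below is
#' normalised into the preceding calendar year.
#'
#' @param incubationStartDoy observed onset, day of year (1 Jan = 1).
#' @param sex `"F"` or `"M"`.
#' @param year optional calendar year of the onset; when given, the result
#'   carries an exact `lay_date`.
#' @param method provenance label (`"light"`, `"immersion"`, `"combined"`).
#' @param bird_id optional identifier carried through.
#' @return data.frame (one row): `bird_id`, `method`, `sex_used`,
#'   `incubation_start_doy`, `lay_doy`, `lay_year_offset` (-1 when the lay
#'   date falls in the previous year), and `lay_date` (`NA` without `year`).
#' @export
estimateLayDate <- function(incubationStartDoy, sex, year = NULL,
                            method = "combined", bird_id = NA_character_) {
  if (!sex %in% c("F", "M")) stop("unknown sex: ", sex)
  if (is.na(incubationStartDoy))
    return(data.frame(bird_id = bird_id, method = method, sex_used = sex,
                      incubation_start_doy = NA_integer_,
                      lay_doy = NA_integer_, lay_year_offset = NA_integer_,
                      lay_date = as.Date(NA), stringsAsFactors = FALSE))
  lay <- incubationStartDoy - as.integer(sex == "F")
  offset <- 0L
  layDate <- as.Date(NA)
  if (!is.null(year) && !is.na(lay)) {
    layDate <- doyToDate(incubationStartDoy, year) - as.integer(sex == "F")
    lay <- dateToDoy(layDate)
    offset <- as.integer(as.integer(format(layDate, "%Y")) - as.integer(year))
  } else if (!is.na(lay) && lay < 1) {
    # no year given: normalise on a 365-day calendar
    offset <- -1L
    lay <- lay + 365L
  }
  data.frame(bird_id = bird_id, method = method, sex_used = sex,
             incubation_start_doy = incubationStartDoy, lay_doy = lay,
             lay_year_offset = offset, lay_date = layDate,
             stringsAsFactors = FALSE)
}

#' Compare lay-date estimates between methods
#'
#' Method-agreement report for birds with both a light-based and an
#' immersion-based estimate: Pearson correlation, mean signed difference
#' (immersion minus light) and a per-bird delta table; optionally the same
#' statistics of each method against field-observed lay dates.
#'
#' @param lightEstimates,immersionEstimates data.frames with `bird_id` and
#'   `lay_doy` ([estimateLayDate()] output rows).
#' @param knownLayDates optional data.frame with `bird_id` and `lay_doy`.
#' @return object of class `methodAgreement`: `n`, `r`, `p`, `bias`,
#'   `perBird`, and `vsKnown` (a list of the same statistics per method) when
#'   known dates are supplied.
#' @export
compareMethods <- function(lightEstimates, immersionEstimates,
                           knownLayDates = NULL) {
  m <- merge(lightEstimates[, c("bird_id", "lay_doy")],
             immersionEstimates[, c("bird_id", "lay_doy")],
             by = "bird_id", suffixes = c("_light", "_immersion"))
  m <- m[stats::complete.cases(m), ]
  if (nrow(m) < 3)
    stop("need at least 3 birds with estimates from both methods, got ",
         nrow(m))
  ct <- stats::cor.test(m$lay_doy_light, m$lay_doy_immersion)
  m$delta <- m$lay_doy_immersion - m$lay_doy_light
  out <- list(n = nrow(m), r = unname(ct$estimate), p = ct$p.value,
              bias = mean(m$delta), perBird = m)
  if (!is.null(knownLayDates)) {
    vs <- lapply(list(light = lightEstimates, immersion = immersionEstimates),
                 function(est) {
      k <- merge(est[, c("bird_id", "lay_doy")], knownLayDates,
                 by = "bird_id", suffixes = c("_est", "_known"))
      k <- k[stats::complete.cases(k), ]
      if (nrow(k) < 3) return(NULL)
      ctk <- stats::cor.test(k$lay_doy_est, k$lay_doy_known)
      list(n = nrow(k), r = unname(ctk$estimate), p = ctk$p.value,
           bias = mean(k$lay_doy_est - k$lay_doy_known))
    })
    out$vsKnown <- vs
  }
  class(out) <- "methodAgreement"
  out
}

#' @export
print.methodAgreement <- function(x, ...) {
  cat(sprintf("Method agreement over %d birds: r = %.3f (p = %.3g), mean bias (immersion - light) = %.2f days\n",
              x$n, x$r, x$p, x$bias))
  invisible(x)
}
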