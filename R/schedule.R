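#' Behaviour schedule for one bird
#'
#' Builds the ordered, gap-free sequence of behaviour intervals (`on_water`,
#' `flying`, `in_burrow`) that drives the sensor renderers over the
#' configured breeding-season span. Incubating birds alternate ~24-h on/off
#' burrow shifts starting at incubation onset (lay day for males, lay day + 1
#' for females), with exchanges at a fixed local night hour plus optional
#' jitter; at-sea days are on-water with short flight bouts; an optional
#' isolated full-day prospecting visit precedes laying.
#'
#' @param bird one row of a `birdTruth` cohort.
#' @param config a [simConfig()].
#' @return data.frame of class `behaviourSchedule` with columns `start`,
#'   `end` (POSIXct UTC) and `state`; intervals are contiguous and cover the
#'   rendered span exactly.
#' @export
behaviourSchedule <- function(bird, config) {
  sc <- config$schedule
  year <- as.integer(bird$year)
  spanStart <- doyStartUTC(sc$renderStartDoy, year)
  spanEnd <- doyStartUTC(sc$renderEndDoy + 1, year)
  lonOffH <- bird$colony_lon / 15

  set.seed(birdSeed(config$seed, bird$bird_id, "schedule"))

  # exchange instant (UTC) at the start of local day `doy`
  exchange <- function(doy) {
    doyStartUTC(doy, year) + (sc$exchangeHourLocal - lonOffH) * 3600
  }

  onset <- bird$lay_day + as.integer(bird$sex == "F")
  dutyDays <- seq(onset, min(onset + sc$incubationDays, sc$renderEndDoy - 1),
                  by = 2)
  dutyDays <- dutyDays[dutyDays >= sc$renderStartDoy + 1]
  burrow <- lapply(dutyDays, function(d) {
    j <- pmin(2, pmax(-2, stats::rnorm(2, 0, sc$shiftJitterSDh)))
    c(exchange(d) + j[1] * 3600, exchange(d + 1) + j[2] * 3600)
  })
  if (isTRUE(sc$prospectVisit)) {
    p <- bird$lay_day - sc$prospectDaysBefore
    if (p >= sc$renderStartDoy + 1 && p < onset - 1)
      burrow <- c(list(c(exchange(p), exchange(p + 1))), burrow)
  }

  # all candidate flight bouts over the span (numeric seconds), precomputed
  dayAnchors <- as.numeric(doyStartUTC(sc$renderStartDoy, year)) +
    (seq(sc$renderStartDoy, sc$renderEndDoy) - sc$renderStartDoy) * 86400
  fStartAll <- if (sc$flightsPerDay > 0)
    sort(as.vector(outer(dayAnchors,
                         (9 + 5 * (seq_len(sc$flightsPerDay) - 1) - lonOffH) * 3600,
                         "+"))) else numeric(0)
  fEndAll <- fStartAll + sc$flightMinutes * 60

  iv <- list()
  cursor <- spanStart
  addSea <- function(iv, from, to) {
    # on-water block [from, to), with flight bouts carved out
    from <- as.numeric(from); to <- as.numeric(to)
    if (to <= from) return(iv)
    for (j in which(fStartAll >= from & fEndAll <= to)) {
      if (fStartAll[j] > from)
        iv[[length(iv) + 1]] <- list(cursor = from, end = fStartAll[j],
                                     state = "on_water")
      iv[[length(iv) + 1]] <- list(cursor = fStartAll[j], end = fEndAll[j],
                                   state = "flying")
      from <- fEndAll[j]
    }
    if (to > from)
      iv[[length(iv) + 1]] <- list(cursor = from, end = to, state = "on_water")
    iv
  }

  for (b in burrow) {
    bStart <- max(b[1], spanStart)
    bEnd <- min(b[2], spanEnd)
    if (bEnd <= bStart) next
    iv <- addSea(iv, cursor, bStart)
    iv[[length(iv) + 1]] <- list(cursor = bStart, end = bEnd, state = "in_burrow")
    cursor <- bEnd
  }
  iv <- addSea(iv, cursor, spanEnd)

  out <- data.frame(
    start = as.POSIXct(vapply(iv, function(x) as.numeric(x$cursor), 0),
                       origin = "1970-01-01", tz = "UTC"),
    end = as.POSIXct(vapply(iv, function(x) as.numeric(x$end), 0),
                     origin = "1970-01-01", tz = "UTC"),
    state = vapply(iv, function(x) x$state, ""),
    stringsAsFactors = FALSE)
  out <- out[order(out$start), ]
  rownames(out) <- NULL
  stopifnot(all(abs(as.numeric(out$end[-nrow(out)]) -
                      as.numeric(out$start[-1])) < 1e-6),
            abs(as.numeric(out$start[1]) - as.numeric(spanStart)) < 1e-6,
            abs(as.numeric(out$end[nrow(out)]) - as.numeric(spanEnd)) < 1e-6)
  class(out) <- c("behaviourSchedule", "data.frame")
  out
}

# state at given instants; intervals are contiguous, so membership is a
# single findInterval; instants outside the covered span are a gap error
scheduleStateAt <- function(schedule, times) {
  tn <- as.numeric(times)
  if (any(tn < as.numeric(schedule$start[1]) - 1e-6) ||
      any(tn >= as.numeric(schedule$end[nrow(schedule)]) + 1e-6))
    stop("schedule gap: requested instants outside the scheduled span")
  schedule$state[pmax(1L, findInterval(tn, as.numeric(schedule$start)))]
}
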