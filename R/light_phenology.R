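#' Detect threshold twilights in a light series
#'
#' Finds every crossing of the illuminance threshold (3 lx by default, the
#' standard working threshold for this tag class): an upward crossing is a
#' sunrise, a downward crossing a sunset. Crossing instants are placed by
#' linear interpolation in time between the two bracketing samples.
#'
#' @param light data.frame with columns `timestamp` (POSIXct, strictly
#'   increasing) and `lux` (non-negative).
#' @param thresholdLux illuminance threshold.
#' @return data.frame of class `twilightEvents` with columns `timestamp`,
#'   `kind` (`"sunrise"`/`"sunset"`) and `flagged` (all `FALSE`).
#' @export
detectTwilights <- function(light, thresholdLux = 3) {
  if (is.null(light) || nrow(light) == 0)
    stop("empty light series")
  t <- as.numeric(light$timestamp)
  if (is.unsorted(t, strictly = TRUE))
    stop("light series timestamps must be strictly increasing")
  if (any(light$lux < 0)) stop("negative illuminance")

  above <- light$lux > thresholdLux
  i <- which(above[-length(above)] != above[-1])
  if (length(i) == 0) {
    out <- data.frame(timestamp = as.POSIXct(numeric(0), origin = "1970-01-01",
                                             tz = "UTC"),
                      kind = character(0), flagged = logical(0))
  } else {
    frac <- (thresholdLux - light$lux[i]) / (light$lux[i + 1] - light$lux[i])
    out <- data.frame(
      timestamp = as.POSIXct(t[i] + frac * (t[i + 1] - t[i]),
                             origin = "1970-01-01", tz = "UTC"),
      kind = ifelse(above[i + 1], "sunrise", "sunset"),
      flagged = FALSE, stringsAsFactors = FALSE)
  }
  class(out) <- c("twilightEvents", "data.frame")
  out
}

#' Flag implausibly close twilight events
#'
#' Both members of any consecutive pair of events closer than
#' `minSeparationH` (5 h by default -- the minimum day or night length at
#' 60 degrees N) are flagged as suspect; all other events are untouched.
#'
#' @param events a `twilightEvents` data.frame (time-ordered).
#' @param minSeparationH minimum plausible separation in hours.
#' @return the events with updated `flagged` column.
#' @export
flagShortIntervals <- function(events, minSeparationH = 5) {
  if (nrow(events) < 2) return(events)
  gaps <- diff(as.numeric(events$timestamp)) / 3600
  short <- which(gaps < minSeparationH)
  events$flagged[unique(c(short, short + 1))] <- TRUE
  events
}

#' Resolve flagged twilight events against the recent trend
#'
#' Automates the visual-inspection step: for each flagged event, the expected
#' time is predicted from a linear trend (clock time regressed on date)
#' fitted to the previous `windowK` retained events of the same kind. A
#' flagged event deviating from its prediction by more than `toleranceH`
#' hours is dropped; if both members of a flagged pair deviate, both are
#' dropped. A flagged event with fewer than 2 prior same-kind events is kept
#' with a warning. Unflagged events are never removed.
#'
#' @param events a `twilightEvents` data.frame, flagged by
#'   [flagShortIntervals()].
#' @param windowK number of prior same-kind events defining the trend.
#' @param toleranceH maximum deviation from the predicted time, hours.
#' @return the retained events; dropped rows are attached as attribute
#'   `dropped`.
#' @export
resolveFlagged <- function(events, windowK = 5, toleranceH = 1) {
  if (!any(events$flagged)) {
    attr(events, "dropped") <- events[0, ]
    return(events)
  }
  keep <- rep(TRUE, nrow(events))
  tn <- as.numeric(events$timestamp)
  for (i in which(events$flagged)) {
    prior <- which(keep & events$kind == events$kind[i] & !events$flagged &
                     seq_along(keep) < i)
    prior <- utils::tail(prior, windowK)
    if (length(prior) < 2) {
      warning("flagged ", events$kind[i], " at ", format(events$timestamp[i]),
              " kept: fewer than 2 prior same-kind events")
      next
    }
    day <- floor(tn[prior] / 86400)
    fit <- stats::lm(tn[prior] ~ day)
    predicted <- unname(stats::predict(fit,
      newdata = data.frame(day = floor(tn[i] / 86400))))
    if (abs(tn[i] - predicted) / 3600 > toleranceH) {
      keep[i] <- FALSE
      message("dropped off-trend ", events$kind[i], " at ",
              format(events$timestamp[i]))
    }
  }
  dropped <- events[!keep, ]
  out <- events[keep, ]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Identify burrow-occupancy days from missing sunrises
#'
#' A daylight period spent underground suppresses the sunrise: for every
#' sunset with no sunrise event in the following 24 h, the next calendar day
#' (in the colony's local solar frame) is emitted as a burrow day.
#'
#' @param events cleaned `twilightEvents`.
#' @param lon longitude (degrees E) defining the local solar day frame.
#' @return data.frame with columns `date` and `evidence` (`"light"`).
#' @export
detectBurrowDays <- function(events, lon = 0) {
  sunsets <- which(events$kind == "sunset")
  sunriseT <- as.numeric(events$timestamp[events$kind == "sunrise"])
  days <- as.Date(character(0))
  for (i in sunsets) {
    t0 <- as.numeric(events$timestamp[i])
    nxt <- sunriseT[sunriseT > t0]
    if (length(nxt) == 0) next  # record ends: no evidence either way
    if (min(nxt) - t0 > 24 * 3600)
      days <- c(days, localDate(events$timestamp[i], lon) + 1)
  }
  data.frame(date = days, evidence = rep("light", length(days)),
             stringsAsFactors = FALSE)
}
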