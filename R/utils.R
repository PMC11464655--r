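# Internal helpers: time frames, day-of-year arithmetic, deterministic substreams.

# Local solar calendar frame: shift a UTC instant by lon/15 hours so that
# "calendar day" means the day at the bird's longitude, then truncate.
localDate <- function(time, lon = 0) {
  as.Date(as.POSIXct(time, tz = "UTC") + lon / 15 * 3600, tz = "UTC")
}

# 1 January = DOY 1.
dateToDoy <- function(date) as.POSIXlt(date)$yday + 1L

doyToDate <- function(doy, year) {
  as.Date(sprintf("%d-01-01", as.integer(year))) + (doy - 1)
}

# Midnight UTC at the start of a given DOY of a given year.
doyStartUTC <- function(doy, year) {
  as.POSIXct(sprintf("%d-01-01 00:00:00", as.integer(year)), tz = "UTC") +
    (doy - 1) * 86400
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Stable 32-bit string hash (polynomial rolling hash mod the Mersenne prime
# 2^31 - 1). Used to derive per-bird RNG substreams so that adding birds to a
# cohort never reshuffles the draws of existing birds.
stableHash <- function(s) {
  vapply(s, function(one) {
    v <- utf8ToInt(enc2utf8(one))
    h <- 0
    for (ch in v) h <- (h * 31 + ch) %% 2147483647
    h
  }, numeric(1), USE.NAMES = FALSE)
}

# Substream seed for one bird (or any labelled stream) under a root seed.
# Kept below 2^31 so it is a valid R integer seed.
birdSeed <- function(rootSeed, id, stream = "truth") {
  as.integer(stableHash(paste(rootSeed, id, stream, sep = "/")))
}

# Within-sample z-scaling that maps a constant vector to zeros instead of
# failing; generation-side counterpart of scaleCovariate().
scaleOrZero <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}
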