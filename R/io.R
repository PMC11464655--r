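# CSV readers/writers for the tag-record interchange formats. Timestamps are
# ISO-8601 UTC throughout.

#' Read and write tag record CSVs
#'
#' `readLightCSV` expects `timestamp,lux`; `readImmersionCSV`
#' `bin_start,wet_count`; `readFixesCSV` `bird_id,date,lat,lon` (or
#' `date,lat,lon` for a single bird); `readRecordsCSV` the one-row-per-bird
#' model input table. Writers emit the same shapes with ISO-8601 UTC
#' timestamps.
#'
#' @param path file path.
#' @param x table to write.
#' @return the parsed data.frame (readers) or `path` invisibly (writer).
#' @name tagIO
NULL

parseUTC <- function(x) {
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                   "%Y-%m-%d"))
  if (any(is.na(out) & !is.na(x))) stop("unparseable timestamp(s)")
  out
}

#' @rdname tagIO
#' @export
readLightCSV <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  data.frame(timestamp = parseUTC(d$timestamp), lux = as.numeric(d$lux))
}

#' @rdname tagIO
#' @export
readImmersionCSV <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  data.frame(bin_start = parseUTC(d$bin_start),
             wet_count = as.integer(d$wet_count))
}

#' @rdname tagIO
#' @export
readFixesCSV <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$date <- as.Date(d$date)
  d
}

#' @rdname tagIO
#' @export
readRecordsCSV <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname tagIO
#' @export
writeTimesCSV <- function(x, path) {
  for (nm in names(x))
    if (inherits(x[[nm]], "POSIXct"))
      x[[nm]] <- format(x[[nm]], "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
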