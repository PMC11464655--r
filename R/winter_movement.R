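#' Select fixes inside the winter window
#'
#' Keeps fixes whose month-day falls inside the closed window (1 Jan to
#' 28 Feb by default), in any year of the track.
#'
#' @param fixes data.frame with a `date` column (`Date`).
#' @param window month-day strings `c(from, to)` with `from <= to`.
#' @return the subset of `fixes`.
#' @export
selectWinterFixes <- function(fixes, window = c("01-01", "02-28")) {
  if (is.null(fixes) || nrow(fixes) == 0) return(fixes)
  md <- format(as.Date(fixes$date), "%m-%d")
  fixes[md >= window[1] & md <= window[2], , drop = FALSE]
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere (radius 6371.0088 km by default, the IUGG
#' mean Earth radius), vectorised over coordinate pairs.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees.
#' @param radiusKm sphere radius in km.
#' @return distance(s) in km.
#' @export
haversineKm <- function(lat1, lon1, lat2, lon2, radiusKm = 6371.0088) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE))
    stop("invalid latitude outside [-90, 90]")
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = radiusKm)
}

#' Kernel utilization distribution of winter fixes
#'
#' Bivariate Gaussian kernel density of the fixes on a local
#' azimuthal-equidistant projection about their mean position, evaluated on
#' a regular grid and normalised to unit mass. The default bandwidth is the
#' reference ("href") rule \eqn{h = \sigma n^{-1/6}} with
#' \eqn{\sigma = \sqrt{(var(x) + var(y))/2}}.
#'
#' @param fixes data.frame with `lat` and `lon` columns (and optionally
#'   `bird_id`, used in error messages).
#' @param bandwidthKm fixed bandwidth in km, or `NULL` for the href rule.
#' @param gridN grid cells per axis.
#' @param minFixes minimum number of fixes required.
#' @param radiusKm sphere radius used by the projection.
#' @param extend grid margin, in bandwidths beyond the fix extent.
#' @return object of class `udGrid`: grid axes `gx`, `gy` (km in the
#'   projected plane), matrices `density` (per km^2) and `mass` (cell
#'   masses summing to 1), `rawMass` (pre-normalisation integral, a
#'   discretisation diagnostic), bandwidth `h`, projection `center`
#'   (lat, lon) and `n`.
#' @export
kernelUD <- function(fixes, bandwidthKm = NULL, gridN = 100, minFixes = 5,
                     radiusKm = 6371.0088, extend = 3) {
  n <- nrow(fixes)
  if (n < minFixes) {
    who <- if ("bird_id" %in% names(fixes) && n > 0) unique(fixes$bird_id)[1]
      else "track"
    stop("too few fixes for ", who, ": ", n, " < ", minFixes)
  }
  if (diff(range(fixes$lon)) > 180)
    stop("fixes span the dateline; this domain expects east-longitude tracks without +/-180 crossings")

  center <- c(lat = mean(fixes$lat), lon = mean(fixes$lon))
  p <- projectAeqd(fixes$lat, fixes$lon, center, radiusKm)

  sigma <- sqrt((stats::var(p$x) + stats::var(p$y)) / 2)
  degenerate <- !is.finite(sigma) || sigma < 1e-9
  h <- if (!is.null(bandwidthKm)) bandwidthKm else sigma * n^(-1 / 6)

  if (degenerate) {
    out <- list(gx = p$x[1], gy = p$y[1],
                density = matrix(Inf, 1, 1), mass = matrix(1, 1, 1),
                rawMass = 1, h = 0, center = center, radiusKm = radiusKm,
                n = n, degenerate = TRUE)
    class(out) <- "udGrid"
    return(out)
  }

  # cell masses by exact integration of the separable Gaussian kernel over
  # cell edges (pnorm differences), so the discretisation is resolution-free
  ex <- seq(min(p$x) - extend * h, max(p$x) + extend * h,
            length.out = gridN + 1)
  ey <- seq(min(p$y) - extend * h, max(p$y) + extend * h,
            length.out = gridN + 1)
  gx <- (ex[-1] + ex[-length(ex)]) / 2
  gy <- (ey[-1] + ey[-length(ey)]) / 2
  A <- stats::pnorm(outer(ex[-1], p$x, "-") / h) -
    stats::pnorm(outer(ex[-length(ex)], p$x, "-") / h)
  B <- stats::pnorm(outer(ey[-1], p$y, "-") / h) -
    stats::pnorm(outer(ey[-length(ey)], p$y, "-") / h)
  cellMass <- (A %*% t(B)) / n
  cellArea <- (ex[2] - ex[1]) * (ey[2] - ey[1])
  rawMass <- sum(cellMass)  # < 1 only by the grid-margin tail truncation
  out <- list(gx = gx, gy = gy, density = cellMass / cellArea,
              mass = cellMass / rawMass, rawMass = rawMass, h = h,
              center = center, radiusKm = radiusKm, n = n,
              degenerate = FALSE)
  class(out) <- "udGrid"
  out
}

#' @export
print.udGrid <- function(x, ...) {
  cat(sprintf("udGrid: %d fixes, %s grid, h = %.1f km, centre (%.2fN, %.2fE)%s\n",
              x$n, if (x$degenerate) "degenerate point" else
                paste0(length(x$gx), "x", length(x$gy)),
              x$h, x$center["lat"], x$center["lon"],
              if (x$degenerate) " [all fixes identical]" else ""))
  invisible(x)
}

# local azimuthal-equidistant projection: km east/north of `center`
projectAeqd <- function(lat, lon, center, radiusKm) {
  d <- haversineKm(center["lat"], center["lon"], lat, lon, radiusKm)
  b <- geosphere::bearing(c(center["lon"], center["lat"]), cbind(lon, lat))
  b[!is.finite(b)] <- 0  # coincident with centre: bearing undefined, d = 0
  list(x = d * sin(deg2rad(b)), y = d * cos(deg2rad(b)))
}

unprojectAeqd <- function(x, y, center, radiusKm) {
  d <- sqrt(x^2 + y^2)
  if (d < 1e-12) return(c(lat = unname(center["lat"]), lon = unname(center["lon"])))
  b <- rad2deg(atan2(x, y))
  p <- geosphere::destPoint(c(center["lon"], center["lat"]), b, d * 1000,
                            r = radiusKm * 1000)
  c(lat = unname(p[1, "lat"]), lon = unname(p[1, "lon"]))
}

#' Centroid of the level-set of a utilization distribution
#'
#' The smallest set of grid cells containing `level` of the total mass is
#' accumulated in order of decreasing density (ties broken by cell index, for
#' determinism); the centroid is the mass-weighted mean position over that
#' set, mapped back to geographic coordinates. `level = 1` gives the
#' mass-weighted mean of the full distribution.
#'
#' @param ud a [kernelUD()] result.
#' @param level mass level of the isopleth (0.9 = the 90\% UD).
#' @return named vector `c(lat, lon)`, plus attributes `levelMass` (mass
#'   actually enclosed) and `nCells`.
#' @export
udCentroid <- function(ud, level = 0.9) {
  stopifnot(inherits(ud, "udGrid"))
  if (ud$degenerate) {
    out <- c(lat = unname(ud$center["lat"]), lon = unname(ud$center["lon"]))
    attr(out, "levelMass") <- 1
    attr(out, "nCells") <- 1L
    return(out)
  }
  m <- as.vector(ud$mass)
  ord <- order(-m, seq_along(m))
  cum <- cumsum(m[ord])
  k <- which(cum >= level - 1e-12)[1]
  sel <- ord[seq_len(k)]
  xs <- ud$gx[(sel - 1) %% length(ud$gx) + 1]
  ys <- ud$gy[(sel - 1) %/% length(ud$gx) + 1]
  w <- m[sel] / sum(m[sel])
  out <- unprojectAeqd(sum(xs * w), sum(ys * w), ud$center, ud$radiusKm)
  attr(out, "levelMass") <- cum[k]
  attr(out, "nCells") <- k
  out
}

#' Migration record for one bird
#'
#' Chains the winter-movement steps for a single bird's track: select the
#' winter fixes, estimate the kernel UD, take the `level` (90\%) level-set
#' centroid, and measure the great-circle distance from the breeding colony
#' to that centroid. The centroid latitude is the bird's wintering latitude.
#'
#' @param fixes data.frame with `bird_id`, `date`, `lat`, `lon` for one bird.
#' @param colony list or one-row data.frame with `name`, `latitude`,
#'   `longitude`.
#' @param window winter window (month-day strings).
#' @param level UD level for the centroid.
#' @param minFixes minimum winter fixes; fewer yields an `NA` record with a
#'   `note` rather than an error.
#' @param radiusKm sphere radius in km.
#' @param ... further arguments to [kernelUD()].
#' @return one-row data.frame: `bird_id`, `n_fixes`, `wintering_latitude`,
#'   `wintering_longitude`, `migration_distance_km`, `note`.
#' @export
migrationSummary <- function(fixes, colony, window = c("01-01", "02-28"),
                             level = 0.9, minFixes = 5,
                             radiusKm = 6371.0088, ...) {
  id <- if (nrow(fixes) > 0) fixes$bird_id[1] else NA_character_
  win <- selectWinterFixes(fixes, window)
  if (nrow(win) < minFixes) {
    return(data.frame(bird_id = id, n_fixes = nrow(win),
                      wintering_latitude = NA_real_,
                      wintering_longitude = NA_real_,
                      migration_distance_km = NA_real_,
                      note = "no-centroid: too few winter fixes",
                      stringsAsFactors = FALSE))
  }
  ud <- kernelUD(win, minFixes = minFixes, radiusKm = radiusKm, ...)
  ctr <- udCentroid(ud, level = level)
  data.frame(bird_id = id, n_fixes = nrow(win),
             wintering_latitude = unname(ctr["lat"]),
             wintering_longitude = unname(ctr["lon"]),
             migration_distance_km = haversineKm(ctr["lat"], ctr["lon"],
                                                 colony$latitude,
                                                 colony$longitude, radiusKm),
             note = "", stringsAsFactors = FALSE)
}
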