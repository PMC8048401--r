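# Map projections for reading longitude/latitude telemetry (e.g. the
# Movebank CSV dialect) into a projected CRS.
#
# Two families are supported, implemented from the standard closed-form
# projection equations on the reference ellipsoid:
#   - EPSG:5070, the CONUS Albers equal-area conic (NAD83 / GRS80), the CRS
#     used throughout the bundled examples;
#   - WGS84 UTM zones (EPSG 32601-32660 north, 32701-32760 south).
# Accuracy is well below 1 m inside each projection's domain of use, which
# is ample for home-range work on GPS data with multi-metre error.

GEOGRAPHIC_EPSG <- c(4326L, 4269L, 4267L, 4258L)

crs_is_geographic <- function(epsg) as.integer(epsg) %in% GEOGRAPHIC_EPSG

check_epsg <- function(crs) {
  if (is.null(crs) || length(crs) != 1L || is.na(suppressWarnings(as.integer(crs)))) {
    stop_domain("`crs` must be a single EPSG integer code (e.g. 5070).")
  }
  as.integer(crs)
}

albers_5070_params <- function() {
  list(
    a = 6378137, f = 1 / 298.257222101,
    lat0 = 23, lon0 = -96, lat1 = 29.5, lat2 = 45.5,
    x0 = 0, y0 = 0
  )
}

.alb_q <- function(phi, e, e2) {
  s <- sin(phi)
  (1 - e2) * (s / (1 - e2 * s^2) - (1 / (2 * e)) * log((1 - e * s) / (1 + e * s)))
}

.alb_m <- function(phi, e2) cos(phi) / sqrt(1 - e2 * sin(phi)^2)

albers_setup <- function(p) {
  e2 <- 2 * p$f - p$f^2
  e <- sqrt(e2)
  d2r <- pi / 180
  phi0 <- p$lat0 * d2r; phi1 <- p$lat1 * d2r; phi2 <- p$lat2 * d2r
  m1 <- .alb_m(phi1, e2); m2 <- .alb_m(phi2, e2)
  q0 <- .alb_q(phi0, e, e2); q1 <- .alb_q(phi1, e, e2); q2 <- .alb_q(phi2, e, e2)
  n <- (m1^2 - m2^2) / (q2 - q1)
  C <- m1^2 + n * q1
  rho0 <- p$a * sqrt(C - n * q0) / n
  list(p = p, e = e, e2 = e2, n = n, C = C, rho0 = rho0, d2r = d2r)
}

albers_forward <- function(lon, lat) {
  s <- albers_setup(albers_5070_params())
  phi <- lat * s$d2r
  q <- .alb_q(phi, s$e, s$e2)
  rho <- s$p$a * sqrt(s$C - s$n * q) / s$n
  theta <- s$n * (lon - s$p$lon0) * s$d2r
  list(x = s$p$x0 + rho * sin(theta), y = s$p$y0 + s$rho0 - rho * cos(theta))
}

albers_inverse <- function(x, y) {
  s <- albers_setup(albers_5070_params())
  x <- x - s$p$x0; y <- y - s$p$y0
  rho <- sqrt(x^2 + (s$rho0 - y)^2)
  theta <- atan2(x, s$rho0 - y)
  q <- (s$C - (rho * s$n / s$p$a)^2) / s$n
  phi <- asin(pmin(pmax(q / 2, -1), 1))
  for (i in 1:25) {
    sp_ <- sin(phi)
    dphi <- (1 - s$e2 * sp_^2)^2 / (2 * cos(phi)) *
      (q / (1 - s$e2) - sp_ / (1 - s$e2 * sp_^2) +
         (1 / (2 * s$e)) * log((1 - s$e * sp_) / (1 + s$e * sp_)))
    phi <- phi + dphi
    if (max(abs(dphi)) < 1e-12) break
  }
  list(lon = s$p$lon0 + theta / s$n / s$d2r, lat = phi / s$d2r)
}

utm_params <- function(epsg) {
  epsg <- as.integer(epsg)
  north <- epsg >= 32601L && epsg <= 32660L
  south <- epsg >= 32701L && epsg <= 32760L
  if (!north && !south) return(NULL)
  zone <- epsg - if (north) 32600L else 32700L
  list(
    a = 6378137, f = 1 / 298.257223563, k0 = 0.9996,
    lon0 = -183 + 6 * zone, x0 = 500000, y0 = if (south) 1e7 else 0
  )
}

utm_forward <- function(lon, lat, p) {
  d2r <- pi / 180
  e2 <- 2 * p$f - p$f^2
  ep2 <- e2 / (1 - e2)
  phi <- lat * d2r
  N <- p$a / sqrt(1 - e2 * sin(phi)^2)
  T <- tan(phi)^2
  C <- ep2 * cos(phi)^2
  A <- cos(phi) * (lon - p$lon0) * d2r
  M <- p$a * ((1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256) * phi -
                (3 * e2 / 8 + 3 * e2^2 / 32 + 45 * e2^3 / 1024) * sin(2 * phi) +
                (15 * e2^2 / 256 + 45 * e2^3 / 1024) * sin(4 * phi) -
                (35 * e2^3 / 3072) * sin(6 * phi))
  x <- p$k0 * N * (A + (1 - T + C) * A^3 / 6 +
                     (5 - 18 * T + T^2 + 72 * C - 58 * ep2) * A^5 / 120) + p$x0
  y <- p$k0 * (M + N * tan(phi) * (A^2 / 2 +
                                     (5 - T + 9 * C + 4 * C^2) * A^4 / 24 +
                                     (61 - 58 * T + T^2 + 600 * C - 330 * ep2) * A^6 / 720)) + p$y0
  list(x = x, y = y)
}

#' Project longitude/latitude coordinates to a supported projected CRS
#'
#' Supported targets are EPSG:5070 (CONUS Albers equal-area, NAD83) and the
#' WGS84 UTM zones (EPSG 32601--32660 and 32701--32760).
#'
#' @param lon,lat numeric vectors of geographic coordinates in decimal degrees.
#' @param crs target EPSG code.
#' @return a list with numeric vectors `x` and `y` in metres.
#' @export
project_lonlat <- function(lon, lat, crs) {
  crs <- check_epsg(crs)
  if (crs == 5070L) return(albers_forward(lon, lat))
  p <- utm_params(crs)
  if (!is.null(p)) return(utm_forward(lon, lat, p))
  stop_unsupported(sprintf(
    "Projection to EPSG:%d is not supported (supported: 5070, WGS84 UTM zones).", crs
  ))
}

#' Inverse-project planar coordinates back to longitude/latitude
#'
#' Only EPSG:5070 is supported for the inverse direction (used when writing
#' Movebank-dialect CSV files).
#'
#' @param x,y numeric vectors of projected coordinates in metres.
#' @param crs source EPSG code.
#' @return a list with numeric vectors `lon` and `lat` in decimal degrees.
#' @export
project_to_lonlat <- function(x, y, crs) {
  crs <- check_epsg(crs)
  if (crs == 5070L) return(albers_inverse(x, y))
  stop_unsupported(sprintf("Inverse projection from EPSG:%d is not supported.", crs))
}
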