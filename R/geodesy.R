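#' Geodetic anchor of the local model frame
#'
#' The local metric frame of a photogrammetric model is interpreted as an
#' east-north-up (ENU) tangent frame at this WGS84 anchor: +x east, +y north,
#' +z up.  Heights are ellipsoidal; depth below the ellipsoid is simply a
#' negative height (no geoid model is applied).
#'
#' @param lat0,lon0 Anchor latitude/longitude in degrees.
#' @param h0 Anchor ellipsoidal height in metres (negative under water).
#' @return An object of class `geo_anchor`.
#' @export
geo_anchor <- function(lat0, lon0, h0 = 0) {
  stopifnot(is.finite(lat0), is.finite(lon0), is.finite(h0))
  if (abs(lat0) > 90) stop("anchor latitude must be in [-90, 90] degrees")
  if (abs(lon0) > 180) stop("anchor longitude must be in [-180, 180] degrees")
  structure(list(lat0 = lat0, lon0 = lon0, h0 = h0), class = "geo_anchor")
}

# WGS84 ellipsoid
WGS84_A <- 6378137
WGS84_F <- 1 / 298.257223563

geodetic_to_ecef <- function(lat_deg, lon_deg, h) {
  e2 <- WGS84_F * (2 - WGS84_F)
  lat <- lat_deg * pi / 180
  lon <- lon_deg * pi / 180
  N <- WGS84_A / sqrt(1 - e2 * sin(lat)^2)
  cbind((N + h) * cos(lat) * cos(lon),
        (N + h) * cos(lat) * sin(lon),
        (N * (1 - e2) + h) * sin(lat))
}

# Bowring's closed form followed by fixed-point refinement on latitude,
# iterated to |dlat| < 1e-14 rad (sub-micrometre in height).
ecef_to_geodetic <- function(xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  a <- WGS84_A
  f <- WGS84_F
  b <- a * (1 - f)
  e2 <- f * (2 - f)
  ep2 <- (a^2 - b^2) / b^2
  x <- xyz[, 1]; y <- xyz[, 2]; z <- xyz[, 3]
  lon <- atan2(y, x)
  p <- sqrt(x^2 + y^2)
  theta <- atan2(z * a, p * b)
  lat <- atan2(z + ep2 * b * sin(theta)^3, p - e2 * a * cos(theta)^3)
  h <- numeric(length(lat))
  for (i in 1:20) {
    N <- a / sqrt(1 - e2 * sin(lat)^2)
    h <- p / cos(lat) - N
    lat_new <- atan2(z, p * (1 - e2 * N / (N + h)))
    if (max(abs(lat_new - lat)) < 1e-14) { lat <- lat_new; break }
    lat <- lat_new
  }
  N <- a / sqrt(1 - e2 * sin(lat)^2)
  h <- p / cos(lat) - N
  cbind(lat = lat * 180 / pi, lon = lon * 180 / pi, h = h)
}

# rows: east, north, up unit vectors in ECEF at the anchor
enu_basis <- function(anchor) {
  lat <- anchor$lat0 * pi / 180
  lon <- anchor$lon0 * pi / 180
  rbind(e = c(-sin(lon), cos(lon), 0),
        n = c(-sin(lat) * cos(lon), -sin(lat) * sin(lon), cos(lat)),
        u = c(cos(lat) * cos(lon), cos(lat) * sin(lon), sin(lat)))
}

#' Convert local ENU coordinates to WGS84 geodetic
#'
#' Exact chain ENU -> ECEF -> geodetic on the WGS84 ellipsoid
#' (a = 6378137 m, 1/f = 298.257223563).
#'
#' @param p_local Length-3 ENU point (metres) or n x 3 matrix.
#' @param anchor A [geo_anchor()].
#' @return n x 3 matrix (or length-3 vector) of (lat deg, lon deg, height m).
#' @export
local_to_geodetic <- function(p_local, anchor) {
  stopifnot(inherits(anchor, "geo_anchor"))
  single <- is.null(dim(p_local))
  p <- matrix(as.numeric(p_local), ncol = 3L)
  x0 <- geodetic_to_ecef(anchor$lat0, anchor$lon0, anchor$h0)
  ecef <- sweep(p %*% enu_basis(anchor), 2L, as.numeric(x0), `+`)
  g <- ecef_to_geodetic(ecef)
  if (single) g[1L, ] else g
}

#' Convert WGS84 geodetic coordinates to the local ENU frame
#'
#' Exact inverse of [local_to_geodetic()].
#'
#' @param lat,lon Degrees; scalars or vectors.
#' @param h Ellipsoidal height in metres.
#' @param anchor A [geo_anchor()].
#' @return n x 3 matrix (or length-3 vector) of ENU coordinates (metres).
#' @export
geodetic_to_local <- function(lat, lon, h, anchor) {
  stopifnot(inherits(anchor, "geo_anchor"))
  single <- length(lat) == 1L
  ecef <- geodetic_to_ecef(lat, lon, h)
  x0 <- geodetic_to_ecef(anchor$lat0, anchor$lon0, anchor$h0)
  d <- sweep(ecef, 2L, as.numeric(x0))
  out <- d %*% t(enu_basis(anchor))
  colnames(out) <- c("x", "y", "z")
  if (single) out[1L, ] else out
}
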