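# Spherical geodesy helpers shared across the package. All distances are
# great-circle (haversine) on the IUGG mean-radius sphere; the ellipsoid is
# deliberately not used (tests carry an ellipsoidal oracle for the error bound).

#' Mean Earth radius (km) used for all spherical geodesy
#'
#' IUGG mean radius, 6371.0088 km.
#' @export
EARTH_RADIUS_KM <- 6371.0088

#' Great-circle distance between points, in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0088 km. Vectorised over all
#' four arguments.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (WGS84, unprojected).
#' @return Numeric vector of distances in km.
#' @examples
#' great_circle_km(0, 0, 0, 1)   # one degree of longitude at the equator
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2) {
  stopifnot(all(abs(lat1) <= 90, na.rm = TRUE), all(abs(lat2) <= 90, na.rm = TRUE))
  n <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  as.numeric(geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_KM))
}

#' Normalize longitudes to (-180, 180]
#' @param lon Longitudes in decimal degrees.
#' @return Normalized longitudes.
#' @export
normalize_lon <- function(lon) {
  out <- (lon + 180) %% 360 - 180
  out[out == -180] <- 180
  out
}

# Spherical linear interpolation along the great circle from p1 to p2.
# f is a vector of fractions in [0, 1]; returns a matrix with lat, lon columns.
gc_interpolate <- function(lat1, lon1, lat2, lon2, f) {
  to_rad <- pi / 180
  a <- c(cos(lat1 * to_rad) * cos(lon1 * to_rad),
         cos(lat1 * to_rad) * sin(lon1 * to_rad),
         sin(lat1 * to_rad))
  b <- c(cos(lat2 * to_rad) * cos(lon2 * to_rad),
         cos(lat2 * to_rad) * sin(lon2 * to_rad),
         sin(lat2 * to_rad))
  d <- acos(pmin(1, pmax(-1, sum(a * b))))
  if (d < 1e-12) {
    return(cbind(lat = rep(lat1, length(f)), lon = rep(lon1, length(f))))
  }
  w1 <- sin((1 - f) * d) / sin(d)
  w2 <- sin(f * d) / sin(d)
  x <- w1 * a[1] + w2 * b[1]
  y <- w1 * a[2] + w2 * b[2]
  z <- w1 * a[3] + w2 * b[3]
  cbind(lat = atan2(z, sqrt(x^2 + y^2)) / to_rad,
        lon = atan2(y, x) / to_rad)
}

# Azimuthal-equidistant projection (sphere) centred at (lat0, lon0).
# Radial distances from the centre are exact; used as the planar working frame
# for per-leg movement-model fitting. Returns x (east) and y (north) in km.
aeqd_project <- function(lat, lon, lat0, lon0) {
  to_rad <- pi / 180
  phi <- lat * to_rad; lam <- lon * to_rad
  phi0 <- lat0 * to_rad; lam0 <- lon0 * to_rad
  dlam <- lam - lam0
  cosc <- sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(dlam)
  c_ang <- acos(pmin(1, pmax(-1, cosc)))
  az <- atan2(sin(dlam) * cos(phi),
              cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(dlam))
  r <- EARTH_RADIUS_KM * c_ang
  cbind(x = r * sin(az), y = r * cos(az))
}

aeqd_inverse <- function(x, y, lat0, lon0) {
  to_rad <- pi / 180
  phi0 <- lat0 * to_rad; lam0 <- lon0 * to_rad
  r <- sqrt(x^2 + y^2)
  c_ang <- r / EARTH_RADIUS_KM
  az <- atan2(x, y)
  sinl <- sin(phi0) * cos(c_ang) + cos(phi0) * sin(c_ang) * cos(az)
  lat <- asin(pmin(1, pmax(-1, sinl)))
  lon <- lam0 + atan2(sin(az) * sin(c_ang) * cos(phi0),
                      cos(c_ang) - sin(phi0) * sinl)
  out <- cbind(lat = lat / to_rad, lon = normalize_lon(lon / to_rad))
  # exactly at the centre the azimuth is undefined
  at0 <- r < 1e-12
  out[at0, 1] <- lat0
  out[at0, 2] <- lon0
  out
}

# Circular mean of longitudes (degrees); used for centroids near the antimeridian.
circular_mean_lon <- function(lon) {
  to_rad <- pi / 180
  normalize_lon(atan2(mean(sin(lon * to_rad)), mean(cos(lon * to_rad))) / to_rad)
}
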