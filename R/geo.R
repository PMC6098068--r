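#' Great-circle distance in kilometres
#'
#' Spherical great-circle (haversine) distance on a mean-radius Earth
#' (R = 6371.0 km), the metric used for all track statistics.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees (vectorised)
#' @return distance(s) in km
#' @examples
#' great_circle_km(0, 0, 180, 0)   # half the circumference, pi * 6371
#' @export
great_circle_km <- function(lon1, lat1, lon2, lat2) {
  stopifnot(all(abs(c(lat1, lat2)) <= 90))
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371)
}

EARTH_RADIUS_KM <- 6371
KM_PER_DEG <- pi * EARTH_RADIUS_KM / 180  # 111.1949 km per degree of arc

## Local tangent-plane (equirectangular) projection used by both the track
## simulator and the state-space model so that the Cartesian displacement
## process is exactly invertible to lon/lat. x is east, y is north, km,
## centred on (lon0, lat0); east-west scale is fixed at cos(lat0).
lonlat_to_km <- function(lon, lat, lon0, lat0) {
  dlon <- wrap_lon(lon - lon0)
  cbind(x = dlon * KM_PER_DEG * cos(lat0 * pi / 180),
        y = (lat - lat0) * KM_PER_DEG)
}

km_to_lonlat <- function(x, y, lon0, lat0) {
  cbind(lon = wrap_lon(lon0 + x / (KM_PER_DEG * cos(lat0 * pi / 180))),
        lat = lat0 + y / KM_PER_DEG)
}

## bilinear sampling of a field matrix [n_lon x n_lat] on regular axes;
## returns NA outside the grid
bilinear_sample <- function(field, lon_axis, lat_axis, lon, lat) {
  stopifnot(is.matrix(field))
  nx <- length(lon_axis); ny <- length(lat_axis)
  fx <- (lon - lon_axis[1]) / (lon_axis[2] - lon_axis[1]) + 1
  fy <- (lat - lat_axis[1]) / (lat_axis[2] - lat_axis[1]) + 1
  i0 <- floor(fx); j0 <- floor(fy)
  wx <- fx - i0; wy <- fy - j0
  ok <- !is.na(fx) & !is.na(fy) & i0 >= 1 & j0 >= 1 & i0 <= nx - 1 & j0 <= ny - 1
  ## points exactly on the far edges
  at_x_edge <- !is.na(fx) & abs(fx - nx) < 1e-9
  at_y_edge <- !is.na(fy) & abs(fy - ny) < 1e-9
  i0[at_x_edge] <- nx - 1; wx[at_x_edge] <- 1
  j0[at_y_edge] <- ny - 1; wy[at_y_edge] <- 1
  ok <- ok | (at_x_edge & j0 >= 1 & j0 <= ny - 1) | (at_y_edge & i0 >= 1 & i0 <= nx - 1)
  ok <- ok & i0 >= 1 & j0 >= 1 & i0 <= nx - 1 & j0 <= ny - 1
  out <- rep(NA_real_, length(lon))
  if (any(ok)) {
    i0k <- i0[ok]; j0k <- j0[ok]; wxk <- wx[ok]; wyk <- wy[ok]
    v00 <- field[cbind(i0k, j0k)]
    v10 <- field[cbind(i0k + 1, j0k)]
    v01 <- field[cbind(i0k, j0k + 1)]
    v11 <- field[cbind(i0k + 1, j0k + 1)]
    out[ok] <- v00 * (1 - wxk) * (1 - wyk) + v10 * wxk * (1 - wyk) +
      v01 * (1 - wxk) * wyk + v11 * wxk * wyk
  }
  out
}
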