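#' Simulate an environmental raster stack with a retreating ice edge
#'
#' Builds, on a common regular lon/lat grid: a static bathymetry field (a
#' smooth random field, metres, negative at sea), a static chlorophyll-a
#' climatology (mg m^-3, a three-month seasonal mean by construction), and
#' daily sea-ice concentration fields (%) for each requested month. The ice
#' edge is a zonal front (with a smooth longitudinal wiggle) that retreats
#' poleward at `retreat_km_per_month`; within-month variability follows a
#' fixed day-of-month pattern whose amplitude is concentrated near the edge
#' (the marginal ice zone), so the coefficient of variation is informative
#' there. With `retreat_km_per_month = 0` the monthly fields are identical;
#' with `ice_var_amp = 0` the daily fields are constant within each month.
#'
#' @param grid_spec list with `lon = c(min, max)`, `lat = c(min, max)` and
#'   `res` (degrees)
#' @param months character vector of consecutive `"YYYY-MM"` months (>= 3,
#'   so that two-month-lagged covariates exist for the later months)
#' @param seed integer seed
#' @param edge_lat0 initial latitude of the 50% ice-concentration front
#' @param retreat_km_per_month poleward (southward) retreat rate of the front
#' @param edge_width_deg latitudinal e-folding width of the front
#' @param ice_var_amp amplitude (%) of the within-month daily variability
#' @param bathy_base mean sea depth (negative metres)
#' @return an object of class `env_stack`: list with `lon`, `lat` (cell-centre
#'   axes), `bathymetry`, `chla` (matrices `[n_lon, n_lat]`), `ice` (named list
#'   of arrays `[n_lon, n_lat, n_days]` per month) and `months`
#' @export
simulate_env_stack <- function(grid_spec = list(lon = c(140, 180),
                                                lat = c(-70, -55), res = 0.5),
                               months = c("2008-10", "2008-11", "2008-12",
                                          "2009-01"),
                               seed = 1, edge_lat0 = -61,
                               retreat_km_per_month = 100,
                               edge_width_deg = 0.8, ice_var_amp = 8,
                               bathy_base = -3800) {
  if (length(months) < 3)
    stop("at least 3 consecutive months are needed for lag-2 covariates")
  mi <- vapply(months, function(m) as.integer(substr(m, 1, 4)) * 12L +
                 as.integer(substr(m, 6, 7)), integer(1))
  if (any(diff(mi) != 1L)) stop("months must be consecutive")
  set.seed(substream_seeds(seed, 1))
  lon <- seq(grid_spec$lon[1] + grid_spec$res / 2, grid_spec$lon[2],
             by = grid_spec$res)
  lat <- seq(grid_spec$lat[1] + grid_spec$res / 2, grid_spec$lat[2],
             by = grid_spec$res)
  nx <- length(lon); ny <- length(lat)

  ## smooth random field from a low-order 2-D cosine series
  smooth_field <- function(order = 4, sd = 1) {
    a <- matrix(rnorm((order + 1)^2, 0, sd / (order + 1)), order + 1)
    ph1 <- matrix(runif((order + 1)^2, 0, 2 * pi), order + 1)
    ph2 <- matrix(runif((order + 1)^2, 0, 2 * pi), order + 1)
    u <- (lon - lon[1]) / (lon[nx] - lon[1])
    v <- (lat - lat[1]) / (lat[ny] - lat[1])
    f <- matrix(0, nx, ny)
    for (p in 0:order) for (q in 0:order)
      f <- f + a[p + 1, q + 1] *
        (cos(pi * p * u + ph1[p + 1, q + 1]) %o% cos(pi * q * v + ph2[p + 1, q + 1]))
    f
  }

  bathymetry <- bathy_base + 1200 * smooth_field(4) +
    outer(rep(1, nx), 60 * (lat - lat[1]))   # gentle shoaling northwards
  bathymetry[bathymetry > -10] <- -10        # keep everything at sea
  chla <- exp(log(0.4) + 0.8 * smooth_field(3))

  retreat_deg <- retreat_km_per_month / KM_PER_DEG
  wiggle <- 1.2 * sin(2 * pi * (lon - lon[1]) / (lon[nx] - lon[1])) +
    0.6 * smooth_field(2)[, 1]
  day_phase <- smooth_field(2)

  ice <- list()
  for (m in seq_along(months)) {
    nd <- days_in_month(months[m])
    arr <- array(0, c(nx, ny, nd))
    for (d in seq_len(nd)) {
      edge <- edge_lat0 - retreat_deg * ((m - 1) + (d - 1) / nd)
      base <- sapply(seq_len(ny), function(j)
        100 / (1 + exp((lat[j] - (edge + wiggle)) / edge_width_deg)))
      if (ice_var_amp > 0) {
        amp <- ice_var_amp * exp(-((outer(rep(1, nx), lat) -
                                      (edge + wiggle)) / 2.5)^2)
        ## fixed 30-day nominal cycle so that months of different lengths
        ## share the same day-of-month pattern (zero retreat then gives
        ## identical monthly fields)
        base <- base + amp * sin(2 * pi * (d - 1) / 30 + day_phase)
      }
      arr[, , d] <- pmin(100, pmax(0, base))
    }
    ice[[months[m]]] <- arr
  }
  structure(list(lon = lon, lat = lat, bathymetry = bathymetry, chla = chla,
                 ice = ice, months = months, res = grid_spec$res),
            class = "env_stack")
}
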