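#' Bathymetric gradient magnitude field
#'
#' Central-difference slope magnitude of a bathymetry field, in metres per
#' km, with forward/backward differences at the grid edges. East-west cell
#' sizes use the local latitude.
#'
#' @param field bathymetry matrix `[n_lon, n_lat]` (metres)
#' @param lon,lat cell-centre axes (degrees)
#' @return gradient magnitude matrix (m per km)
#' @export
gradient_field <- function(field, lon, lat) {
  nx <- length(lon); ny <- length(lat)
  if (nx < 2 || ny < 2) stop("gradient needs at least a 2x2 field")
  dx_km <- outer(rep(diff(lon)[1], nx), KM_PER_DEG * cos(lat * pi / 180))
  dy_km <- diff(lat)[1] * KM_PER_DEG
  gx <- field
  gx[2:(nx - 1), ] <- (field[3:nx, ] - field[1:(nx - 2), ]) / (2 * dx_km[2:(nx - 1), ])
  gx[1, ] <- (field[2, ] - field[1, ]) / dx_km[1, ]
  gx[nx, ] <- (field[nx, ] - field[nx - 1, ]) / dx_km[nx, ]
  gy <- field
  gy[, 2:(ny - 1)] <- (field[, 3:ny] - field[, 1:(ny - 2)]) / (2 * dy_km)
  gy[, 1] <- (field[, 2] - field[, 1]) / dy_km
  gy[, ny] <- (field[, ny] - field[, ny - 1]) / dy_km
  sqrt(gx^2 + gy^2)
}

#' Monthly mean and coefficient of variation of daily ice fields
#'
#' Per-cell mean and CV (sample SD / mean) over the daily ice-concentration
#' fields of one month. Cells with zero mean have an undefined CV and are
#' returned as `NA`.
#'
#' @param daily array `[n_lon, n_lat, n_days]` of daily ice concentration (%)
#' @return list with `mean` and `cv` matrices
#' @export
ice_monthly_stats <- function(daily) {
  if (length(dim(daily)) != 3 || dim(daily)[3] < 2)
    stop("need at least 2 daily fields in the month")
  m <- apply(daily, c(1, 2), mean)
  s <- apply(daily, c(1, 2), sd)
  cv <- s / m
  cv[m == 0] <- NA_real_
  list(mean = m, cv = cv)
}

#' Distance to the ice edge
#'
#' Unsigned great-circle distance from each query point to the nearest edge
#' cell of a monthly mean ice field, where an edge cell has concentration at
#' or above the threshold (default 15%, the marginal-ice-zone convention) and
#' at least one 4-neighbour below it. Returns `NA` (with a message) when the
#' field contains no edge.
#'
#' @param mean_field monthly mean ice matrix `[n_lon, n_lat]`
#' @param lon,lat grid axes
#' @param points matrix or data frame with columns `lon`, `lat`
#' @param threshold edge concentration threshold (%)
#' @return numeric vector of distances (km)
#' @export
ice_edge_distance <- function(mean_field, lon, lat, points, threshold = 15) {
  pts <- as.data.frame(points)
  above <- mean_field >= threshold
  if (all(above) || !any(above)) {
    message("no ice edge at threshold ", threshold, "% in this field")
    return(rep(NA_real_, nrow(pts)))
  }
  nx <- nrow(above); ny <- ncol(above)
  pad <- function(m, di, dj) {
    out <- matrix(FALSE, nx, ny)
    si <- seq_len(nx) + di; sj <- seq_len(ny) + dj
    ok_i <- si >= 1 & si <= nx; ok_j <- sj >= 1 & sj <= ny
    out[ok_i, ok_j] <- !above[si[ok_i], sj[ok_j]]
    out
  }
  neigh_below <- pad(above, 1, 0) | pad(above, -1, 0) |
    pad(above, 0, 1) | pad(above, 0, -1)
  edge <- above & neigh_below
  if (!any(edge)) {
    message("no ice edge at threshold ", threshold, "% in this field")
    return(rep(NA_real_, nrow(pts)))
  }
  idx <- which(edge, arr.ind = TRUE)
  elon <- lon[idx[, 1]]; elat <- lat[idx[, 2]]
  vapply(seq_len(nrow(pts)), function(j)
    min(great_circle_km(pts$lon[j], pts$lat[j], elon, elat)), numeric(1))
}

#' Ice melt-rate field
#'
#' Per-cell melt rate between two consecutive monthly means, floored at zero
#' (it is a melt rate, not a change rate): `max(0, (prev - cur) / days)`,
#' with `days` the spacing between the month mid-points.
#'
#' @param mean_prev,mean_cur monthly mean ice matrices for months m-1 and m
#' @param days days between the two month mid-points
#' @return melt-rate matrix (% per day)
#' @export
melt_rate_field <- function(mean_prev, mean_cur, days) {
  stopifnot(days > 0, all(dim(mean_prev) == dim(mean_cur)))
  pmax((mean_prev - mean_cur) / days, 0)   # first argument keeps the dims
}

#' Extract the six environmental covariates at whale locations
#'
#' For every location at or south of the latitude cut-off (default 60 deg S),
#' samples the static fields bilinearly and matches the monthly ice fields by
#' the location's calendar month: mean ice concentration one month prior
#' (`ice_mn_lag1`), the coefficient of variation of ice concentration two
#' months prior (`ice_cv_lag2`), the melt rate for the location's month
#' (difference of the two bracketing monthly means), and the distance to the
#' current month's ice edge. Transforms applied: natural log with an additive
#' floor of 1e-6 for the bathymetric gradient and chlorophyll, square root
#' for the edge distance. The response is `y = 1` when the discrete state is
#' search (2), else 0. Rows with any missing covariate are dropped and
#' counted.
#'
#' @param track data frame with `whale_id`, `time`, `lon`, `lat` and either
#'   `b_mode` (classified tracks), `b` (posterior realisations) or `state`
#'   (simulated truth)
#' @param stack an `env_stack`
#' @param lat_cutoff keep locations with `lat <= lat_cutoff`
#' @param edge_threshold ice-edge concentration threshold (%)
#' @param eps additive floor applied before the log transforms
#' @param quiet suppress the dropped-row message
#' @return a `covariate_rows` data frame with columns `whale_id`, `time`,
#'   `lon`, `lat`, `y`, `log_bathyg`, `log_chla`, `sqrt_dist_ice`,
#'   `melt_rate`, `ice_cv_lag2`, `ice_mn_lag1`, `campaign`; the number of
#'   dropped rows is in attribute `n_dropped`
#' @export
extract_covariates <- function(track, stack, lat_cutoff = -60,
                               edge_threshold = 15, eps = 1e-6,
                               quiet = FALSE) {
  state_col <- intersect(c("b_mode", "b", "state"), names(track))[1]
  if (is.na(state_col)) stop("no behavioural state column in track")
  tr <- track[track$lat <= lat_cutoff, ]
  n_in <- nrow(tr)
  if (n_in == 0) {
    out <- data.frame(whale_id = character(), time = as.POSIXct(character(), tz = "UTC"),
                      lon = numeric(), lat = numeric(), y = integer(),
                      log_bathyg = numeric(), log_chla = numeric(),
                      sqrt_dist_ice = numeric(), melt_rate = numeric(),
                      ice_cv_lag2 = numeric(), ice_mn_lag1 = numeric(),
                      campaign = character())
    class(out) <- c("covariate_rows", "data.frame")
    return(out)
  }
  months <- month_of(tr$time)
  grad <- gradient_field(stack$bathymetry, stack$lon, stack$lat)
  bathyg <- bilinear_sample(grad, stack$lon, stack$lat, tr$lon, tr$lat)
  chla <- bilinear_sample(stack$chla, stack$lon, stack$lat, tr$lon, tr$lat)

  monthly <- lapply(stack$ice, ice_monthly_stats)
  need <- unique(months)
  dist_ice <- melt <- cv2 <- mn1 <- rep(NA_real_, n_in)
  for (m in need) {
    sel <- months == m
    m1 <- month_shift(m, -1); m2 <- month_shift(m, -2)
    if (m %in% names(monthly)) {
      dist_ice[sel] <- ice_edge_distance(monthly[[m]]$mean, stack$lon,
                                         stack$lat, tr[sel, c("lon", "lat")],
                                         threshold = edge_threshold)
      if (m1 %in% names(monthly)) {
        gap <- month_midpoint(m) - month_midpoint(m1)
        mr <- melt_rate_field(monthly[[m1]]$mean, monthly[[m]]$mean, gap)
        melt[sel] <- bilinear_sample(mr, stack$lon, stack$lat,
                                     tr$lon[sel], tr$lat[sel])
      }
    }
    if (m1 %in% names(monthly))
      mn1[sel] <- bilinear_sample(monthly[[m1]]$mean, stack$lon, stack$lat,
                                  tr$lon[sel], tr$lat[sel])
    if (m2 %in% names(monthly))
      cv2[sel] <- bilinear_sample(monthly[[m2]]$cv, stack$lon, stack$lat,
                                  tr$lon[sel], tr$lat[sel])
  }
  out <- data.frame(
    whale_id = tr$whale_id, time = tr$time, lon = tr$lon, lat = tr$lat,
    y = as.integer(tr[[state_col]] == 2),
    log_bathyg = log(bathyg + eps), log_chla = log(chla + eps),
    sqrt_dist_ice = sqrt(dist_ice), melt_rate = melt,
    ice_cv_lag2 = cv2, ice_mn_lag1 = mn1,
    campaign = if ("campaign" %in% names(tr)) tr$campaign else "SYN")
  keep <- complete.cases(out[, c("log_bathyg", "log_chla", "sqrt_dist_ice",
                                 "melt_rate", "ice_cv_lag2", "ice_mn_lag1")])
  n_dropped <- sum(!keep)
  if (n_dropped > 0 && !quiet)
    message(n_dropped, " location(s) dropped for missing covariates")
  out <- out[keep, ]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("covariate_rows", "data.frame")
  out
}

#' Collinearity screen on the covariate set
#'
#' Iteratively drops the covariate with the largest variance inflation factor
#' until every VIF is below the threshold (default 3), then inspects the
#' Pearson correlation matrix and, for any remaining pair with `|r|` at or
#' above the correlation threshold (default 0.8), drops the member with the
#' larger mean absolute correlation to the other covariates. Constant
#' covariates are dropped first with a warning.
#'
#' @param rows a `covariate_rows` data frame or any data frame of numeric
#'   covariates
#' @param covariates covariate column names (defaults to the six standard
#'   covariates present)
#' @param vif_threshold,r_threshold screen thresholds
#' @return list with `retained`, `dropped`, `vif` (final VIF table) and
#'   `cor` (final correlation matrix)
#' @export
collinearity_screen <- function(rows, covariates = NULL, vif_threshold = 3,
                                r_threshold = 0.8) {
  if (is.null(covariates))
    covariates <- intersect(c("log_bathyg", "log_chla", "sqrt_dist_ice",
                              "melt_rate", "ice_cv_lag2", "ice_mn_lag1"),
                            names(rows))
  stopifnot(length(covariates) >= 2, nrow(rows) >= 10)
  X <- as.data.frame(rows)[, covariates, drop = FALSE]
  dropped <- character(0)
  const <- vapply(X, function(v) sd(v) == 0 || !is.finite(sd(v)), logical(1))
  if (any(const)) {
    warning("constant covariate(s) dropped: ",
            paste(names(X)[const], collapse = ", "))
    dropped <- names(X)[const]
    X <- X[, !const, drop = FALSE]
  }
  vif_of <- function(X) {
    vapply(seq_along(X), function(j) {
      ## perfect fits (duplicated covariates) legitimately occur here
      r2 <- suppressWarnings(
        summary(lm(X[[j]] ~ ., data = X[, -j, drop = FALSE]))$r.squared)
      1 / max(1 - r2, 1e-12)
    }, numeric(1))
  }
  repeat {
    if (ncol(X) < 2) break
    v <- vif_of(X)
    if (max(v) < vif_threshold) break
    worst <- which.max(v)
    dropped <- c(dropped, names(X)[worst])
    X <- X[, -worst, drop = FALSE]
  }
  repeat {
    if (ncol(X) < 2) break
    cm <- cor(X)
    diag(cm) <- 0
    if (max(abs(cm)) < r_threshold) break
    pair <- which(abs(cm) == max(abs(cm)), arr.ind = TRUE)[1, ]
    mean_r <- rowMeans(abs(cm))
    worst <- pair[which.max(mean_r[pair])]
    dropped <- c(dropped, names(X)[worst])
    X <- X[, -worst, drop = FALSE]
  }
  list(retained = names(X), dropped = dropped,
       vif = if (ncol(X) >= 2) setNames(vif_of(X), names(X)) else
         setNames(rep(1, ncol(X)), names(X)),
       cor = if (ncol(X) >= 2) cor(X) else NULL)
}
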