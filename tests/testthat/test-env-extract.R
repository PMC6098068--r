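test_that("gradient field matches analytic slopes", {
  lon <- seq(0, 2, by = 0.1); lat <- seq(-0.5, 0.5, by = 0.1)
  ## constant field: zero gradient
  expect_true(all(gradient_field(matrix(5, length(lon), length(lat)),
                                 lon, lat) == 0))
  ## plane rising 2 m per km eastward (near the equator so cells are square)
  km_east <- outer(lon, cos(lat * pi / 180)) * pi * 6371 / 180
  g <- gradient_field(2 * km_east, lon, lat)
  interior <- g[2:(length(lon) - 1), 2:(length(lat) - 1)]
  expect_equal(max(abs(interior - 2)), 0, tolerance = 1e-3)
  ## radial seamount: steepest on the flank, flat at the peak
  lon2 <- seq(-1, 1, by = 0.05); lat2 <- seq(-1, 1, by = 0.05)
  r2 <- outer(lon2^2, rep(1, length(lat2))) + outer(rep(1, length(lon2)), lat2^2)
  mount <- -3000 + 2000 * exp(-r2 / 0.2)
  gm <- gradient_field(mount, lon2, lat2)
  centre <- c(which(lon2 == 0), which(lat2 == 0))
  expect_lt(gm[centre[1], centre[2]], 1e-6)
  expect_gt(max(gm), gm[centre[1], centre[2]])
  expect_error(gradient_field(matrix(1, 1, 1), 0, 0), "2x2")
})

test_that("monthly ice statistics compute mean and CV per cell", {
  daily <- array(80, c(3, 3, 30))
  st <- ice_monthly_stats(daily)
  expect_true(all(st$mean == 80) && all(st$cv == 0))
  ## alternating 40/60: mean 50, sample-SD based CV about 0.2034
  alt <- array(rep(c(40, 60), each = 9, length.out = 9 * 30), c(3, 3, 30))
  st2 <- ice_monthly_stats(alt)
  expect_equal(st2$mean[1, 1], 50)
  expect_equal(st2$cv[1, 1], sd(rep(c(40, 60), 15)) / 50, tolerance = 1e-12)
  expect_equal(st2$cv[1, 1], 0.2034, tolerance = 1e-3)
  ## all-zero cells have undefined CV
  z <- array(0, c(2, 2, 5))
  expect_true(all(is.na(ice_monthly_stats(z)$cv)))
  expect_error(ice_monthly_stats(array(1, c(2, 2, 1))), "2 daily fields")
})

test_that("ice-edge distance uses the 15% edge and spherical arcs", {
  lon <- seq(150, 160, by = 0.5); lat <- seq(-70, -58, by = 0.5)
  ## zonal edge: full ice south of -64, none north
  f <- outer(rep(1, length(lon)), ifelse(lat <= -64, 80, 0))
  d <- ice_edge_distance(f, lon, lat, data.frame(lon = 155, lat = -65))
  expect_equal(d, great_circle_km(155, -65, 155, -64), tolerance = 30 / 111)
  ## about one degree of meridional arc
  expect_equal(d, 111.19, tolerance = 30 / 111)
  ## a point on the edge itself is within half a cell diagonal
  d0 <- ice_edge_distance(f, lon, lat, data.frame(lon = 155, lat = -64))
  expect_lt(d0, great_circle_km(0, 0, 0.5, 0.5) / 2 + 1)
  ## no edge above threshold 100
  expect_message(dn <- ice_edge_distance(f, lon, lat,
                                         data.frame(lon = 155, lat = -65),
                                         threshold = 100), "no ice edge")
  expect_true(is.na(dn))
  ## monotone approach to a straight edge
  pts <- data.frame(lon = 155, lat = c(-68, -67, -66, -65))
  dm <- ice_edge_distance(f, lon, lat, pts)
  expect_true(all(diff(dm) < 0))
})

test_that("melt rate floors at zero and scales by day gap", {
  a <- matrix(80, 2, 2); b <- matrix(50, 2, 2)
  expect_true(all(melt_rate_field(a, b, 30) == 1))
  expect_true(all(melt_rate_field(b, a, 30) == 0))   # ice advance floored
  expect_true(all(melt_rate_field(a, a, 30) == 0))
})

test_that("covariate extraction matches analytic fields and lag conventions", {
  stack <- tiny_stack()
  ## inject hand-built ice months with distinguishable CVs and a real edge:
  ## lag-2 arithmetic must pick October's CV for a December location
  nx <- length(stack$lon); ny <- length(stack$lat)
  mk_month <- function(base_south, wiggle) {
    nd <- 30
    base <- outer(rep(1, nx), ifelse(stack$lat <= -64, base_south, 3))
    arr <- array(NA_real_, c(nx, ny, nd))
    for (d in seq_len(nd)) arr[, , d] <- base + wiggle * sin(2 * pi * d / nd)
    arr
  }
  stack$ice[["2008-10"]] <- mk_month(50, 20)
  stack$ice[["2008-11"]] <- mk_month(50, 5)
  stack$ice[["2008-12"]] <- mk_month(40, 1)
  ## query exactly at a cell centre so bilinear sampling is the cell value
  ci <- match(155.25, stack$lon); cj <- match(-65.25, stack$lat)
  tr <- data.frame(whale_id = "w1",
                   time = as.POSIXct("2008-12-10 00:00:00", tz = "UTC"),
                   lon = 155.25, lat = -65.25, state = 2L)
  rows <- extract_covariates(tr, stack, quiet = TRUE)
  expect_equal(nrow(rows), 1)
  oct_cv <- ice_monthly_stats(stack$ice[["2008-10"]])$cv[ci, cj]
  expect_equal(rows$ice_cv_lag2, oct_cv, tolerance = 1e-6)
  nov_mn <- ice_monthly_stats(stack$ice[["2008-11"]])$mean[ci, cj]
  expect_equal(rows$ice_mn_lag1, nov_mn, tolerance = 1e-6)
  expect_equal(rows$y, 1L)
  ## melt from November (50) to December (40) over the mid-point gap (30.5 d)
  gap <- as.numeric((as.Date("2008-12-01") + 31 / 2) -
                      (as.Date("2008-11-01") + 30 / 2))
  expect_equal(rows$melt_rate, 10 / gap, tolerance = 1e-6)
  ## flat bathymetry floors the log gradient at log(eps)
  stack2 <- stack
  stack2$bathymetry <- matrix(-3000, nx, ny)
  rows2 <- extract_covariates(tr, stack2, quiet = TRUE)
  expect_equal(rows2$log_bathyg, log(1e-6))
  ## latitude restriction
  trN <- tr; trN$lat <- -50
  expect_equal(nrow(extract_covariates(trN, stack, quiet = TRUE)), 0)
})

test_that("collinearity screen enforces VIF and correlation bounds", {
  set.seed(2)
  n <- 1000
  x1 <- rnorm(n); x2 <- rnorm(n)
  sc <- collinearity_screen(data.frame(a = x1, b = x2),
                            covariates = c("a", "b"))
  expect_setequal(sc$retained, c("a", "b"))
  expect_true(all(sc$vif < 1.1))
  ## exact duplicate: exactly one of the pair survives
  scd <- collinearity_screen(data.frame(a = x1, b = x1, c = x2),
                             covariates = c("a", "b", "c"))
  expect_length(intersect(scd$retained, c("a", "b")), 1)
  expect_true("c" %in% scd$retained)
  ## near-duplicate: x3 independent survives, one of x1/x2 goes
  x2n <- x1 + rnorm(n, 0, 0.01)
  scn <- collinearity_screen(data.frame(a = x1, b = x2n, c = x2),
                             covariates = c("a", "b", "c"))
  expect_true("c" %in% scn$retained)
  expect_length(intersect(scn$retained, c("a", "b")), 1)
  ## screened output satisfies both bounds
  expect_true(all(scn$vif < 3))
  if (!is.null(scn$cor)) {
    cm <- scn$cor; diag(cm) <- 0
    expect_true(all(abs(cm) < 0.8))
  }
  ## constant covariate dropped first with a warning
  expect_warning(collinearity_screen(data.frame(a = x1, b = rep(1, n), c = x2),
                                     covariates = c("a", "b", "c")),
                 "constant")
})
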