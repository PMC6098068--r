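test_that("persistence-1 noiseless walk is a straight meridian line", {
  p <- movement_params(gamma = c(1, 0.5), theta = c(0, pi),
                       stay_prob = c(1 - 1e-12, 0.5), process_sd = 1e-9)
  tr <- simulate_tracks(p, n_whales = 1, n_steps = 40, seed = 1)[[1]]
  expect_true(all(abs(tr$lon - tr$lon[1]) < 1e-6))
  expect_true(all(diff(tr$lat) < 0))
  steps <- diff(tr$y_km)
  expect_true(all(abs(steps - steps[1]) < 1e-6))
})

test_that("search-state turn angles concentrate near 180 degrees", {
  ## force the chain into state 2 and check the empirical mean turn angle
  p <- movement_params(gamma = c(0.8, 0.11), theta = c(0, pi),
                       stay_prob = c(1e-9, 1 - 1e-9), process_sd = 5)
  tr <- simulate_tracks(p, n_whales = 1, n_steps = 10000, seed = 7)[[1]]
  expect_true(mean(tr$state[-1] == 2) > 0.999)
  d <- cbind(diff(tr$x_km), diff(tr$y_km))
  v <- d[-nrow(d), ]; u <- d[-1, ]
  ang <- atan2(-u[, 1] * v[, 2] + u[, 2] * v[, 1], rowSums(u * v))
  circ_mean <- atan2(mean(sin(ang)), mean(cos(ang)))
  err_deg <- abs(((circ_mean - pi + pi) %% (2 * pi)) - pi) * 180 / pi
  expect_lt(err_deg, 5)
})

test_that("state sequence follows the Markov chain stationary distribution", {
  ## near-zero movement so a 1e5-step chain stays on the globe
  p <- movement_params(stay_prob = c(0.9, 0.9), process_sd = 1e-9)
  tr <- simulate_tracks(p, n_whales = 1, n_steps = 1e5, seed = 3,
                        step0_km = 0)[[1]]
  expect_equal(mean(tr$state == 2), 0.5, tolerance = 0.01 / 0.5)
  ## empirical transition matrix converges to the specified chain
  prev <- tr$state[-nrow(tr)]; nxt <- tr$state[-1]
  expect_equal(mean(nxt[prev == 1] == 1), 0.9, tolerance = 0.02)
  expect_equal(mean(nxt[prev == 2] == 2), 0.9, tolerance = 0.02)
})

test_that("noise-free Argos corruption reproduces interpolated truth", {
  p <- movement_params()
  tr <- simulate_tracks(p, n_whales = 2, n_steps = 30, seed = 5)
  em <- argos_error_model(scale_km = c(`3` = 1e-12, `2` = 2e-12, `1` = 3e-12,
                                       `0` = 4e-12, A = 5e-12, B = 6e-12))
  obs <- corrupt_to_argos(tr, em, obs_per_day = 4, seed = 6)
  for (id in unique(obs$whale_id)) {
    o <- obs[obs$whale_id == id, ]
    t_ <- tr[[which(vapply(tr, function(x) x$whale_id[1], "") == id)]]
    pos <- as.numeric(difftime(o$time, t_$time[1], units = "hours")) / 12
    k <- pmin(floor(pos) + 1, nrow(t_) - 1); f <- pos - (k - 1)
    expect_equal(o$lat, (1 - f) * t_$lat[k] + f * t_$lat[k + 1], tolerance = 1e-6)
  }
})

test_that("poor location classes displace fixes more than good ones", {
  p <- movement_params()
  tr <- simulate_tracks(p, n_whales = 3, n_steps = 60, seed = 5)
  only <- function(cl) {
    fr <- setNames(rep(1e-9, 6), c("3", "2", "1", "0", "A", "B"))
    fr[cl] <- 1 - 5e-9
    argos_error_model(class_freq = fr)
  }
  rms <- function(obs) {
    err <- numeric(0)
    for (id in unique(obs$whale_id)) {
      o <- obs[obs$whale_id == id, ]
      t_ <- tr[[which(vapply(tr, function(x) x$whale_id[1], "") == id)]]
      pos <- as.numeric(difftime(o$time, t_$time[1], units = "hours")) / 12
      k <- pmin(floor(pos) + 1, nrow(t_) - 1); f <- pos - (k - 1)
      err <- c(err, great_circle_km(o$lon, o$lat,
                                    (1 - f) * t_$lon[k] + f * t_$lon[k + 1],
                                    (1 - f) * t_$lat[k] + f * t_$lat[k + 1]))
    }
    sqrt(mean(err^2))
  }
  rms3 <- rms(corrupt_to_argos(tr, only("3"), obs_per_day = 6, seed = 8))
  rmsB <- rms(corrupt_to_argos(tr, only("B"), obs_per_day = 6, seed = 8))
  expect_gt(rmsB, rms3)
})

test_that("observation thinning matches the requested daily rate", {
  p <- movement_params()
  tr <- simulate_tracks(p, n_whales = 1, n_steps = 61, seed = 2)  # 30 days
  obs <- corrupt_to_argos(tr, obs_per_day = 2, seed = 4)
  expect_lt(abs(nrow(obs) - 60), 4 * sqrt(60))
  expect_equal(corrupt_to_argos(list(), obs_per_day = 2, seed = 1) |> nrow(), 0)
})

test_that("environmental stack responds to its controls", {
  gs <- list(lon = c(150, 160), lat = c(-68, -58), res = 0.5)
  mo <- c("2008-11", "2008-12", "2009-01")
  ## zero retreat: monthly fields identical
  s0 <- simulate_env_stack(gs, mo, seed = 1, retreat_km_per_month = 0)
  expect_equal(s0$ice[["2008-12"]][, , 3], s0$ice[["2008-11"]][, , 3])
  ## no daily variability and no retreat: within-month CV is zero wherever
  ## defined
  sc <- simulate_env_stack(gs, mo, seed = 1, ice_var_amp = 0,
                           retreat_km_per_month = 0)
  cv <- ice_monthly_stats(sc$ice[["2008-12"]])$cv
  expect_true(all(cv[!is.na(cv)] < 1e-10))
  ## retreat moves the edge poleward by about the requested distance
  s1 <- simulate_env_stack(gs, mo, seed = 1, retreat_km_per_month = 100,
                           ice_var_amp = 0)
  pt <- data.frame(lon = 155, lat = -66)
  d1 <- ice_edge_distance(ice_monthly_stats(s1$ice[["2008-11"]])$mean,
                          s1$lon, s1$lat, pt)
  d2 <- ice_edge_distance(ice_monthly_stats(s1$ice[["2008-12"]])$mean,
                          s1$lon, s1$lat, pt)
  expect_equal(abs(d2 - d1), 100, tolerance = 45 / 100)
  expect_error(simulate_env_stack(gs, mo[1:2], seed = 1), "3 consecutive")
})

test_that("behaviour-environment coupling has the specified logistic effects", {
  stack <- tiny_stack()
  p <- movement_params(gamma = c(0.5, 0.1), stay_prob = c(0.85, 0.85),
                       process_sd = 8)
  tracks <- simulate_tracks(p, n_whales = 8, n_steps = 100,
                            start = list(lon = 152, lat = -60,
                                         time = as.POSIXct("2008-12-01",
                                                           tz = "UTC")),
                            seed = 11, step0_km = 15)
  ## all effects zero: search fraction near one half
  t0 <- couple_behaviour_to_env(tracks, stack, effect = c("(Intercept)" = 0),
                                seed = 1)
  states <- unlist(lapply(t0, `[[`, "state"))
  expect_equal(mean(states == 2), 0.5, tolerance = 0.08 / 0.5)
  ## saturating negative intercept: no search at coupled locations
  tneg <- couple_behaviour_to_env(tracks, stack,
                                  effect = c("(Intercept)" = -20), seed = 1)
  all_tr <- do.call(rbind, tneg)
  rows <- extract_covariates(all_tr, stack, lat_cutoff = Inf, quiet = TRUE)
  expect_true(all(rows$y == 0))
  ## strong positive melt effect: search concentrates where melt is high
  tm <- couple_behaviour_to_env(tracks, stack,
                                effect = c("(Intercept)" = 0, melt_rate = 3),
                                seed = 2)
  rows <- extract_covariates(do.call(rbind, tm), stack, lat_cutoff = Inf,
                             quiet = TRUE)
  hi <- rows$melt_rate > median(rows$melt_rate)
  expect_gt(mean(rows$y[hi]), mean(rows$y[!hi]))
})

test_that("deployment fixture matches its published row anchors", {
  fx <- load_table1_fixture()
  expect_equal(nrow(fx), 30)
  w <- fx[fx$ptt == "88729", ]
  expect_equal(w$search_days_total, 56)
  expect_equal(w$max_patch_days, 37)
  expect_equal(w$search_days_au_ec, 3)
  expect_equal(w$search_days_ant, 53)
  expect_equal(fx$duration_days[fx$ptt == "88744"], 3)
  expect_equal(range(fx$duration_days), c(3, 155))
  ## region-count invariants
  ant <- !is.na(fx$search_days_ant) & fx$search_days_ant > 0
  expect_equal(sum(ant), 16)
  au <- fx$tagging_location %in% c("AU-Eden", "AU-SC")
  temperate <- !is.na(fx$search_days_total) &
    (fx$search_days_au_ec > 0 | fx$search_days_ts > 0)
  expect_equal(sum(au), 21)
  expect_equal(sum(temperate & au), 10)
})
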