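test_that("great-circle distances match closed forms", {
  expect_equal(great_circle_km(150, -37, 150, -37), 0)
  expect_equal(great_circle_km(0, 0, 180, 0), pi * 6371, tolerance = 1e-7)
  d <- great_circle_km(150, -37, 151, -37)
  expect_equal(d, haversine_oracle(150, -37, 151, -37), tolerance = 1e-6)
})

test_that("patch segmentation follows the stated rule on hand traces", {
  p1 <- segment_search_patches(c(1.9, 1.9, 1.8, 1.0, 1.0, 1.0, 1.9))
  expect_equal(nrow(p1), 2)
  expect_equal(p1$start_idx, c(1, 7))
  expect_equal(p1$end_idx, c(3, 7))
  expect_equal(p1$duration_days, c(1.5, 0.5))
  expect_equal(nrow(segment_search_patches(rep(1.2, 10))), 0)
  ## a sub-threshold run shorter than 3 does not terminate the patch
  p2 <- segment_search_patches(c(1.9, 1.0, 1.0, 1.9))
  expect_equal(nrow(p2), 1)
  expect_equal(c(p2$start_idx, p2$end_idx), c(1, 4))
  expect_equal(p2$n_locations, 2)   # only the two above-threshold locations
})

test_that("patch segmentation agrees with the brute-force oracle", {
  set.seed(10)
  for (rep in 1:1000) {
    n <- sample(1:50, 1)
    b <- runif(n, 1, 2)
    got <- segment_search_patches(b)
    want <- patch_oracle(b)
    expect_equal(got$start_idx, want$start_idx)
    expect_equal(got$end_idx, want$end_idx)
    expect_equal(got$n_locations, want$n_locations)
    ## duration bookkeeping invariant
    expect_equal(sum(got$duration_days), 0.5 * sum(want$n_locations))
  }
})

test_that("regions are assigned by latitude and the Tasman boundary", {
  expect_equal(assign_region(160, -65), "ANT")
  expect_equal(assign_region(165, -45), "TS")
  expect_equal(assign_region(150, -37), "AU-EC")
  expect_equal(assign_region(c(150, 165, 160), c(-37, -45, -65)),
               c("AU-EC", "TS", "ANT"))
})

test_that("initial trajectory classes follow the meridian-crossing rules", {
  t0 <- as.POSIXct("2008-11-01", tz = "UTC")
  mk <- function(lon, lat) data.frame(time = t0 + seq_along(lon) * 43200,
                                      lon = lon, lat = lat)
  east <- mk(seq(150, 165, by = 1), seq(-37, -45, length.out = 16))
  expect_equal(classify_trajectory(east), "East")
  west <- mk(seq(150, 140, by = -1), seq(-37, -42, length.out = 11))
  expect_equal(classify_trajectory(west), "West")
  south <- mk(rep(150, 12), seq(-37, -59, by = -2))
  expect_equal(classify_trajectory(south), "South")
  ## an Antarctic-tagged whale never north of 60 S gets the NA marker
  ant <- mk(seq(150, 170, by = 2), rep(-66, 11))
  expect_true(is.na(classify_trajectory(ant)))
  ## eastbound across the dateline still counts as East
  dateline <- mk(c(150, 170, 179, -175, -170), rep(-50, 5))
  expect_equal(classify_trajectory(dateline), "East")
})

test_that("parallel crossing interpolates linearly in time", {
  t0 <- as.POSIXct("2008-12-01 00:00:00", tz = "UTC")
  tr <- data.frame(time = t0 + c(0, 12 * 3600), lat = c(-59.5, -60.5),
                   lon = c(150, 150))
  expect_equal(parallel_crossing(tr), t0 + 6 * 3600)
  none <- data.frame(time = t0 + c(0, 43200), lat = c(-50, -55), lon = c(150, 150))
  expect_null(parallel_crossing(none))
  ## invariant to inserting collinear intermediate locations
  tr3 <- data.frame(time = t0 + c(0, 6, 12) * 3600,
                    lat = c(-59.5, -60, -60.5), lon = 150)
  expect_equal(parallel_crossing(tr3), parallel_crossing(tr))
})

test_that("movement summaries reproduce arithmetic anchors", {
  t0 <- as.POSIXct("2008-12-01 00:00:00", tz = "UTC")
  ## stationary track
  still <- data.frame(whale_id = "w", time = t0 + (0:10) * 43200,
                      lon = 150, lat = -50, b_mean = 1, b_mode = 1L)
  s <- summarize_movement(still)
  expect_equal(s$distance_km, 0)
  ## 39 km each 12 h southwards for 10 days: 78 km/day and 3.25 km/h
  n <- 21
  lat <- -40 - (0:(n - 1)) * 39 / (pi * 6371 / 180)
  tr <- data.frame(whale_id = "w", time = t0 + (0:(n - 1)) * 43200,
                   lon = 150, lat = lat, b_mean = 1, b_mode = 1L)
  s2 <- summarize_movement(tr)
  expect_equal(s2$km_per_day_north, 78, tolerance = 1e-6)
  expect_equal(s2$km_per_h_north, 3.25, tolerance = 1e-6)
  ## cumulative distance matches the generator's own path ledger
  p <- movement_params()
  sim <- simulate_tracks(p, n_whales = 1, n_steps = 50, seed = 9)[[1]]
  cls <- data.frame(whale_id = sim$whale_id, time = sim$time, lon = sim$lon,
                    lat = sim$lat, b_mean = 1, b_mode = 1L)
  s3 <- summarize_movement(cls)
  expect_equal(s3$distance_km, attr(sim, "path_km"), tolerance = 1e-9)
  ## north + south split sums exactly to the total across the 60 S crossing
  lat2 <- seq(-55, -65, length.out = 30)
  tr2 <- data.frame(whale_id = "w", time = t0 + (0:29) * 43200,
                    lon = seq(150, 155, length.out = 30), lat = lat2,
                    b_mean = 1, b_mode = 1L)
  s4 <- summarize_movement(tr2)
  expect_equal(s4$distance_north_km + s4$distance_south_km, s4$distance_km)
  expect_false(is.na(s4$crossing_time))
})

test_that("cohort table aggregates movement summaries by trajectory", {
  t0 <- as.POSIXct("2008-11-01", tz = "UTC")
  mk <- function(id, lon, lat) data.frame(whale_id = id,
                                          time = t0 + seq_along(lon) * 43200,
                                          lon = lon, lat = lat,
                                          b_mean = 1, b_mode = 1L)
  trks <- rbind(mk("e1", seq(150, 165, 1), seq(-37, -45, length.out = 16)),
                mk("s1", rep(150, 12), seq(-37, -59, by = -2)),
                mk("s2", rep(151, 12), seq(-40, -62, by = -2)))
  ct <- cohort_table(summarize_movement(trks))
  tot <- ct[ct$group == "Total", ]
  expect_equal(tot$n, 3)
  expect_equal(tot$n_east, 1)
  expect_equal(tot$n_south, 2)
  expect_equal(tot$n_crossed_60s, 1)
  expect_equal(tot$pct_east, 33.3)
})

test_that("cohort table reproduces the published aggregate anchors", {
  ct <- cohort_table(load_table1_fixture())
  tot <- ct[ct$group == "Total", ]
  expect_equal(round(tot$duration_mean), 50)
  expect_equal(round(tot$duration_sd), 35)
  expect_equal(round(tot$distance_mean), 3271)
  expect_equal(round(tot$distance_sd), 2414)
  expect_equal(tot$n_antarctic, 16)
  expect_equal(round(100 * 16 / 30), 53)
  eden <- ct[ct$group == "AU-Eden", ]
  expect_equal(round(eden$duration_mean), 55)
  expect_equal(round(eden$distance_mean, 1), 3809.5)
  expect_equal(eden$n_temperate_ec + eden$n_temperate_ts, 10)
  expect_equal(eden$n_antarctic, 7)
  sc <- ct[ct$group == "AU-SC", ]
  expect_equal(sc$n, 5)
  expect_equal(sc$n_antarctic, 2)
  ant <- ct[ct$group == "ANT", ]
  expect_equal(round(ant$duration_mean), 37)
  expect_equal(ant$n_antarctic, 7)
})
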