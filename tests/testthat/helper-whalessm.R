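## shared fixtures and small oracles used across test files

## a tiny environmental stack, cached per test run
tiny_stack <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_env_stack(
        grid_spec = list(lon = c(140, 170), lat = c(-70, -56), res = 0.5),
        months = c("2008-10", "2008-11", "2008-12", "2009-01"),
        seed = 42)
    cache
  }
})

## independent haversine closed form (test oracle for great_circle_km)
haversine_oracle <- function(lon1, lat1, lon2, lat2, R = 6371) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * R * asin(pmin(1, sqrt(a)))
}

## brute-force patch oracle: enumerates candidate patch memberships literally.
## A location belongs to the current patch while the running count of
## consecutive at-or-below-threshold locations since the last above-threshold
## location stays below `gap`; implemented as an explicit membership walk,
## independent of the package's scan.
patch_oracle <- function(b, threshold = 1.75, gap = 3) {
  above <- b > threshold
  membership <- integer(length(b))   # 0 = no patch
  patch_id <- 0L
  i <- 1
  while (i <= length(b)) {
    if (above[i]) {
      patch_id <- patch_id + 1L
      j <- i
      last_above <- i
      below_run <- 0L
      while (j <= length(b)) {
        if (above[j]) {
          last_above <- j
          below_run <- 0L
        } else {
          below_run <- below_run + 1L
          if (below_run >= gap) break
        }
        j <- j + 1
      }
      membership[i:last_above] <- patch_id
      i <- if (j > length(b)) j else j + 1
    } else i <- i + 1
  }
  if (patch_id == 0L)
    return(data.frame(start_idx = integer(), end_idx = integer(),
                      n_locations = integer()))
  do.call(rbind, lapply(seq_len(patch_id), function(p) {
    idx <- which(membership == p)
    data.frame(start_idx = min(idx), end_idx = max(idx),
               n_locations = sum(above[idx]))
  }))
}

## build a minimal ssm_posterior object by hand, for classification and
## realisation-drawing tests (and to inject near-certain synthetic posteriors)
fake_posterior <- function(b_samples, xy_samples, times, origin,
                           whale_ids = NULL, n_chains = 2) {
  ## b_samples: list per chain of array [kept, nw, Tmax]
  ## xy_samples: list per chain of array [kept, nw, Tmax, 2] (km)
  nw <- dim(b_samples[[1]])[2]
  Tmax <- dim(b_samples[[1]])[3]
  if (is.null(whale_ids)) whale_ids <- sprintf("W%02d", seq_len(nw))
  kept <- dim(b_samples[[1]])[1]
  chains <- lapply(seq_len(n_chains), function(ch)
    list(gamma = matrix(c(0.8, 0.1), kept, 2, byrow = TRUE),
         theta = matrix(c(0, pi), kept, 2, byrow = TRUE),
         alpha = matrix(0.9, kept, 2),
         sigma = matrix(10, kept, nw),
         b = b_samples[[ch]], x_km = xy_samples[[ch]]))
  structure(list(whale_ids = whale_ids, Tn = rep(Tmax, nw), Tmax = Tmax,
                 times = setNames(rep(list(times), nw), whale_ids),
                 origin = matrix(rep(origin, each = nw), nw, 2,
                                 dimnames = list(whale_ids, c("lon", "lat"))),
                 chains = chains,
                 config = mcmc_config(n_chains = n_chains, n_iter = 100,
                                      burn_in = 50, thin = 1, seed = 1),
                 error_model = argos_error_model(), campaign = "SYN",
                 rhat = c(gamma1 = 1, gamma2 = 1, theta1 = 1, theta2 = 1),
                 converged = TRUE),
            class = "ssm_posterior")
}

## near-certain synthetic posterior around a set of true tracks: states are
## the truth with a small flip probability, locations the truth plus noise
posterior_from_truth <- function(tracks, kept = 60, flip = 0.03,
                                 loc_sd_km = 3, seed = 99) {
  set.seed(seed)
  nw <- length(tracks)
  Tmax <- max(vapply(tracks, nrow, integer(1)))
  org <- attr(tracks[[1]], "origin")
  mk <- function() {
    b <- array(NA_integer_, c(kept, nw, Tmax))
    xy <- array(NA_real_, c(kept, nw, Tmax, 2))
    for (i in seq_len(nw)) {
      tr <- tracks[[i]]
      for (s in seq_len(kept)) {
        fl <- runif(nrow(tr)) < flip
        b[s, i, seq_len(nrow(tr))] <- ifelse(fl, 3L - tr$state, tr$state)
        xy[s, i, seq_len(nrow(tr)), 1] <- tr$x_km + rnorm(nrow(tr), 0, loc_sd_km)
        xy[s, i, seq_len(nrow(tr)), 2] <- tr$y_km + rnorm(nrow(tr), 0, loc_sd_km)
      }
    }
    list(b = b, xy = xy)
  }
  c1 <- mk(); c2 <- mk()
  post <- fake_posterior(list(c1$b, c2$b), list(c1$xy, c2$xy),
                         times = tracks[[1]]$time, origin = org,
                         whale_ids = vapply(tracks, function(t) t$whale_id[1],
                                            character(1)))
  post$Tn <- vapply(tracks, nrow, integer(1))
  post$times <- setNames(lapply(tracks, `[[`, "time"), post$whale_ids)
  post
}
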