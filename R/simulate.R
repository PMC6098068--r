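#' Simulate two-state switching correlated-random-walk tracks
#'
#' Generates ground-truth whale tracks on a regular 12-h grid. Behavioural
#' states follow a two-state Markov chain with self-transition probabilities
#' `stay_prob`; the displacement at step t is the previous displacement rotated
#' by the state's mean turn angle, damped by the state's persistence, plus
#' isotropic Gaussian process noise:
#' `d_t = gamma[b_t] * R(theta[b_t]) %*% d_{t-1} + eps`.
#' The walk lives on a local tangent plane in km centred on the start position
#' and is mapped to lon/lat with a fixed equirectangular projection, so the
#' Cartesian process is exactly invertible from the geographic coordinates.
#'
#' @param params a [movement_params()] object; `process_sd` is recycled over
#'   whales
#' @param n_whales number of whales
#' @param n_steps number of 12-h locations per whale (>= 3)
#' @param start list with `lon`, `lat` (degrees) and `time` (POSIXct UTC) of
#'   the common deployment origin
#' @param seed integer master seed (expanded into per-whale substreams)
#' @param step0_km length of the initial displacement (km per 12 h), headed
#'   due south
#' @return list of `true_track` data frames with columns `whale_id`, `time`,
#'   `lon`, `lat`, `x_km`, `y_km`, `state`; attributes `origin` and `path_km`
#'   (cumulative great-circle path length ledger)
#' @export
simulate_tracks <- function(params, n_whales, n_steps,
                            start = list(lon = 150.07, lat = -37.15,
                                         time = as.POSIXct("2008-10-25 00:00:00",
                                                           tz = "UTC")),
                            seed = 1, step0_km = 39) {
  stopifnot(inherits(params, "movement_params"))
  if (n_steps < 3) stop("n_steps must be >= 3")
  sds <- rep_len(params$process_sd, n_whales)
  seeds <- substream_seeds(seed, n_whales)
  times <- start$time + (seq_len(n_steps) - 1) * 12 * 3600
  lapply(seq_len(n_whales), function(i) {
    set.seed(seeds[i])
    b <- integer(n_steps)
    b[1] <- 1L
    for (t in 2:n_steps) {
      stay <- params$stay_prob[b[t - 1]]
      b[t] <- if (runif(1) < stay) b[t - 1] else 3L - b[t - 1]
    }
    xy <- matrix(0, n_steps, 2)
    xy[2, ] <- c(0, -step0_km)
    for (t in 3:n_steps) {
      g <- params$gamma[b[t]]; th <- params$theta[b[t]]
      d <- xy[t - 1, ] - xy[t - 2, ]
      mu <- xy[t - 1, ] + g * c(cos(th) * d[1] - sin(th) * d[2],
                                sin(th) * d[1] + cos(th) * d[2])
      xy[t, ] <- mu + rnorm(2, 0, sds[i])
    }
    ll <- km_to_lonlat(xy[, 1], xy[, 2], start$lon, start$lat)
    trk <- data.frame(whale_id = sprintf("SIM%02d", i), time = times,
                      lon = ll[, "lon"], lat = ll[, "lat"],
                      x_km = xy[, 1], y_km = xy[, 2], state = b)
    attr(trk, "origin") <- c(lon = start$lon, lat = start$lat)
    attr(trk, "path_km") <- sum(great_circle_km(ll[-n_steps, "lon"], ll[-n_steps, "lat"],
                                                ll[-1, "lon"], ll[-1, "lat"]))
    class(trk) <- c("true_track", "data.frame")
    trk
  })
}

#' Corrupt true tracks into duty-cycled Argos observations
#'
#' Thins each 12-h track to an irregular observation stream (a Poisson process
#' at `obs_per_day` fixes per day), interpolates the true position at each
#' observation time, assigns an Argos location class by the error model's
#' class frequencies, and adds independent Student-t errors in the east and
#' north components scaled by the class error scale. Optionally emits invalid
#' class-Z fixes (junk locations) at rate `p_invalid`; these carry no usable
#' position and are dropped by [prefilter_observations()].
#'
#' @param tracks list of `true_track` objects from [simulate_tracks()]
#' @param error_model an [argos_error_model()]
#' @param obs_per_day expected number of fixes per day (> 0)
#' @param seed integer master seed
#' @param p_invalid probability that a fix is an invalid class-Z location
#' @param campaign campaign label attached to every observation
#' @return `argos_obs` data frame with columns `whale_id`, `time`, `lon`,
#'   `lat`, `loc_class`, `campaign`, sorted by whale then time
#' @export
corrupt_to_argos <- function(tracks, error_model = argos_error_model(),
                             obs_per_day = 6, seed = 1, p_invalid = 0,
                             campaign = "SYN") {
  stopifnot(inherits(error_model, "argos_error_model"), obs_per_day > 0)
  seeds <- substream_seeds(seed, max(1L, length(tracks)))
  out <- lapply(seq_along(tracks), function(i) {
    trk <- tracks[[i]]
    if (nrow(trk) == 0) return(NULL)
    set.seed(seeds[i])
    span_days <- as.numeric(difftime(max(trk$time), min(trk$time), units = "days"))
    n_obs <- rpois(1, obs_per_day * span_days)
    if (n_obs == 0) return(NULL)
    tt <- sort(runif(n_obs, 0, span_days))
    obs_time <- min(trk$time) + tt * 86400
    org <- attr(trk, "origin")
    step_pos <- tt * 2  # position on the 12-h grid, 0-based
    k <- pmin(floor(step_pos) + 1, nrow(trk) - 1)
    f <- step_pos - (k - 1)
    px <- (1 - f) * trk$x_km[k] + f * trk$x_km[k + 1]
    py <- (1 - f) * trk$y_km[k] + f * trk$y_km[k + 1]
    cls <- sample(names(error_model$class_freq), n_obs, replace = TRUE,
                  prob = error_model$class_freq)
    if (p_invalid > 0) cls[runif(n_obs) < p_invalid] <- "Z"
    sc <- ifelse(cls == "Z", 500, error_model$scale_km[cls])
    dfree <- ifelse(cls == "Z", 5, error_model$df[cls])
    ex <- sc * rt(n_obs, dfree)
    ey <- sc * rt(n_obs, dfree)
    ll <- km_to_lonlat(px + ex, py + ey, org["lon"], org["lat"])
    data.frame(whale_id = trk$whale_id[1], time = obs_time,
               lon = ll[, "lon"], lat = ll[, "lat"], loc_class = cls,
               campaign = campaign)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(whale_id = character(), time = as.POSIXct(character(), tz = "UTC"),
                      lon = numeric(), lat = numeric(), loc_class = character(),
                      campaign = character())
  out <- out[order(out$whale_id, out$time), ]
  rownames(out) <- NULL
  class(out) <- c("argos_obs", "data.frame")
  out
}

#' Re-draw behavioural states from an environmental logistic coupling
#'
#' Replaces the Markov-chain states of simulated tracks with independent
#' draws whose search probability follows a logistic model in the (internally
#' standardised) environmental covariates extracted from a raster stack:
#' `P(state = search) = plogis(intercept + sum(effect * covariate_z))`.
#' This provides ground truth with a known behaviour-environment coupling for
#' testing the habitat model. Locations where a covariate cannot be computed
#' keep their original state and are reported via the `n_skipped` attribute.
#'
#' @param tracks list of `true_track` objects
#' @param stack an `env_stack`
#' @param effect named numeric log-odds coefficients per standard deviation of
#'   the named covariate columns (see [extract_covariates()] for names);
#'   an unnamed first element or a `"(Intercept)"` entry is the intercept
#' @param seed integer seed
#' @param lat_cutoff latitude cut applied when extracting covariates
#'   (default none: the coupling applies wherever covariates exist)
#' @return the track list with `state` re-drawn
#' @export
couple_behaviour_to_env <- function(tracks, stack, effect, seed = 1,
                                    lat_cutoff = Inf) {
  intercept <- if ("(Intercept)" %in% names(effect)) effect[["(Intercept)"]] else 0
  slopes <- effect[setdiff(names(effect), "(Intercept)")]
  all_tracks <- do.call(rbind, lapply(tracks, function(t)
    t[, c("whale_id", "time", "lon", "lat", "state")]))
  rows <- extract_covariates(all_tracks, stack, lat_cutoff = lat_cutoff,
                             quiet = TRUE)
  set.seed(substream_seeds(seed, 1))
  n_skipped <- 0L
  for (i in seq_along(tracks)) {
    trk <- tracks[[i]]
    ri <- rows[rows$whale_id == trk$whale_id[1], ]
    eta <- rep(intercept, nrow(ri))
    for (nm in names(slopes)) {
      z <- ri[[nm]]
      s <- sd(rows[[nm]])
      if (!is.finite(s) || s == 0) s <- 1
      eta <- eta + slopes[[nm]] * (z - mean(rows[[nm]])) / s
    }
    new_state <- 1L + rbinom(nrow(ri), 1, stats::plogis(eta))
    m <- match(ri$time, trk$time)
    trk$state[m] <- new_state
    n_skipped <- n_skipped + (nrow(trk) - nrow(ri))
    tracks[[i]] <- trk
  }
  if (n_skipped > 0)
    message(n_skipped, " locations lacked covariates; their states were kept")
  attr(tracks, "n_skipped") <- n_skipped
  tracks
}
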