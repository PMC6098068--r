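#' MCMC schedule for the state-space model
#'
#' Defaults follow the full fitting schedule used for campaign-scale analyses:
#' two parallel chains of 100,000 iterations, the first 50,000 discarded as
#' burn-in and the remainder thinned to every 50th sample (1,000 retained per
#' chain). Reduced schedules are appropriate for simulation studies.
#'
#' @param n_chains number of chains
#' @param n_iter iterations per chain
#' @param burn_in burn-in iterations discarded per chain
#' @param thin thinning interval; `(n_iter - burn_in) / thin` must be a
#'   positive integer
#' @param seed integer seed
#' @return an `mcmc_config` list
#' @export
mcmc_config <- function(n_chains = 2, n_iter = 100000, burn_in = 50000,
                        thin = 50, seed = 1) {
  kept <- (n_iter - burn_in) / thin
  if (kept <= 0 || kept != round(kept))
    stop("(n_iter - burn_in) / thin must be a positive integer")
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 n_kept = as.integer(kept), seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Build the regular 12-h state grid for a set of observations
#'
#' For each whale, lays a regular grid of state times (default 12 h step)
#' covering its observation window and maps every observation to its
#' bracketing interval index and fractional position. By default the grid is
#' anchored to absolute UTC bin boundaries (midnight / noon for a 12-h step),
#' so state estimates fall at the same instants for every whale and are
#' directly comparable across individuals and campaigns;
#' `anchor = "first_obs"` starts the grid at each whale's first observation
#' instead. Whales with fewer than 2 usable observations are excluded with a
#' warning. Fractions lie in [0, 1); an observation falling exactly on the
#' final grid time is assigned to the last interval with fraction 1.
#'
#' @param obs an `argos_obs` data frame
#' @param dt_hours state time step in hours
#' @param anchor `"utc"` (absolute UTC bins) or `"first_obs"`
#' @return a `state_grid`: list with `dt_hours` and per-whale elements
#'   `times` (POSIXct grid), `k` (interval index per observation), `f`
#'   (fraction), `obs_rows` (row indices into `obs`)
#' @export
build_state_grid <- function(obs, dt_hours = 12, anchor = c("utc", "first_obs")) {
  anchor <- match.arg(anchor)
  ids <- sort(unique(obs$whale_id))
  whales <- list()
  for (id in ids) {
    rows <- which(obs$whale_id == id)
    if (length(rows) < 2) {
      warning("whale ", id, " has fewer than 2 observations; excluded")
      next
    }
    tt <- obs$time[rows]
    t0 <- min(tt)
    if (anchor == "utc") {
      dt_s <- dt_hours * 3600
      t0 <- as.POSIXct(floor(as.numeric(t0) / dt_s) * dt_s,
                       origin = "1970-01-01", tz = "UTC")
    }
    span_h <- as.numeric(difftime(max(tt), t0, units = "hours"))
    n <- ceiling(span_h / dt_hours) + 1
    times <- t0 + (seq_len(n) - 1) * dt_hours * 3600
    pos <- as.numeric(difftime(tt, t0, units = "hours")) / dt_hours
    k <- pmin(floor(pos) + 1, n - 1)
    f <- pos - (k - 1)
    whales[[id]] <- list(times = times, k = as.integer(k), f = f,
                         obs_rows = rows)
  }
  if (length(whales) == 0) stop("no whale with >= 2 observations")
  structure(list(dt_hours = dt_hours, whales = whales), class = "state_grid")
}
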