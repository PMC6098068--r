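#' Fit the hierarchical two-state switching state-space model
#'
#' Jointly estimates true 12-h locations and discrete behavioural states
#' (1 = transit, 2 = search) for all whales of one deployment campaign. The
#' process model is a switching first-difference correlated random walk: the
#' displacement at each step is the previous displacement rotated by the
#' state's mean turn angle `theta` and damped by the state's persistence
#' `gamma`, plus per-whale isotropic Gaussian process noise (each whale has
#' its own diffusivity). Behaviour evolves as a first-order Markov chain. The
#' observation model links each irregular Argos fix to the time interpolation
#' of its bracketing states, with independent Student-t errors in the east and
#' north components scaled by the fix's location class.
#'
#' Inference is by a blocked Gibbs sampler written for this model: the full
#' behavioural sequence of each whale is drawn exactly by forward filtering /
#' backward sampling; latent locations are drawn in conjugate Gaussian blocks
#' (a three-colour schedule over the second-order Markov neighbourhood; the
#' Student-t errors are represented as scale mixtures of normals so location
#' updates stay conjugate); `gamma` is drawn from its truncated-normal
#' conditional under the ordering constraint `gamma[1] > gamma[2]` (which
#' fixes state labels), and `theta`, per-whale process scales use slice
#' sampling. Priors: `gamma[1] ~ U(0,1)`, `gamma[2] ~ U(0, gamma[1])`,
#' `theta[1] ~ N(0, 1)` on (-pi, pi], `theta[2] ~ N(pi, 1)` on (0, 2*pi),
#' stay probabilities `~ Beta(1,1)`, process scales half-normal.
#'
#' Convergence is assessed by split-chain potential scale reduction on
#' `gamma` and `theta`; values above 1.1 leave the returned posterior flagged
#' `converged = FALSE` with a prominent warning (never silently).
#'
#' @param obs an `argos_obs` data frame for a single campaign
#' @param grid optional [build_state_grid()] result (built if `NULL`)
#' @param config an [mcmc_config()]
#' @param error_model an [argos_error_model()] giving the per-class
#'   observation error scales and degrees of freedom
#' @param priors list with `theta_sd` (prior SD of the turn angles, radians)
#'   and `sigma_scale` (half-normal scale of the process SD, km)
#' @param verbose print progress per chain
#' @return an `ssm_posterior` object; see [classify_behaviour()] and
#'   [draw_realisations()]
#' @export
fit_hssm <- function(obs, grid = NULL, config = mcmc_config(),
                     error_model = argos_error_model(),
                     priors = list(theta_sd = 1, sigma_scale = 25),
                     verbose = FALSE) {
  stopifnot(inherits(config, "mcmc_config"))
  campaign <- if ("campaign" %in% names(obs)) unique(obs$campaign) else "unknown"
  if (length(campaign) > 1)
    stop("fit_hssm fits one campaign at a time; split the observations first (",
         paste(campaign, collapse = ", "), ")")
  obs <- obs[obs$loc_class != "Z", ]
  if (is.null(grid)) grid <- build_state_grid(obs)
  ids <- names(grid$whales)
  short <- vapply(grid$whales, function(w) length(w$times) < 8, logical(1))
  if (any(short)) {
    warning("whale(s) with < 8 state times excluded: ",
            paste(ids[short], collapse = ", "))
    grid$whales <- grid$whales[!short]
    ids <- names(grid$whales)
  }
  if (length(ids) == 0) stop("no whale with >= 8 state times in this campaign")

  nw <- length(ids)
  Tn <- vapply(grid$whales, function(w) length(w$times), integer(1))
  Tmax <- max(Tn)
  origin <- t(vapply(ids, function(id) {
    r <- grid$whales[[id]]$obs_rows[1]
    c(lon = obs$lon[r], lat = obs$lat[r])
  }, numeric(2)))

  ## observation vectors (km in each whale's tangent plane)
  ow <- integer(0); ok_ <- integer(0); of <- numeric(0)
  oy1 <- numeric(0); oy2 <- numeric(0); osc <- numeric(0); odf <- numeric(0)
  for (i in seq_len(nw)) {
    w <- grid$whales[[ids[i]]]
    km <- lonlat_to_km(obs$lon[w$obs_rows], obs$lat[w$obs_rows],
                       origin[i, "lon"], origin[i, "lat"])
    cls <- obs$loc_class[w$obs_rows]
    ow <- c(ow, rep(i, length(w$k))); ok_ <- c(ok_, w$k); of <- c(of, w$f)
    oy1 <- c(oy1, km[, "x"]); oy2 <- c(oy2, km[, "y"])
    osc <- c(osc, unname(error_model$scale_km[cls]))
    odf <- c(odf, unname(error_model$df[cls]))
  }
  no <- length(ow)

  ## static site accumulator: obs j touches sites (ow, ok) with weight 1-f and
  ## (ow, ok+1) with weight f; site id = (i-1)*Tmax + t
  sid1 <- (ow - 1L) * Tmax + ok_
  sid2 <- (ow - 1L) * Tmax + ok_ + 1L
  mk_acc <- function(ids_) {
    o <- order(ids_)
    sorted <- ids_[o]
    ends <- cumsum(rle(sorted)$lengths)
    starts <- c(1L, head(ends, -1) + 1L)
    targets <- sorted[starts]
    function(vals, n) {
      cs <- cumsum(vals[o])
      sums <- cs[ends] - c(0, cs[head(ends, -1)])
      out <- numeric(n)
      out[targets] <- sums
      out
    }
  }
  acc1 <- mk_acc(sid1); acc2 <- mk_acc(sid2)

  mask <- outer(seq_len(nw), seq_len(Tmax), function(i, t) t <= Tn[i])
  tmat <- outer(rep(1, nw), seq_len(Tmax))

  ## initial locations: time interpolation of the observations
  xinit <- array(0, c(nw, Tmax, 2))
  binit <- matrix(1L, nw, Tmax)
  for (i in seq_len(nw)) {
    j <- ow == i
    pos <- ok_[j] + of[j]
    xinit[i, 1:Tn[i], 1] <- approx(pos, oy1[j], xout = seq_len(Tn[i]), rule = 2,
                                   ties = mean)$y
    xinit[i, 1:Tn[i], 2] <- approx(pos, oy2[j], xout = seq_len(Tn[i]), rule = 2,
                                   ties = mean)$y
    step <- sqrt(diff(xinit[i, 1:Tn[i], 1])^2 + diff(xinit[i, 1:Tn[i], 2])^2)
    binit[i, 2:Tn[i]] <- ifelse(step < median(step), 2L, 1L)
  }

  chain_seeds <- substream_seeds(config$seed, config$n_chains)
  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    if (verbose) message("chain ", ch, "/", config$n_chains)
    chains[[ch]] <- run_dcrws_chain(
      seed = chain_seeds[ch], n_iter = config$n_iter, burn_in = config$burn_in,
      thin = config$thin, nw = nw, Tn = Tn, Tmax = Tmax, mask = mask,
      tmat = tmat, xinit = xinit, binit = binit,
      ow = ow, ok_ = ok_, of = of, oy1 = oy1, oy2 = oy2, osc = osc, odf = odf,
      acc1 = acc1, acc2 = acc2, priors = priors, jitter = (ch - 1))
  }

  ## split-chain convergence diagnostics on the movement parameters
  par_draws <- function(nm, col) sapply(chains, function(c_) c_[[nm]][, col])
  rhat <- c(gamma1 = split_rhat(par_draws("gamma", 1)),
            gamma2 = split_rhat(par_draws("gamma", 2)),
            theta1 = split_rhat(par_draws("theta", 1)),
            theta2 = split_rhat(par_draws("theta", 2)))
  converged <- all(is.na(rhat) | rhat < 1.1)
  if (!converged)
    warning("MCMC convergence diagnostic above 1.1 for: ",
            paste(names(rhat)[!is.na(rhat) & rhat >= 1.1], collapse = ", "),
            " -- interpret this posterior with caution", call. = FALSE)

  structure(list(whale_ids = ids, Tn = Tn, Tmax = Tmax,
                 times = lapply(grid$whales, `[[`, "times"), origin = origin,
                 chains = chains, config = config, error_model = error_model,
                 campaign = campaign, rhat = rhat, converged = converged),
            class = "ssm_posterior")
}

#' @export
print.ssm_posterior <- function(x, ...) {
  cat("Hierarchical switching state-space model posterior\n")
  cat("  campaign:", x$campaign, " whales:", length(x$whale_ids),
      " state times:", sum(x$Tn), "\n")
  cat("  chains:", length(x$chains), " retained per chain:",
      nrow(x$chains[[1]]$gamma), "\n")
  gm <- colMeans(do.call(rbind, lapply(x$chains, `[[`, "gamma")))
  th <- colMeans(do.call(rbind, lapply(x$chains, `[[`, "theta")))
  cat(sprintf("  gamma: %.3f / %.3f   theta: %.3f / %.3f rad\n",
              gm[1], gm[2], th[1], th[2]))
  cat("  split-Rhat:", paste(sprintf("%s=%.3f", names(x$rhat), x$rhat),
                             collapse = " "),
      if (x$converged) "(converged)" else "(NOT CONVERGED)", "\n")
  invisible(x)
}

## one MCMC chain of the blocked Gibbs sampler; internal
run_dcrws_chain <- function(seed, n_iter, burn_in, thin, nw, Tn, Tmax, mask,
                            tmat, xinit, binit, ow, ok_, of, oy1, oy2, osc,
                            odf, acc1, acc2, priors, jitter) {
  set.seed(seed)
  no <- length(ow)
  ns <- nw * Tmax
  w1 <- 1 - of; w2 <- of

  X1 <- xinit[, , 1] + matrix(rnorm(ns, 0, 0.1 * jitter), nw, Tmax)
  X2 <- xinit[, , 2] + matrix(rnorm(ns, 0, 0.1 * jitter), nw, Tmax)
  X1[!mask] <- 0; X2[!mask] <- 0
  B <- binit
  gamma <- pmin(pmax(c(0.6, 0.2) + jitter * c(0.1, -0.05), 0.01), 0.95)
  theta <- c(0, pi) + jitter * c(0.05, -0.05)
  alpha <- c(0.8, 0.8)
  sigma <- rep(5, nw)
  lam1 <- rep(1, no); lam2 <- rep(1, no)

  n_kept <- (n_iter - burn_in) %/% thin
  keep_gamma <- matrix(NA_real_, n_kept, 2)
  keep_theta <- matrix(NA_real_, n_kept, 2)
  keep_alpha <- matrix(NA_real_, n_kept, 2)
  keep_sigma <- matrix(NA_real_, n_kept, nw)
  keep_b <- array(NA_integer_, c(n_kept, nw, Tmax))
  keep_x <- array(NA_real_, c(n_kept, nw, Tmax, 2))

  sig_mat <- function() matrix(sigma[row(tmat)], nw, Tmax)
  proc_mask <- mask & tmat >= 3   # steps with a process density

  kept <- 0L
  for (it in seq_len(n_iter)) {
    a_st <- gamma * cos(theta)   # per state
    s_st <- gamma * sin(theta)

    ## --- latent-scale (t as normal scale mixture) update ------------------
    p1 <- (1 - of) * X1[cbind(ow, ok_)] + of * X1[cbind(ow, ok_ + 1L)]
    p2 <- (1 - of) * X2[cbind(ow, ok_)] + of * X2[cbind(ow, ok_ + 1L)]
    r1o <- oy1 - p1; r2o <- oy2 - p2
    lam1 <- rgamma(no, (odf + 1) / 2, rate = (odf + (r1o / osc)^2) / 2)
    lam2 <- rgamma(no, (odf + 1) / 2, rate = (odf + (r2o / osc)^2) / 2)

    ## --- location update, three-colour conjugate blocks ------------------
    sg2 <- sig_mat()^2
    for (g in 0:2) {
      A1 <- matrix(a_st[B], nw, Tmax); S1 <- matrix(s_st[B], nw, Tmax)
      D1 <- cbind(matrix(0, nw, 1), X1[, -1, drop = FALSE] - X1[, -Tmax, drop = FALSE])
      D2 <- cbind(matrix(0, nw, 1), X2[, -1, drop = FALSE] - X2[, -Tmax, drop = FALSE])
      Dp1 <- cbind(matrix(0, nw, 2), D1[, 2:(Tmax - 1), drop = FALSE])
      Dp2 <- cbind(matrix(0, nw, 2), D2[, 2:(Tmax - 1), drop = FALSE])
      R1 <- D1 - (A1 * Dp1 - S1 * Dp2); R1[!proc_mask] <- 0
      R2 <- D2 - (S1 * Dp1 + A1 * Dp2); R2[!proc_mask] <- 0

      prec1 <- matrix(0, nw, Tmax); num1 <- matrix(0, nw, Tmax)
      prec2 <- matrix(0, nw, Tmax); num2 <- matrix(0, nw, Tmax)

      ## step into t (K = +1 on own coordinate)
      pa <- proc_mask / sg2
      prec1 <- prec1 + pa; num1 <- num1 - R1 * pa
      prec2 <- prec2 + pa; num2 <- num2 - R2 * pa

      ## step into t+1
      shift_l <- function(m) cbind(m[, -1, drop = FALSE], matrix(0, nw, 1))
      vB <- shift_l(proc_mask) / sg2
      A1n <- shift_l(A1); S1n <- shift_l(S1)
      R1n <- shift_l(R1); R2n <- shift_l(R2)
      prec1 <- prec1 + ((1 + A1n)^2 + S1n^2) * vB
      prec2 <- prec2 + ((1 + A1n)^2 + S1n^2) * vB
      num1 <- num1 + ((1 + A1n) * R1n + S1n * R2n) * vB
      num2 <- num2 + (-S1n * R1n + (1 + A1n) * R2n) * vB

      ## step into t+2
      shift_l2 <- function(m) cbind(m[, -(1:2), drop = FALSE], matrix(0, nw, 2))
      vC <- shift_l2(proc_mask) / sg2
      A1nn <- shift_l2(A1); S1nn <- shift_l2(S1)
      R1nn <- shift_l2(R1); R2nn <- shift_l2(R2)
      prec1 <- prec1 + (A1nn^2 + S1nn^2) * vC
      prec2 <- prec2 + (A1nn^2 + S1nn^2) * vC
      num1 <- num1 - (A1nn * R1nn + S1nn * R2nn) * vC
      num2 <- num2 - (-S1nn * R1nn + A1nn * R2nn) * vC

      ## observations
      p1 <- (1 - of) * X1[cbind(ow, ok_)] + of * X1[cbind(ow, ok_ + 1L)]
      p2 <- (1 - of) * X2[cbind(ow, ok_)] + of * X2[cbind(ow, ok_ + 1L)]
      r1o <- oy1 - p1; r2o <- oy2 - p2
      t1 <- lam1 / osc^2; t2 <- lam2 / osc^2
      obs_prec1 <- acc1(w1^2 * t1, ns) + acc2(w2^2 * t1, ns)
      obs_prec2 <- acc1(w1^2 * t2, ns) + acc2(w2^2 * t2, ns)
      obs_num1 <- acc1(w1 * r1o * t1, ns) + acc2(w2 * r1o * t1, ns)
      obs_num2 <- acc1(w1 * r2o * t2, ns) + acc2(w2 * r2o * t2, ns)
      ## site id (i-1)*Tmax + t maps to matrix [i, t] stored row-major in the
      ## accumulator; our matrices are column-major [i, t] so reindex
      idx <- matrix(seq_len(ns), nw, Tmax, byrow = TRUE)
      prec1 <- prec1 + matrix(obs_prec1[idx], nw, Tmax)
      prec2 <- prec2 + matrix(obs_prec2[idx], nw, Tmax)
      num1 <- num1 + matrix(obs_num1[idx], nw, Tmax)
      num2 <- num2 + matrix(obs_num2[idx], nw, Tmax)

      sel <- mask & (tmat %% 3L == g) & prec1 > 1e-12
      nsel <- sum(sel)
      if (nsel > 0) {
        X1[sel] <- X1[sel] + num1[sel] / prec1[sel] +
          rnorm(nsel) / sqrt(prec1[sel])
        X2[sel] <- X2[sel] + num2[sel] / prec2[sel] +
          rnorm(nsel) / sqrt(prec2[sel])
      }
    }

    ## --- behavioural states: forward filtering, backward sampling --------
    D1 <- cbind(matrix(0, nw, 1), X1[, -1, drop = FALSE] - X1[, -Tmax, drop = FALSE])
    D2 <- cbind(matrix(0, nw, 1), X2[, -1, drop = FALSE] - X2[, -Tmax, drop = FALSE])
    ll <- array(0, c(nw, Tmax, 2))   # log emission per state
    for (k in 1:2) {
      e1 <- D1 - (a_st[k] * cbind(matrix(0, nw, 1), D1[, -Tmax, drop = FALSE]) -
                    s_st[k] * cbind(matrix(0, nw, 1), D2[, -Tmax, drop = FALSE]))
      e2 <- D2 - (s_st[k] * cbind(matrix(0, nw, 1), D1[, -Tmax, drop = FALSE]) +
                    a_st[k] * cbind(matrix(0, nw, 1), D2[, -Tmax, drop = FALSE]))
      lk <- -(e1^2 + e2^2) / (2 * sig_mat()^2)
      lk[!proc_mask] <- 0
      ll[, , k] <- lk
    }
    P <- matrix(c(alpha[1], 1 - alpha[2], 1 - alpha[1], alpha[2]), 2, 2)
    Fprob <- array(0, c(nw, Tmax, 2))
    f_cur <- matrix(0.5, nw, 2)
    f_cur <- f_cur * exp(ll[, 1, ] - apply(ll[, 1, ], 1, max))
    f_cur <- f_cur / rowSums(f_cur)
    Fprob[, 1, ] <- f_cur
    for (t in 2:Tmax) {
      pred <- f_cur %*% P
      e <- exp(ll[, t, ] - apply(ll[, t, ], 1, max))
      f_cur2 <- pred * e
      f_cur2 <- f_cur2 / rowSums(f_cur2)
      upd <- t <= Tn
      f_cur[upd, ] <- f_cur2[upd, ]
      Fprob[, t, ] <- f_cur
    }
    u <- matrix(runif(nw * Tmax), nw, Tmax)
    for (i in seq_len(nw)) B[i, Tn[i]] <- if (u[i, Tn[i]] < Fprob[i, Tn[i], 2]) 2L else 1L
    for (t in (Tmax - 1):1) {
      act <- which(t < Tn)
      if (length(act) == 0) next
      bn <- B[cbind(act, pmin(t + 1L, Tn[act]))]
      p2s <- Fprob[act, t, 2] * P[2, bn]
      p1s <- Fprob[act, t, 1] * P[1, bn]
      B[cbind(act, rep(t, length(act)))] <- ifelse(
        u[cbind(act, rep(t, length(act)))] < p2s / (p1s + p2s), 2L, 1L)
    }

    ## --- Markov stay probabilities (conjugate Beta) -----------------------
    n11 <- n12 <- n21 <- n22 <- 0L
    prev <- B[, -Tmax, drop = FALSE]; nxt <- B[, -1, drop = FALSE]
    pm <- mask[, -1, drop = FALSE]
    n11 <- sum(prev == 1 & nxt == 1 & pm); n12 <- sum(prev == 1 & nxt == 2 & pm)
    n22 <- sum(prev == 2 & nxt == 2 & pm); n21 <- sum(prev == 2 & nxt == 1 & pm)
    alpha[1] <- rbeta(1, 1 + n11, 1 + n12)
    alpha[2] <- rbeta(1, 1 + n22, 1 + n21)

    ## --- movement parameters ---------------------------------------------
    D1p <- cbind(matrix(0, nw, 1), D1[, -Tmax, drop = FALSE])
    D2p <- cbind(matrix(0, nw, 1), D2[, -Tmax, drop = FALSE])
    wgt <- proc_mask / sig_mat()^2
    for (k in 1:2) {
      sk <- (B == k) & proc_mask
      wk <- wgt * sk
      A <- sum((D1p^2 + D2p^2) * wk)
      B1 <- sum((D1 * D1p + D2 * D2p) * wk)
      B2 <- sum((-D1 * D2p + D2 * D1p) * wk)
      mu_th <- if (k == 1) 0 else pi
      lo_th <- if (k == 1) -pi else 0
      hi_th <- if (k == 1) pi else 2 * pi
      logf_th <- function(th)
        gamma[k] * (B1 * cos(th) + B2 * sin(th)) -
          (th - mu_th)^2 / (2 * priors$theta_sd^2)
      theta[k] <- slice_sample1(logf_th, theta[k], w = 0.5, lower = lo_th,
                                upper = hi_th)
      proj <- B1 * cos(theta[k]) + B2 * sin(theta[k])
      lo_g <- if (k == 1) gamma[2] else 0
      hi_g <- if (k == 1) 1 else gamma[1]
      gamma[k] <- if (A > 0) rtruncnorm1(proj / A, 1 / sqrt(A), lo_g, hi_g)
        else runif(1, lo_g, hi_g)
    }

    ## --- per-whale process scales (slice) ---------------------------------
    a_cur <- gamma * cos(theta); s_cur <- gamma * sin(theta)
    A1 <- matrix(a_cur[B], nw, Tmax); S1 <- matrix(s_cur[B], nw, Tmax)
    E1 <- D1 - (A1 * D1p - S1 * D2p)
    E2 <- D2 - (S1 * D1p + A1 * D2p)
    SSm <- (E1^2 + E2^2) * proc_mask
    for (i in seq_len(nw)) {
      ss <- sum(SSm[i, ]); m <- 2 * (Tn[i] - 2)
      logf_s <- function(sg)
        -m * log(sg) - ss / (2 * sg^2) - sg^2 / (2 * priors$sigma_scale^2)
      sigma[i] <- slice_sample1(logf_s, sigma[i], w = 1, lower = 1e-3,
                                upper = 1e4)
    }

    ## --- retention --------------------------------------------------------
    if (it > burn_in && (it - burn_in) %% thin == 0) {
      kept <- kept + 1L
      keep_gamma[kept, ] <- gamma
      keep_theta[kept, ] <- theta
      keep_alpha[kept, ] <- alpha
      keep_sigma[kept, ] <- sigma
      keep_b[kept, , ] <- B
      keep_x[kept, , , 1] <- X1
      keep_x[kept, , , 2] <- X2
    }
  }
  list(gamma = keep_gamma, theta = keep_theta, alpha = keep_alpha,
       sigma = keep_sigma, b = keep_b, x_km = keep_x)
}

## univariate slice sampler (stepping out + shrinkage); internal
slice_sample1 <- function(logf, x0, w = 1, lower = -Inf, upper = Inf,
                          max_steps = 50) {
  f0 <- logf(x0)
  if (!is.finite(f0)) return(x0)
  z <- f0 + log(runif(1))
  u <- runif(1)
  L <- max(x0 - w * u, lower)
  R <- min(L + w, upper)
  steps <- 0
  while (L > lower && logf(L) > z && steps < max_steps) {
    L <- max(L - w, lower); steps <- steps + 1
  }
  steps <- 0
  while (R < upper && logf(R) > z && steps < max_steps) {
    R <- min(R + w, upper); steps <- steps + 1
  }
  for (rep in 1:100) {
    x1 <- runif(1, L, R)
    if (logf(x1) >= z) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
  x0
}

## truncated normal draw via inverse CDF with tail guard; internal
rtruncnorm1 <- function(m, s, lo, hi) {
  plo <- pnorm(lo, m, s); phi <- pnorm(hi, m, s)
  if (phi - plo < 1e-12) {
    ## numerically degenerate: fall back to the nearest bound region
    return(if (m < lo) lo + 1e-8 * (hi - lo) else hi - 1e-8 * (hi - lo))
  }
  qnorm(runif(1, plo, phi), m, s)
}
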