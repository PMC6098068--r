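#' Classify behaviour from the posterior
#'
#' For every whale and 12-h state time, pools the retained samples across
#' chains and computes the posterior mean behavioural state (continuous
#' between 1 and 2), the modal discrete state (majority vote over samples;
#' an exact tie breaks conservatively to state 1, transit), posterior mean
#' location, and a display label from the posterior-mean thresholds:
#' `transit` below 1.25, `search` above 1.75, `uncertain` in between
#' (both inequalities strict, so a mean of exactly 1.25 or 1.75 is
#' `uncertain`).
#'
#' @param posterior an `ssm_posterior` from [fit_hssm()]
#' @param transit_threshold,search_threshold posterior-mean thresholds
#' @return a `classified_tracks` data frame with columns `whale_id`, `time`,
#'   `lon`, `lat`, `b_mean`, `b_mode`, `label`
#' @export
classify_behaviour <- function(posterior, transit_threshold = 1.25,
                               search_threshold = 1.75) {
  stopifnot(inherits(posterior, "ssm_posterior"))
  b_all <- do.call(abind1, lapply(posterior$chains, `[[`, "b"))
  x_all <- do.call(abind1, lapply(posterior$chains, `[[`, "x_km"))
  if (dim(b_all)[1] < 1) stop("posterior has no retained samples")
  out <- lapply(seq_along(posterior$whale_ids), function(i) {
    Ti <- posterior$Tn[i]
    bmat <- b_all[, i, seq_len(Ti), drop = FALSE]
    dim(bmat) <- c(dim(b_all)[1], Ti)
    b_mean <- colMeans(bmat)
    n2 <- colSums(bmat == 2L)
    b_mode <- ifelse(n2 > nrow(bmat) / 2, 2L, 1L)   # tie -> transit
    mx <- colMeans(matrix(x_all[, i, seq_len(Ti), 1], ncol = Ti))
    my <- colMeans(matrix(x_all[, i, seq_len(Ti), 2], ncol = Ti))
    ll <- km_to_lonlat(mx, my, posterior$origin[i, "lon"],
                       posterior$origin[i, "lat"])
    data.frame(whale_id = posterior$whale_ids[i],
               time = posterior$times[[i]],
               lon = ll[, "lon"], lat = ll[, "lat"],
               b_mean = b_mean, b_mode = b_mode,
               label = ifelse(b_mean < transit_threshold, "transit",
                              ifelse(b_mean > search_threshold, "search",
                                     "uncertain")))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("classified_tracks", "data.frame")
  out
}

## bind along the first (sample) dimension; internal
abind1 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  n <- sum(vapply(parts, function(p) dim(p)[1], integer(1)))
  out <- array(parts[[1]][1], c(n, d[-1]))
  at <- 0L
  for (p in parts) {
    np <- dim(p)[1]
    if (length(d) == 3) out[at + seq_len(np), , ] <- p
    else out[at + seq_len(np), , , ] <- p
    at <- at + np
  }
  out
}

#' Draw joint posterior realisations of locations and states
#'
#' Randomly samples retained MCMC iterations, balanced across chains (for two
#' chains, n/2 indices per chain, without replacement within a chain), and
#' returns each as a coherent joint track realisation: the locations and the
#' discrete behavioural states of one and the same MCMC sample. These
#' realisations drive the multiple-imputation refits of the habitat model.
#'
#' @param posterior an `ssm_posterior`
#' @param n number of realisations
#' @param seed integer seed
#' @return list of `n` data frames with columns `whale_id`, `time`, `lon`,
#'   `lat`, `b`
#' @export
draw_realisations <- function(posterior, n = 100, seed = 1) {
  stopifnot(inherits(posterior, "ssm_posterior"))
  nch <- length(posterior$chains)
  kept <- nrow(posterior$chains[[1]]$gamma)
  per <- rep(n %/% nch, nch)
  extra <- n - sum(per)
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  if (any(per > kept))
    stop("insufficient retained samples: need ", max(per),
         " per chain but only ", kept, " are retained")
  set.seed(substream_seeds(seed, 1))
  picks <- lapply(seq_len(nch), function(ch)
    sample.int(kept, per[ch], replace = FALSE))
  out <- list()
  for (ch in seq_len(nch)) {
    cobj <- posterior$chains[[ch]]
    for (s in picks[[ch]]) {
      df <- lapply(seq_along(posterior$whale_ids), function(i) {
        Ti <- posterior$Tn[i]
        ll <- km_to_lonlat(cobj$x_km[s, i, seq_len(Ti), 1],
                           cobj$x_km[s, i, seq_len(Ti), 2],
                           posterior$origin[i, "lon"],
                           posterior$origin[i, "lat"])
        data.frame(whale_id = posterior$whale_ids[i],
                   time = posterior$times[[i]],
                   lon = ll[, "lon"], lat = ll[, "lat"],
                   b = cobj$b[s, i, seq_len(Ti)])
      })
      out[[length(out) + 1L]] <- do.call(rbind, df)
    }
  }
  out
}
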