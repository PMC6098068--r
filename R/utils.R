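#' Derive independent substream seeds from a single master seed
#'
#' Every stochastic operation in the package takes one integer seed and, where
#' it needs several independent random streams (one per whale, one per
#' realisation), expands it into substream seeds with this helper so that
#' results are reproducible and substreams do not collide.
#'
#' @param seed master integer seed
#' @param n number of substreams
#' @return integer vector of length `n`
#' @export
substream_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed), n >= 1)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

## wrap an angle to (-pi, pi]
wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

## wrap longitudes to [-180, 180)
wrap_lon <- function(lon) ((lon + 180) %% 360) - 180

## "YYYY-MM" arithmetic
month_shift <- function(ym, k) {
  y <- as.integer(substr(ym, 1, 4))
  m <- as.integer(substr(ym, 6, 7))
  idx <- y * 12L + (m - 1L) + as.integer(k)
  sprintf("%04d-%02d", idx %/% 12L, idx %% 12L + 1L)
}

month_of <- function(time) format(time, "%Y-%m", tz = "UTC")

days_in_month <- function(ym) {
  first <- as.Date(paste0(ym, "-01"))
  as.integer(as.Date(paste0(month_shift(ym, 1), "-01")) - first)
}

## mid-point (in days since epoch) of a calendar month, for melt-rate spacing
month_midpoint <- function(ym) {
  as.numeric(as.Date(paste0(ym, "-01"))) + days_in_month(ym) / 2
}

## split-chain potential scale reduction factor (rank-plain version) on a
## matrix with one column per chain
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  sub <- cbind(draws[seq_len(half), , drop = FALSE],
               draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, stats::var)
  B <- half * stats::var(means)
  W <- mean(vars)
  if (W <= 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}
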