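#' Fit the binomial GAMM for search behaviour
#'
#' Penalized-regression-spline additive model on the logit scale for the
#' probability of search behaviour, with one smooth of moderate rank
#' (default basis dimension k = 10) per environmental covariate, a whale
#' random intercept (random-effect smooth), and deployment campaign as a
#' categorical fixed effect when more than one campaign is present.
#' Smoothing parameters are selected by the (restricted) marginal-likelihood
#' criterion. Approximate per-smooth p-values are based on Chi-square
#' statistics.
#'
#' @param rows a `covariate_rows` data frame
#' @param covariates covariate columns to smooth (defaults to the six
#'   standard covariates present in `rows`)
#' @param k smooth basis dimension per covariate
#' @param min_rows minimum number of rows required
#' @return a `whale_gamm` object wrapping the `mgcv::gam` fit
#' @export
fit_gamm <- function(rows, covariates = NULL, k = 10, min_rows = 100) {
  if (is.null(covariates))
    covariates <- intersect(c("log_bathyg", "log_chla", "sqrt_dist_ice",
                              "melt_rate", "ice_cv_lag2", "ice_mn_lag1"),
                            names(rows))
  if (nrow(rows) < min_rows)
    stop("need at least ", min_rows, " rows; got ", nrow(rows))
  if (length(unique(rows$whale_id)) < 2)
    stop("need at least 2 whales for the random effect")
  if (length(unique(rows$y)) < 2)
    stop("response is all one class; the model is not estimable")
  dat <- as.data.frame(rows)
  dat$whale_id <- factor(dat$whale_id)
  dat$campaign <- if ("campaign" %in% names(dat)) factor(dat$campaign)
    else factor("all")
  ## cap basis size at what the data can support
  kk <- vapply(covariates, function(v)
    max(3, min(k, length(unique(dat[[v]])) - 1)), numeric(1))
  terms <- paste(sprintf("s(%s, k = %d)", covariates, kk), collapse = " + ")
  fml <- paste("y ~", terms, "+ s(whale_id, bs = \"re\")")
  if (nlevels(dat$campaign) > 1) fml <- paste(fml, "+ campaign")
  fit <- mgcv::gam(as.formula(fml), family = binomial(link = "logit"),
                   data = dat, method = "REML")
  p <- fitted(fit)
  if (all(p < 1e-8 | p > 1 - 1e-8))
    warning("fitted probabilities are all degenerate; possible separation")
  structure(list(fit = fit, covariates = covariates,
                 s_table = summary(fit)$s.table,
                 p_table = summary(fit)$pTerms.table,
                 n = nrow(dat)),
            class = "whale_gamm")
}

#' @export
print.whale_gamm <- function(x, ...) {
  cat("Binomial GAMM for search behaviour (", x$n, " locations)\n", sep = "")
  print(round(x$s_table, 4))
  invisible(x)
}

#' Per-covariate significance table
#'
#' @param fit a `whale_gamm`
#' @param alpha significance level; a covariate is flagged when its
#'   approximate p-value is strictly below `alpha`
#' @return data frame with `covariate`, `chi_sq`, `edf`, `p_value`,
#'   `significant`, ordered as the model formula (campaign, when present,
#'   is reported last as a parametric term)
#' @export
significance_table <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "whale_gamm"))
  st <- fit$s_table
  smooth_rows <- paste0("s(", fit$covariates, ")")
  out <- data.frame(covariate = fit$covariates,
                    chi_sq = st[smooth_rows, "Chi.sq"],
                    edf = st[smooth_rows, "edf"],
                    p_value = st[smooth_rows, "p-value"])
  if (!is.null(fit$p_table) && "campaign" %in% rownames(fit$p_table))
    out <- rbind(out, data.frame(covariate = "campaign",
                                 chi_sq = fit$p_table["campaign", "Chi.sq"],
                                 edf = fit$p_table["campaign", "df"],
                                 p_value = fit$p_table["campaign", "p-value"]))
  out$significant <- out$p_value < alpha
  rownames(out) <- NULL
  out
}

#' Multiple-imputation significance retention across posterior realisations
#'
#' Propagates state-space-model uncertainty into the habitat model: draws `n`
#' joint posterior realisations of locations and discrete states
#' ([draw_realisations()]), re-extracts the environmental covariates at each
#' realisation's locations, sets the response from its discrete states,
#' refits the GAMM, and counts how often each covariate is significant at
#' `alpha`. Individual refit failures are logged and counted as
#' not-significant so the denominator stays at `n`; more than 20% failures
#' aborts with a diagnostic.
#'
#' @param posterior an `ssm_posterior`
#' @param stack an `env_stack`
#' @param n number of realisations / refits
#' @param alpha significance level
#' @param seed integer seed
#' @param lat_cutoff latitude cut-off passed to [extract_covariates()]
#' @param k smooth basis dimension
#' @param covariates covariate subset (defaults as in [fit_gamm()])
#' @param min_rows minimum rows per refit
#' @return a `retention_summary` data frame: `covariate`, `n_significant`,
#'   `n_fits`, with attributes `n_failures` and `alpha`
#' @export
mi_retention <- function(posterior, stack, n = 100, alpha = 0.05, seed = 1,
                         lat_cutoff = -60, k = 10, covariates = NULL,
                         min_rows = 100) {
  draws <- draw_realisations(posterior, n = n, seed = seed)
  counts <- NULL
  n_fail <- 0L
  for (d in draws) {
    res <- tryCatch({
      rows <- extract_covariates(d, stack, lat_cutoff = lat_cutoff,
                                 quiet = TRUE)
      f <- fit_gamm(rows, covariates = covariates, k = k,
                    min_rows = min_rows)
      sig <- significance_table(f, alpha = alpha)
      sig <- sig[sig$covariate != "campaign", ]
      setNames(as.integer(sig$significant), sig$covariate)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      n_fail <- n_fail + 1L
      message("refit failed (counted not significant): ",
              conditionMessage(res))
      next
    }
    counts <- if (is.null(counts)) res else counts + res[names(counts)]
  }
  if (n_fail > 0.2 * n)
    stop("more than 20% of the multiple-imputation refits failed (",
         n_fail, "/", n, ")")
  out <- data.frame(covariate = names(counts),
                    n_significant = as.integer(counts), n_fits = n)
  attr(out, "n_failures") <- n_fail
  attr(out, "alpha") <- alpha
  rownames(out) <- NULL
  class(out) <- c("retention_summary", "data.frame")
  out
}

#' Predicted probability-of-search map
#'
#' Evaluates a fitted GAMM (or the pointwise mean over a list of fits) on the
#' raster grid for one month, at the population level (whale random effect
#' excluded, i.e. set to its zero mean; campaign at its reference level).
#' Cells where a covariate is missing are `NA`.
#'
#' @param fit a `whale_gamm` or list of them
#' @param stack an `env_stack`
#' @param month `"YYYY-MM"` month for the ice covariates
#' @param lat_cutoff latitude cut-off defining the prediction domain
#' @param edge_threshold ice-edge threshold (%)
#' @return list with `lon`, `lat`, `p` (probability matrix `[n_lon, n_lat]`)
#' @export
predict_map <- function(fit, stack, month, lat_cutoff = -60,
                        edge_threshold = 15) {
  fits <- if (inherits(fit, "whale_gamm")) list(fit) else fit
  stopifnot(all(vapply(fits, inherits, logical(1), "whale_gamm")))
  cells <- expand.grid(lon = stack$lon, lat = stack$lat)
  cells$whale_id <- "population"
  cells$time <- as.POSIXct(paste0(month, "-15 00:00:00"), tz = "UTC")
  cells$state <- 1L
  rows <- extract_covariates(cells, stack, lat_cutoff = lat_cutoff,
                             edge_threshold = edge_threshold, quiet = TRUE)
  p_cells <- rep(NA_real_, nrow(cells))
  if (nrow(rows) > 0) {
    m <- match(paste(rows$lon, rows$lat), paste(cells$lon, cells$lat))
    acc <- 0
    for (f in fits) {
      nd <- as.data.frame(rows)
      nd$whale_id <- factor(f$fit$model$whale_id[1],
                            levels = levels(f$fit$model$whale_id))
      if ("campaign" %in% names(f$fit$model))
        nd$campaign <- factor(levels(f$fit$model$campaign)[1],
                              levels = levels(f$fit$model$campaign))
      pr <- predict(f$fit, newdata = nd, type = "response",
                    exclude = "s(whale_id)", newdata.guaranteed = TRUE)
      acc <- acc + as.numeric(pr)
    }
    p_cells[m] <- acc / length(fits)
  }
  list(lon = stack$lon, lat = stack$lat,
       p = matrix(p_cells, length(stack$lon), length(stack$lat)))
}

#' Aggregate per-whale probabilities into coarse grid cells
#'
#' Two-stage (whale-first) averaging into 1 degree latitude by 2 degree
#' longitude cells (configurable): within each cell, first average each
#' whale's own values, then average across whales, so every whale present in
#' a cell carries equal weight. Empty cells are absent from the output.
#'
#' @param df data frame with `whale_id`, `lon`, `lat`, `p`
#' @param cell_deg named vector `c(lat = 1, lon = 2)` cell sizes in degrees
#' @param pooled if `TRUE`, average all values in a cell directly instead
#'   (every location equal weight)
#' @return data frame with cell-centre `cell_lon`, `cell_lat`, `p_mean`,
#'   `n_whales`
#' @export
aggregate_cells <- function(df, cell_deg = c(lat = 1, lon = 2),
                            pooled = FALSE) {
  ci <- floor(df$lon / cell_deg["lon"])
  cj <- floor(df$lat / cell_deg["lat"])
  key <- paste(ci, cj)
  out <- lapply(split(seq_len(nrow(df)), key), function(rows) {
    p <- if (pooled) mean(df$p[rows])
      else mean(tapply(df$p[rows], df$whale_id[rows], mean))
    data.frame(cell_lon = (ci[rows[1]] + 0.5) * cell_deg[["lon"]],
               cell_lat = (cj[rows[1]] + 0.5) * cell_deg[["lat"]],
               p_mean = p,
               n_whales = length(unique(df$whale_id[rows])))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
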