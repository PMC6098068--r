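#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end synthetic pipeline with the
#' analysis defaults: behavioural thresholds 1.25 / 1.75 on the posterior
#' mean state, the 60 deg S Antarctic parallel, the 15% ice-edge threshold,
#' significance level 0.05, and the Tasman boundary at 155 deg E. The
#' default scenario sizes (whales, steps, MCMC schedule, number of
#' multiple-imputation refits) are desk-scale so a full run completes in
#' minutes; campaign-scale analyses should raise them towards the
#' [mcmc_config()] defaults.
#'
#' @param n_whales,n_steps synthetic campaign size
#' @param step0_km initial displacement passed to [simulate_tracks()]
#' @param movement a [movement_params()]
#' @param error_model an [argos_error_model()]
#' @param obs_per_day Argos fixes per day
#' @param mcmc an [mcmc_config()]
#' @param mi_n number of multiple-imputation refits
#' @param alpha significance level
#' @param transit_threshold,search_threshold posterior-mean state thresholds
#' @param parallel Antarctic boundary latitude
#' @param ice_edge_threshold ice-edge concentration threshold (%)
#' @param ts_boundary Tasman Sea boundary meridian (deg E)
#' @param env_effect named log-odds coefficients coupling behaviour to the
#'   environment in the synthetic truth
#' @param start deployment origin (see [simulate_tracks()])
#' @param months environmental stack months
#' @param grid_spec environmental grid specification
#' @param seed master seed
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(n_whales = 6, n_steps = 120,
                            movement = movement_params(gamma = c(0.7, 0.11),
                                                       stay_prob = c(0.88, 0.88),
                                                       process_sd = 10),
                            error_model = argos_error_model(),
                            obs_per_day = 6, step0_km = 18,
                            mcmc = mcmc_config(n_chains = 2, n_iter = 3000,
                                               burn_in = 1500, thin = 15,
                                               seed = 1),
                            mi_n = 20, alpha = 0.05,
                            transit_threshold = 1.25, search_threshold = 1.75,
                            parallel = -60, ice_edge_threshold = 15,
                            ts_boundary = 155,
                            env_effect = c("(Intercept)" = 0, melt_rate = 1.5,
                                           ice_cv_lag2 = 1),
                            start = list(lon = 152, lat = -58,
                                         time = as.POSIXct("2008-11-05 00:00:00",
                                                           tz = "UTC")),
                            months = c("2008-09", "2008-10", "2008-11",
                                       "2008-12", "2009-01"),
                            grid_spec = list(lon = c(130, 175),
                                             lat = c(-75, -50), res = 0.5),
                            seed = 1) {
  cfg <- list(n_whales = n_whales, n_steps = n_steps, movement = movement,
              error_model = error_model, obs_per_day = obs_per_day,
              step0_km = step0_km, mcmc = mcmc, mi_n = mi_n, alpha = alpha,
              transit_threshold = transit_threshold,
              search_threshold = search_threshold, parallel = parallel,
              ice_edge_threshold = ice_edge_threshold,
              ts_boundary = ts_boundary, env_effect = env_effect,
              start = start, months = months, grid_spec = grid_spec,
              seed = seed)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full synthetic pipeline
#'
#' Executes every stage in order on a synthetic scenario with known ground
#' truth: simulate tracks, couple behaviour to the environment, corrupt to
#' Argos observations, fit the state-space model, classify behaviour,
#' segment patches and summarise movement, extract covariates, screen
#' collinearity, fit the GAMM, run the multiple-imputation retention, and
#' produce a prediction map. Every intermediate artifact is written as
#' delimited text (or a plain-text raster) under `out_dir`, together with a
#' JSON report carrying the seed and a hash of the configuration; runs with
#' identical configuration and seed produce identical tables.
#'
#' @param config a [pipeline_config()]
#' @param out_dir output directory
#' @param verbose print stage progress
#' @return the report, invisibly (a list)
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("whalessm-"),
                         verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[", format(Sys.time(), "%H:%M:%S"),
                                            "] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  seeds <- substream_seeds(config$seed, 6)

  say("simulate: tracks and environment")
  stack <- stage("simulate-env", simulate_env_stack(
    grid_spec = config$grid_spec, months = config$months, seed = seeds[1]))
  tracks <- stage("simulate-tracks", simulate_tracks(
    config$movement, config$n_whales, config$n_steps, start = config$start,
    seed = seeds[2], step0_km = config$step0_km))
  tracks <- stage("couple-env", couple_behaviour_to_env(
    tracks, stack, config$env_effect, seed = seeds[3]))
  obs <- stage("corrupt", corrupt_to_argos(
    tracks, config$error_model, obs_per_day = config$obs_per_day,
    seed = seeds[4]))
  write_argos_csv(obs, file.path(out_dir, "argos.csv"))
  write_env_stack(stack, file.path(out_dir, "env"))

  say("fit-ssm: ", config$mcmc$n_iter, " iterations x ",
      config$mcmc$n_chains, " chains")
  obs_f <- stage("prefilter", prefilter_observations(obs))
  post <- stage("fit-ssm", fit_hssm(obs_f, config = config$mcmc,
                                    error_model = config$error_model))

  say("classify and summarise")
  cls <- stage("classify", classify_behaviour(
    post, config$transit_threshold, config$search_threshold))
  write.csv(fmt_num(cls), file.path(out_dir, "classified.csv"),
            row.names = FALSE)
  patches <- stage("patches", segment_search_patches(
    cls, threshold = config$search_threshold))
  write.csv(fmt_num(patches), file.path(out_dir, "patches.csv"),
            row.names = FALSE)
  moves <- stage("summarize", summarize_movement(cls, parallel = config$parallel))
  write.csv(fmt_num(moves), file.path(out_dir, "movement_summary.csv"),
            row.names = FALSE)
  write.csv(fmt_num(cohort_table(load_table1_fixture())),
            file.path(out_dir, "cohort_table.csv"), row.names = FALSE)

  say("extract-env and fit-gamm")
  rows <- stage("extract-env", extract_covariates(
    cls, stack, lat_cutoff = config$parallel,
    edge_threshold = config$ice_edge_threshold, quiet = TRUE))
  write.csv(fmt_num(rows), file.path(out_dir, "covariates.csv"),
            row.names = FALSE)
  screen <- stage("collinearity", collinearity_screen(rows))
  gam_fit <- stage("fit-gamm", fit_gamm(rows, covariates = screen$retained,
                                        min_rows = 50))
  sig <- stage("significance", significance_table(gam_fit, alpha = config$alpha))
  write.csv(fmt_num(sig), file.path(out_dir, "significance.csv"),
            row.names = FALSE)

  say("mi-retention: ", config$mi_n, " refits")
  retention <- stage("mi-retention", suppressMessages(mi_retention(
    post, stack, n = config$mi_n, alpha = config$alpha, seed = seeds[5],
    lat_cutoff = config$parallel, covariates = screen$retained,
    min_rows = 50)))
  write.csv(fmt_num(retention), file.path(out_dir, "retention.csv"),
            row.names = FALSE)

  say("predict-map")
  map_month <- config$months[length(config$months)]
  pmap <- stage("predict-map", predict_map(
    gam_fit, stack, month = map_month, lat_cutoff = config$parallel,
    edge_threshold = config$ice_edge_threshold))
  write_raster(pmap$p, file.path(out_dir, "predicted_search.grid"),
               "p_search", "probability", pmap$lon, pmap$lat)

  report <- list(
    seed = config$seed,
    config_hash = config_hash(config),
    n_whales = config$n_whales,
    whales_fit = length(post$whale_ids),
    converged = post$converged,
    rhat = as.list(round(post$rhat, 4)),
    n_patches = nrow(patches),
    n_covariate_rows = nrow(rows),
    covariates_retained = screen$retained,
    retention = setNames(as.list(retention$n_significant),
                         retention$covariate),
    artifacts = list.files(out_dir, recursive = TRUE))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done: ", out_dir)
  invisible(report)
}

## fixed-format numeric columns so that repeated runs are byte-identical
fmt_num <- function(df) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]]) && !is.integer(df[[nm]]))
      df[[nm]] <- sprintf("%.10g", df[[nm]])
    if (inherits(df[[nm]], "POSIXct"))
      df[[nm]] <- format(df[[nm]], "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  }
  df
}

## stable hash of the configuration (md5 of its deparsed form)
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(config[order(names(unclass(config)))]), tf)
  unname(tools::md5sum(tf))
}
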