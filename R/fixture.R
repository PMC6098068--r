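#' Per-whale deployment summary fixture
#'
#' Returns the packaged summary table of 30 satellite-tag deployments on east
#' Australian humpback whales over the 2008/09, 2009/10 and 2010/11 austral
#' summers: tag identifier (ptt), gender, tagging location (AU-Eden, AU-SC,
#' ANT), deployment / first / last location dates (UTC), track duration and
#' transmitting days, track distance (km), number of search patches, total
#' search time and extreme patch durations (days), and per-region search-day
#' counts (AU-EC = east coast Australia, TS = Tasman Sea, ANT = Antarctica;
#' `NA` where the whale had no search patches). Region day counts sum to the
#' total search time in every row.
#'
#' @return a `deployment_summary` data frame with 30 rows
#' @examples
#' fx <- load_table1_fixture()
#' nrow(fx)                      # 30 whales
#' mean(fx$duration_days)        # ~50 days
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_deployments.tsv", package = "whalessm",
                      mustWork = TRUE)
  fx <- read.delim(path, colClasses = c(
    ptt = "character", gender = "character", gender_inferred = "logical",
    tagging_location = "character", deploy_date = "Date",
    first_loc_date = "Date", last_loc_date = "Date"))
  stopifnot(nrow(fx) == 30)
  ok <- is.na(fx$search_days_total) |
    fx$search_days_total == rowSums(fx[, c("search_days_au_ec", "search_days_ts",
                                           "search_days_ant")])
  stopifnot(all(ok))
  class(fx) <- c("deployment_summary", "data.frame")
  fx
}

#' Headline statistics of the deployment summary fixture
#'
#' Convenience summaries used by the cohort table and reporting: mean and
#' sample SD of track duration and distance, counts of whales with Antarctic
#' and temperate search regions, and the longest search patch attributable to
#' the Antarctic region (a whale's longest patch is Antarctic when its
#' Antarctic search-day count can contain it).
#'
#' @param fx a `deployment_summary` from [load_table1_fixture()]
#' @return named list of scalar statistics
#' @export
fixture_stats <- function(fx = load_table1_fixture()) {
  au <- fx$tagging_location %in% c("AU-Eden", "AU-SC")
  temperate <- !is.na(fx$search_days_total) &
    (fx$search_days_au_ec > 0 | fx$search_days_ts > 0)
  ant <- !is.na(fx$search_days_total) & fx$search_days_ant > 0
  ant_patch <- !is.na(fx$max_patch_days) & fx$search_days_ant > 0 &
    fx$max_patch_days <= fx$search_days_ant
  list(
    n = nrow(fx),
    duration_mean = mean(fx$duration_days),
    duration_sd = sd(fx$duration_days),
    distance_mean = mean(fx$distance_km),
    distance_sd = sd(fx$distance_km),
    n_antarctic_search = sum(ant),
    n_australian_tagged = sum(au),
    n_temperate_search_au = sum(temperate & au),
    pct_temperate_search_au = 100 * sum(temperate & au) / sum(au),
    max_antarctic_patch_days = max(fx$max_patch_days[ant_patch])
  )
}
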