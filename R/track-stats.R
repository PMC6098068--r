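#' Segment search patches from a classified track
#'
#' Applies the patch rule to the posterior-mean behaviour sequence: a patch
#' opens at a location with mean state above the search threshold (1.75) and
#' ends when 3 or more consecutive locations fall at or below it, closing at
#' the last above-threshold location; the track end closes any open patch.
#' Sub-threshold locations inside a surviving patch do not count towards its
#' duration: a patch's duration is 0.5 days per above-threshold location, so
#' per-whale total search time equals the sum of its patch durations.
#'
#' @param track a `classified_tracks` data frame for a single whale (or a
#'   multi-whale one, segmented per whale), or a bare numeric vector of
#'   posterior-mean states
#' @param threshold search threshold on the posterior mean state
#' @param gap number of consecutive at-or-below-threshold locations that
#'   terminates a patch
#' @return data frame with one row per patch: `whale_id` (if available),
#'   `start_idx`, `end_idx`, `start_time`, `end_time`, `n_locations`,
#'   `duration_days`, `region` (majority region of the patch's
#'   above-threshold locations, if coordinates are available)
#' @export
segment_search_patches <- function(track, threshold = 1.75, gap = 3) {
  if (is.numeric(track)) {
    return(patch_scan(track, threshold, gap))
  }
  stopifnot(is.data.frame(track), "b_mean" %in% names(track))
  out <- lapply(split(seq_len(nrow(track)), track$whale_id), function(rows) {
    tr <- track[rows, ]
    p <- patch_scan(tr$b_mean, threshold, gap)
    if (nrow(p) == 0) return(NULL)
    p$whale_id <- tr$whale_id[1]
    p$start_time <- tr$time[p$start_idx]
    p$end_time <- tr$time[p$end_idx]
    p$region <- vapply(seq_len(nrow(p)), function(j) {
      sel <- p$start_idx[j]:p$end_idx[j]
      sel <- sel[tr$b_mean[sel] > threshold]
      regs <- assign_region(tr$lon[sel], tr$lat[sel])
      names(sort(table(regs), decreasing = TRUE))[1]
    }, character(1))
    p[, c("whale_id", "start_idx", "end_idx", "start_time", "end_time",
          "n_locations", "duration_days", "region")]
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(whale_id = character(), start_idx = integer(),
                      end_idx = integer(), n_locations = integer(),
                      duration_days = numeric(), region = character())
  rownames(out) <- NULL
  out
}

## the patch rule on a bare numeric sequence; internal
patch_scan <- function(b, threshold, gap) {
  starts <- integer(0); ends <- integer(0); nlocs <- integer(0)
  open_start <- NA_integer_; last_above <- NA_integer_; n_above <- 0L
  run_below <- 0L
  for (i in seq_along(b)) {
    if (!is.na(b[i]) && b[i] > threshold) {
      if (is.na(open_start)) open_start <- i
      last_above <- i; n_above <- n_above + 1L
      run_below <- 0L
    } else if (!is.na(open_start)) {
      run_below <- run_below + 1L
      if (run_below >= gap) {
        starts <- c(starts, open_start); ends <- c(ends, last_above)
        nlocs <- c(nlocs, n_above)
        open_start <- NA_integer_; n_above <- 0L; run_below <- 0L
      }
    }
  }
  if (!is.na(open_start)) {
    starts <- c(starts, open_start); ends <- c(ends, last_above)
    nlocs <- c(nlocs, n_above)
  }
  data.frame(start_idx = starts, end_idx = ends, n_locations = nlocs,
             duration_days = nlocs * 0.5)
}

#' Assign a search-region label to locations
#'
#' `ANT` (Antarctica) at or south of the Antarctic parallel (60 deg S), else
#' `TS` (Tasman Sea) at or east of the configurable Tasman boundary meridian,
#' else `AU-EC` (east coast Australia).
#'
#' @param lon,lat coordinates in degrees (vectorised)
#' @param ts_boundary meridian (deg E) separating the coastal corridor from
#'   the Tasman Sea
#' @param ant_lat Antarctic boundary latitude
#' @return character vector of region labels
#' @export
assign_region <- function(lon, lat, ts_boundary = 155, ant_lat = -60) {
  ifelse(lat <= ant_lat, "ANT", ifelse(lon >= ts_boundary, "TS", "AU-EC"))
}

#' Classify the initial migratory trajectory
#'
#' `East` if the track first crosses the eastern meridian (160 deg E)
#' eastbound while north of 60 deg S, `West` if it first crosses the western
#' meridian (146 deg E) westbound while north of 60 deg S, otherwise `South`.
#' Longitudes are unwrapped cumulatively so dateline crossings are handled.
#' Tracks entirely south of 60 deg S (Antarctic-tagged whales) return `NA`.
#'
#' @param track data frame with `lon`, `lat` in time order
#' @param east_meridian,west_meridian crossing meridians (deg E)
#' @param ant_lat latitude bounding the temperate zone
#' @return one of `"East"`, `"West"`, `"South"`, or `NA_character_`
#' @export
classify_trajectory <- function(track, east_meridian = 160,
                                west_meridian = 146, ant_lat = -60) {
  north <- track$lat > ant_lat
  if (sum(north) < 2) return(NA_character_)
  lon <- track$lon
  dl <- wrap_lon(diff(lon))
  unwrapped <- lon[1] + c(0, cumsum(dl))
  east_hit <- which(unwrapped >= east_meridian & north)
  west_hit <- which(unwrapped <= west_meridian & north)
  first_east <- if (length(east_hit)) east_hit[1] else Inf
  first_west <- if (length(west_hit)) west_hit[1] else Inf
  if (is.infinite(first_east) && is.infinite(first_west)) return("South")
  if (first_east < first_west) "East" else "West"
}

#' First southbound crossing of a latitude parallel
#'
#' Scans the track in time order for the first segment whose latitude drops
#' through the parallel and returns the linearly interpolated (in time)
#' crossing instant, or `NULL` when the track never crosses southbound.
#'
#' @param track data frame with `time`, `lat` in time order
#' @param lat crossing parallel in degrees (default 60 deg S)
#' @return POSIXct crossing time, or `NULL`
#' @export
parallel_crossing <- function(track, lat = -60) {
  la <- track$lat
  n <- length(la)
  if (n < 2) return(NULL)
  if (la[1] <= lat) return(track$time[1])
  hit <- which(la[-1] <= lat & la[-n] > lat)
  if (length(hit) == 0) return(NULL)
  i <- hit[1]
  frac <- (lat - la[i]) / (la[i + 1] - la[i])
  track$time[i] + frac * as.numeric(difftime(track$time[i + 1], track$time[i],
                                             units = "secs"))
}

#' Per-whale movement summary
#'
#' Computes per whale: track duration, cumulative great-circle distance over
#' consecutive state locations, the first southbound 60 deg S crossing, the
#' distance and speeds (km/day and km/h) north and south of the crossing
#' (the bracketing segment is split at the crossing in proportion to time so
#' the two parts sum exactly to the total), and the initial trajectory class.
#'
#' @param track a `classified_tracks` data frame (one or more whales)
#' @param parallel splitting parallel in degrees
#' @return a `movement_summary` data frame, one row per whale
#' @export
summarize_movement <- function(track, parallel = -60) {
  out <- lapply(split(seq_len(nrow(track)), track$whale_id), function(rows) {
    tr <- track[rows, ]
    n <- nrow(tr)
    if (n < 2) stop("whale ", tr$whale_id[1], " has fewer than 2 locations")
    seg <- great_circle_km(tr$lon[-n], tr$lat[-n], tr$lon[-1], tr$lat[-1])
    total_km <- sum(seg)
    dur_days <- as.numeric(difftime(tr$time[n], tr$time[1], units = "days"))
    crossing <- parallel_crossing(tr, parallel)
    if (is.null(crossing)) {
      north_km <- if (tr$lat[1] > parallel) total_km else 0
      south_km <- total_km - north_km
      days_north <- if (tr$lat[1] > parallel) dur_days else 0
      days_south <- dur_days - days_north
      crossing_time <- as.POSIXct(NA, tz = "UTC")
    } else {
      crossing_time <- crossing
      segf <- numeric(n - 1)
      for (i in seq_len(n - 1)) {
        if (tr$time[i + 1] <= crossing) segf[i] <- 1
        else if (tr$time[i] >= crossing) segf[i] <- 0
        else segf[i] <- as.numeric(difftime(crossing, tr$time[i], units = "secs")) /
            as.numeric(difftime(tr$time[i + 1], tr$time[i], units = "secs"))
      }
      north_km <- sum(seg * segf)
      south_km <- total_km - north_km
      days_north <- as.numeric(difftime(crossing, tr$time[1], units = "days"))
      days_south <- dur_days - days_north
    }
    data.frame(
      whale_id = tr$whale_id[1], duration_days = dur_days,
      distance_km = total_km, crossing_time = crossing_time,
      distance_north_km = north_km, distance_south_km = south_km,
      km_per_day_north = if (days_north > 0) north_km / days_north else NA_real_,
      km_per_day_south = if (days_south > 0) south_km / days_south else NA_real_,
      km_per_h_north = if (days_north > 0) north_km / (24 * days_north) else NA_real_,
      km_per_h_south = if (days_south > 0) south_km / (24 * days_south) else NA_real_,
      trajectory = classify_trajectory(tr))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("movement_summary", "data.frame")
  out
}

#' Cohort aggregate table
#'
#' Aggregates a deployment summary (the packaged fixture) or a set of
#' per-whale [summarize_movement()] rows into per-tagging-group and total
#' rows: n, mean and sample SD (n-1) of track duration and distance and, for
#' deployment summaries, counts (with percentages) of whales with temperate
#' (AU-EC / TS) and Antarctic search regions, or, for movement summaries,
#' initial-trajectory counts with percentages. Temperate and trajectory
#' percentages use the Australian-tagged whales as denominator; Antarctic
#' percentages use all whales.
#'
#' @param x a `deployment_summary` or `movement_summary` data frame; movement
#'   summaries without a `tagging_location` column are aggregated as one
#'   group
#' @return data frame with one row per tagging group plus a `Total` row
#' @export
cohort_table <- function(x) {
  stopifnot(is.data.frame(x))
  if (inherits(x, "movement_summary") || "trajectory" %in% names(x))
    return(cohort_table_moves(x))
  stopifnot("tagging_location" %in% names(x))
  groups <- c(sort(unique(x$tagging_location)), "Total")
  rows <- lapply(groups, function(g) {
    xx <- if (g == "Total") x else x[x$tagging_location == g, ]
    au <- xx$tagging_location %in% c("AU-Eden", "AU-SC")
    has_patch <- !is.na(xx$search_days_total)
    n_ec <- sum(has_patch & xx$search_days_au_ec > 0, na.rm = TRUE)
    n_ts <- sum(has_patch & xx$search_days_ts > 0, na.rm = TRUE)
    n_ant <- sum(has_patch & xx$search_days_ant > 0, na.rm = TRUE)
    n_au <- sum(au)
    data.frame(
      group = g, n = nrow(xx),
      duration_mean = mean(xx$duration_days), duration_sd = sd(xx$duration_days),
      distance_mean = mean(xx$distance_km), distance_sd = sd(xx$distance_km),
      n_temperate_ec = n_ec, n_temperate_ts = n_ts, n_antarctic = n_ant,
      pct_temperate_ec = if (n_au > 0) round(100 * n_ec / n_au, 1) else NA_real_,
      pct_temperate_ts = if (n_au > 0) round(100 * n_ts / n_au, 1) else NA_real_,
      pct_antarctic = round(100 * n_ant / nrow(xx), 1))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## trajectory-count aggregation of movement summaries; internal
cohort_table_moves <- function(x) {
  if (!"tagging_location" %in% names(x)) x$tagging_location <- "all"
  groups <- c(sort(unique(x$tagging_location)), "Total")
  rows <- lapply(groups, function(g) {
    xx <- if (g == "Total") x else x[x$tagging_location == g, ]
    n_cls <- sum(!is.na(xx$trajectory))
    cnt <- function(v) sum(xx$trajectory == v, na.rm = TRUE)
    data.frame(
      group = g, n = nrow(xx),
      duration_mean = mean(xx$duration_days), duration_sd = sd(xx$duration_days),
      distance_mean = mean(xx$distance_km), distance_sd = sd(xx$distance_km),
      n_south = cnt("South"), n_west = cnt("West"), n_east = cnt("East"),
      pct_south = if (n_cls > 0) round(100 * cnt("South") / n_cls, 1) else NA_real_,
      pct_west = if (n_cls > 0) round(100 * cnt("West") / n_cls, 1) else NA_real_,
      pct_east = if (n_cls > 0) round(100 * cnt("East") / n_cls, 1) else NA_real_,
      n_crossed_60s = sum(!is.na(xx$crossing_time)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
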