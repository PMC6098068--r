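#' Read Argos observations from delimited text
#'
#' Parses a CSV with header `whale_id, timestamp, lon, lat, loc_class`
#' (optionally `campaign`). Timestamps are ISO-8601 UTC. Rows with an unknown
#' location-class token or an unparseable timestamp are rejected with a
#' warning; within each whale, rows are time-sorted and later duplicates of a
#' timestamp are dropped (with a message). Longitudes are normalised to
#' [-180, 180).
#'
#' @param path file path
#' @return an `argos_obs` data frame
#' @export
read_argos_csv <- function(path) {
  raw <- read.csv(path, colClasses = "character")
  if (nrow(raw) == 0) stop("empty Argos file: ", path)
  need <- c("whale_id", "timestamp", "lon", "lat", "loc_class")
  if (!all(need %in% names(raw)))
    stop("missing required columns: ", paste(setdiff(need, names(raw)), collapse = ", "))
  time <- as.POSIXct(raw$timestamp, tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                    "%Y-%m-%d"))
  lon <- suppressWarnings(as.numeric(raw$lon))
  lat <- suppressWarnings(as.numeric(raw$lat))
  bad_class <- !(raw$loc_class %in% ARGOS_CLASSES)
  bad <- bad_class | is.na(time) | is.na(lon) | is.na(lat) | abs(lat) > 90
  if (any(bad_class))
    warning(sum(bad_class), " row(s) with unknown location class rejected")
  if (any(bad & !bad_class))
    warning(sum(bad & !bad_class), " malformed row(s) rejected")
  obs <- data.frame(whale_id = raw$whale_id[!bad], time = time[!bad],
                    lon = wrap_lon(lon[!bad]), lat = lat[!bad],
                    loc_class = raw$loc_class[!bad],
                    campaign = if ("campaign" %in% names(raw))
                      raw$campaign[!bad] else "unknown")
  obs <- obs[order(obs$whale_id, obs$time), ]
  dup <- duplicated(obs[, c("whale_id", "time")])
  if (any(dup))
    message(sum(dup), " duplicate timestamp(s) dropped (later duplicate)")
  obs <- obs[!dup, ]
  rownames(obs) <- NULL
  class(obs) <- c("argos_obs", "data.frame")
  obs
}

#' Write Argos observations as delimited text
#'
#' @param obs an `argos_obs` data frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_argos_csv <- function(obs, path) {
  out <- data.frame(whale_id = obs$whale_id,
                    timestamp = format(obs$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                    lon = sprintf("%.10f", obs$lon),
                    lat = sprintf("%.10f", obs$lat),
                    loc_class = obs$loc_class,
                    campaign = if ("campaign" %in% names(obs)) obs$campaign else "unknown")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pre-model observation filtering
#'
#' Drops invalid class-Z fixes and, optionally, fixes implying a sustained
#' great-circle speed above `max_speed_kmh` relative to the previous retained
#' fix of the same whale. The speed filter is disabled by default because the
#' state-space observation model absorbs Argos location error; enabling it is
#' only sensible for exploratory track cleaning. Never reorders rows; output
#' is a subset of the input.
#'
#' @param obs an `argos_obs` data frame
#' @param max_speed_kmh speed threshold in km/h (`Inf` disables)
#' @param drop_z drop class-Z rows (default TRUE)
#' @return filtered `argos_obs`
#' @export
prefilter_observations <- function(obs, max_speed_kmh = Inf, drop_z = TRUE) {
  keep <- rep(TRUE, nrow(obs))
  if (drop_z) keep <- obs$loc_class != "Z"
  if (is.finite(max_speed_kmh)) {
    for (id in unique(obs$whale_id)) {
      idx <- which(obs$whale_id == id & keep)
      if (length(idx) < 2) next
      last <- idx[1]
      for (j in idx[-1]) {
        dt_h <- as.numeric(difftime(obs$time[j], obs$time[last], units = "hours"))
        d <- great_circle_km(obs$lon[last], obs$lat[last], obs$lon[j], obs$lat[j])
        if (dt_h > 0 && d / dt_h > max_speed_kmh) keep[j] <- FALSE else last <- j
      }
    }
  }
  out <- obs[keep, ]
  rownames(out) <- NULL
  class(out) <- c("argos_obs", "data.frame")
  out
}
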