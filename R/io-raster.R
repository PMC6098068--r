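#' Write a gridded field to a self-describing plain-text raster file
#'
#' Serialises a regular lon/lat field (optionally with a time dimension) in a
#' small CF-like plain-text format: a header carrying the variable name,
#' units and coordinate axes, followed by the values row-by-row. Values are
#' written with full double precision so a write/read round trip is exact.
#'
#' @param field matrix `[n_lon, n_lat]` or array `[n_lon, n_lat, n_time]`
#' @param path output path
#' @param name variable name
#' @param units units string (preserved on read)
#' @param lon,lat cell-centre axes
#' @param time optional character vector of time labels (dates or days)
#' @return `path`, invisibly
#' @export
write_raster <- function(field, path, name, units, lon, lat, time = NULL) {
  nd <- length(dim(field))
  stopifnot(nd %in% c(2, 3), dim(field)[1] == length(lon),
            dim(field)[2] == length(lat))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("whalessm-grid 1",
               paste0("name: ", name),
               paste0("units: ", units),
               paste0("lon: ", paste(sprintf("%.17g", lon), collapse = ",")),
               paste0("lat: ", paste(sprintf("%.17g", lat), collapse = ","))),
             con)
  if (!is.null(time)) writeLines(paste0("time: ", paste(time, collapse = ",")), con)
  writeLines("data:", con)
  slices <- if (nd == 2) 1 else dim(field)[3]
  for (s in seq_len(slices)) {
    sl <- if (nd == 2) field else field[, , s]
    for (j in seq_len(length(lat)))
      writeLines(paste(sprintf("%.17g", sl[, j]), collapse = " "), con)
  }
  invisible(path)
}

#' Read a gridded field written by [write_raster()]
#'
#' Ice-concentration fields (units `%`) with values above 100 are clipped to
#' 100 with a warning; values below 0 are clipped to 0.
#'
#' @param path file path
#' @return list with `field` (matrix or 3-d array), `name`, `units`, `lon`,
#'   `lat` and optional `time`
#' @export
read_raster <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 6 || lines[1] != "whalessm-grid 1")
    stop("not a whalessm grid file: ", path)
  hdr_end <- match("data:", lines)
  hdr <- lines[2:(hdr_end - 1)]
  get <- function(key) {
    m <- grep(paste0("^", key, ": "), hdr, value = TRUE)
    if (length(m) == 0) NULL else sub(paste0("^", key, ": "), "", m[1])
  }
  name <- get("name"); units <- get("units")
  lon <- as.numeric(strsplit(get("lon"), ",")[[1]])
  lat <- as.numeric(strsplit(get("lat"), ",")[[1]])
  time <- if (!is.null(get("time"))) strsplit(get("time"), ",")[[1]] else NULL
  vals <- lines[(hdr_end + 1):length(lines)]
  nx <- length(lon); ny <- length(lat)
  nt <- if (is.null(time)) 1L else length(time)
  if (length(vals) != ny * nt)
    stop("grid file has ", length(vals), " data rows; expected ", ny * nt)
  num <- lapply(vals, function(l) as.numeric(strsplit(l, " ")[[1]]))
  if (any(lengths(num) != nx)) stop("row length mismatch in ", path)
  arr <- array(NA_real_, c(nx, ny, nt))
  r <- 1L
  for (s in seq_len(nt)) for (j in seq_len(ny)) {
    arr[, j, s] <- num[[r]]; r <- r + 1L
  }
  if (identical(units, "%")) {
    over <- sum(arr > 100, na.rm = TRUE)
    if (over > 0) {
      warning(over, " ice concentration value(s) above 100% clipped to 100")
      arr[arr > 100] <- 100
    }
    arr[arr < 0] <- 0
  }
  field <- if (is.null(time)) arr[, , 1] else arr
  list(field = field, name = name, units = units, lon = lon, lat = lat,
       time = time)
}

#' Write an environmental stack to a directory of raster files
#'
#' @param stack an `env_stack`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_env_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_raster(stack$bathymetry, file.path(dir, "bathymetry.grid"),
               "bathymetry", "m", stack$lon, stack$lat)
  write_raster(stack$chla, file.path(dir, "chla.grid"),
               "chlorophyll_climatology", "mg m-3", stack$lon, stack$lat)
  for (m in stack$months) {
    arr <- stack$ice[[m]]
    write_raster(arr, file.path(dir, paste0("ice_", m, ".grid")),
                 "ice_concentration", "%", stack$lon, stack$lat,
                 time = paste0(m, "-", sprintf("%02d", seq_len(dim(arr)[3]))))
  }
  invisible(dir)
}

#' Read an environmental stack from a directory written by [write_env_stack()]
#'
#' All fields must share one grid; a mismatch is an error naming both grids.
#'
#' @param dir directory path
#' @return an `env_stack`
#' @export
read_env_stack <- function(dir) {
  bathy <- read_raster(file.path(dir, "bathymetry.grid"))
  chla <- read_raster(file.path(dir, "chla.grid"))
  check_grid <- function(a, b) {
    if (!isTRUE(all.equal(a$lon, b$lon)) || !isTRUE(all.equal(a$lat, b$lat)))
      stop(sprintf(
        "grid mismatch: %s is %dx%d [%g..%g, %g..%g] but %s is %dx%d [%g..%g, %g..%g]",
        a$name, length(a$lon), length(a$lat), min(a$lon), max(a$lon),
        min(a$lat), max(a$lat),
        b$name, length(b$lon), length(b$lat), min(b$lon), max(b$lon),
        min(b$lat), max(b$lat)))
  }
  check_grid(bathy, chla)
  ice_files <- sort(list.files(dir, pattern = "^ice_\\d{4}-\\d{2}\\.grid$",
                               full.names = TRUE))
  months <- sub("^ice_(\\d{4}-\\d{2})\\.grid$", "\\1", basename(ice_files))
  ice <- list()
  for (i in seq_along(ice_files)) {
    r <- read_raster(ice_files[i])
    check_grid(bathy, r)
    ice[[months[i]]] <- r$field
  }
  structure(list(lon = bathy$lon, lat = bathy$lat, bathymetry = bathy$field,
                 chla = chla$field, ice = ice, months = months,
                 res = if (length(bathy$lon) > 1) diff(bathy$lon[1:2]) else NA_real_),
            class = "env_stack")
}
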