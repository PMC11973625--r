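#' Write release polygons as GeoJSON
#'
#' FeatureCollection of Polygon features in lon/lat (WGS84) with properties
#' `id`, `cover_pct` and, when allocated, `n_particles`.
#'
#' @param polygons List of [release_polygon()].
#' @param grid A [grid_spec()] (for the local-to-lon/lat conversion).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_polygons_geojson <- function(polygons, grid, path) {
  feats <- lapply(polygons, function(p) {
    v <- rbind(p$vertices, p$vertices[1, ])
    ll <- local_to_lonlat(grid, v[, 1], v[, 2])
    props <- list(id = p$id, cover_pct = p$cover_pct)
    if (!is.na(p$n_particles)) props$n_particles <- p$n_particles
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(Map(c, ll$lon, ll$lat))))
  })
  gj <- list(type = "FeatureCollection", features = unname(feats))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read release polygons from GeoJSON
#'
#' @param path GeoJSON FeatureCollection file.
#' @param grid A [grid_spec()].
#' @return List of [release_polygon()] (coordinates converted to local
#'   metres; the closing vertex is dropped).
#' @export
read_polygons_geojson <- function(path, grid) {
  gj <- jsonlite::read_json(path)
  out <- list()
  for (f in gj$features) {
    ring <- f$geometry$coordinates[[1]]
    lon <- vapply(ring, function(c) c[[1]], numeric(1))
    lat <- vapply(ring, function(c) c[[2]], numeric(1))
    m <- length(lon)
    if (lon[1] == lon[m] && lat[1] == lat[m]) { lon <- lon[-m]; lat <- lat[-m] }
    xy <- lonlat_to_local(grid, lon, lat)
    p <- f$properties
    id <- if (!is.null(p$id)) p$id else paste0("poly_", length(out) + 1L)
    out[[id]] <- release_polygon(
      id = id, vertices = cbind(xy$x, xy$y),
      cover_pct = if (!is.null(p$cover_pct)) p$cover_pct else 0,
      n_particles = if (!is.null(p$n_particles)) p$n_particles else NA_integer_)
  }
  out
}

#' Convert a track ensemble to a long data frame
#'
#' One row per particle and timepoint, the tabular form fed to GIS tools and
#' count post-processing.
#'
#' @param ensemble A [advect_ensemble()] result.
#' @param grid Optional [grid_spec()] to add lon/lat columns.
#' @return Data frame with `particle`, `step`, `time_s`, `x`, `y`, `depth_m`,
#'   `status` (and `lon`, `lat` when `grid` is given).
#' @export
tracks_to_df <- function(ensemble, grid = NULL) {
  nT <- nrow(ensemble$x); np <- ncol(ensemble$x)
  labs <- c("active", "boundary_hit", "removed_stationary")
  out <- data.frame(
    particle = rep(seq_len(np), each = nT),
    step = rep(seq_len(nT), times = np),
    time_s = rep(ensemble$times, times = np),
    x = as.vector(ensemble$x), y = as.vector(ensemble$y),
    depth_m = rep(ensemble$depth, nT * np),
    status = labs[as.vector(ensemble$status) + 1L])
  if (!is.null(grid)) {
    ll <- local_to_lonlat(grid, out$x, out$y)
    out$lon <- ll$lon; out$lat <- ll$lat
  }
  out
}

#' Write a track ensemble as JSON
#'
#' Per-particle arrays of `[time_s, x, y, depth_m]` plus a status vector and
#' run metadata; the round trip through [read_tracks_json()] is lossless.
#'
#' @param ensemble A [advect_ensemble()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tracks_json <- function(ensemble, path) {
  np <- ncol(ensemble$x)
  obj <- list(
    format = "larvaflow_tracks_v1",
    polygon_id = ensemble$polygon_id,
    depth_m = ensemble$depth,
    dt_s = ensemble$config$dt,
    times = ensemble$times,
    t_release = ensemble$t_release,
    release_complete_step = ensemble$release_complete_step,
    excluded_from_step = ensemble$excluded_from_step,
    particles = lapply(seq_len(np), function(p) list(
      x = ensemble$x[, p], y = ensemble$y[, p],
      status = ensemble$status[, p])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read a track ensemble from JSON
#'
#' @param path File written by [write_tracks_json()].
#' @param config Optional [tracking_config()] to attach (the JSON stores only
#'   `dt`).
#' @return A `track_ensemble`.
#' @export
read_tracks_json <- function(path, config = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(obj$format, "larvaflow_tracks_v1"))
    stop("not a larvaflow track file: ", path)
  np <- length(obj$particles)
  nT <- length(obj$times)
  X <- matrix(NA_real_, nT, np); Y <- X; S <- matrix(0L, nT, np)
  for (p in seq_len(np)) {
    X[, p] <- obj$particles[[p]]$x
    Y[, p] <- obj$particles[[p]]$y
    S[, p] <- obj$particles[[p]]$status
  }
  structure(list(times = obj$times, x = X, y = Y, status = S,
                 depth = obj$depth_m, config = config,
                 polygon_id = obj$polygon_id,
                 t_release = obj$t_release,
                 release_complete_step = obj$release_complete_step,
                 excluded_from_step =
                   if (is.null(obj$excluded_from_step)) NA_integer_
                   else obj$excluded_from_step),
            class = "track_ensemble")
}

#' Write a density raster as an ESRI ASCII grid
#'
#' Plain-text raster interchange format readable by standard GIS tools.
#'
#' @param raster A [slick_density()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(raster, path) {
  g <- raster$grid
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", g$nx),
               sprintf("nrows %d", g$ny),
               "xllcorner 0", "yllcorner 0",
               sprintf("cellsize %g", g$cell_size),
               "NODATA_value -9999"), con)
  for (j in rev(seq_len(g$ny)))   # north row first
    writeLines(paste(raster$counts[j, ], collapse = " "), con)
  invisible(path)
}

#' Write / read a current field as headered CSV text
#'
#' Self-describing plain-text serialization: `#`-prefixed header lines with
#' the grid parameters, then one row per (step, depth, row, column) with u, v
#' and the cell mask. Intended for small fields (fixtures, demos); use
#' [write_field_netcdf()] for large ones.
#'
#' @param field A [current_field()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(field, path) {
  g <- field$grid
  hdr <- c("# larvaflow current_field v1",
           sprintf("# nx=%d ny=%d cell_size=%g time_step=%g n_steps=%d",
                   g$nx, g$ny, g$cell_size, g$time_step, g$n_steps),
           sprintf("# origin_lon=%.10g origin_lat=%.10g",
                   g$origin_lonlat[1], g$origin_lonlat[2]),
           sprintf("# depth_layers=%s",
                   paste(g$depth_layers, collapse = ";")))
  nD <- length(g$depth_layers)
  df <- data.frame(
    step = rep(seq_len(g$n_steps), times = nD * g$ny * g$nx),
    depth_idx = rep(rep(seq_len(nD), each = g$n_steps), times = g$ny * g$nx),
    j = rep(rep(seq_len(g$ny), each = g$n_steps * nD), times = g$nx),
    i = rep(seq_len(g$nx), each = g$n_steps * nD * g$ny),
    u = as.vector(field$u), v = as.vector(field$v))
  df$mask <- field$mask[cbind(df$j, df$i)]
  con <- file(path, "w")
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_field_csv
#' @export
read_field_csv <- function(path) {
  lines <- readLines(path, n = 10)
  hdr <- lines[startsWith(lines, "#")]
  kv <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[^ ]+"), hdr))
    sub(paste0(key, "="), "", m[m != ""][1])
  }
  depths <- as.numeric(strsplit(kv("depth_layers"), ";")[[1]])
  g <- grid_spec(nx = as.integer(kv("nx")), ny = as.integer(kv("ny")),
                 cell_size = as.numeric(kv("cell_size")),
                 depth_layers = depths,
                 time_step = as.numeric(kv("time_step")),
                 n_steps = as.integer(kv("n_steps")),
                 origin_lonlat = c(as.numeric(kv("origin_lon")),
                                   as.numeric(kv("origin_lat"))))
  df <- utils::read.csv(path, comment.char = "#")
  dm <- c(g$n_steps, length(depths), g$ny, g$nx)
  u <- array(df$u, dim = dm); v <- array(df$v, dim = dm)
  mask <- matrix(0L, g$ny, g$nx)
  first <- df$step == 1 & df$depth_idx == 1
  mask[cbind(df$j[first], df$i[first])] <- as.integer(df$mask[first])
  current_field(g, u, v, mask)
}

#' Write / read a current field as CF-style NetCDF
#'
#' Dimensions `time`, `depth`, `y`, `x`; variables `u`, `v`, `mask`; global
#' attributes carry the grid origin and cell size. Requires the `ncdf4`
#' package.
#'
#' @param field A [current_field()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_field_netcdf <- function(field, path) {
  if (!requireNamespace("ncdf4", quietly = TRUE))
    stop("the ncdf4 package is required for NetCDF output; ",
         "use write_field_csv() otherwise")
  g <- field$grid
  ctr <- grid_centers(g)
  dim_t <- ncdf4::ncdim_def("time", "seconds since start", grid_times(g))
  dim_d <- ncdf4::ncdim_def("depth", "m", g$depth_layers)
  dim_y <- ncdf4::ncdim_def("y", "m", ctr$y)
  dim_x <- ncdf4::ncdim_def("x", "m", ctr$x)
  dims <- list(dim_t, dim_d, dim_y, dim_x)
  vu <- ncdf4::ncvar_def("u", "m s-1", dims, prec = "double")
  vv <- ncdf4::ncvar_def("v", "m s-1", dims, prec = "double")
  vm <- ncdf4::ncvar_def("mask", "", list(dim_y, dim_x), prec = "integer")
  nc <- ncdf4::nc_create(path, list(vu, vv, vm))
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, vu, field$u)
  ncdf4::ncvar_put(nc, vv, field$v)
  ncdf4::ncvar_put(nc, vm, field$mask)
  ncdf4::ncatt_put(nc, 0, "origin_lon", g$origin_lonlat[1])
  ncdf4::ncatt_put(nc, 0, "origin_lat", g$origin_lonlat[2])
  ncdf4::ncatt_put(nc, 0, "cell_size_m", g$cell_size)
  invisible(path)
}

#' @rdname write_field_netcdf
#' @export
read_field_netcdf <- function(path) {
  if (!requireNamespace("ncdf4", quietly = TRUE))
    stop("the ncdf4 package is required for NetCDF input")
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  u <- ncdf4::ncvar_get(nc, "u", collapse_degen = FALSE)
  v <- ncdf4::ncvar_get(nc, "v", collapse_degen = FALSE)
  mask <- ncdf4::ncvar_get(nc, "mask", collapse_degen = FALSE)
  tt <- ncdf4::ncvar_get(nc, "time")
  dd <- ncdf4::ncvar_get(nc, "depth")
  g <- grid_spec(
    nx = dim(u)[4], ny = dim(u)[3],
    cell_size = ncdf4::ncatt_get(nc, 0, "cell_size_m")$value,
    depth_layers = dd,
    time_step = if (length(tt) > 1) tt[2] - tt[1] else 1,
    n_steps = length(tt),
    origin_lonlat = c(ncdf4::ncatt_get(nc, 0, "origin_lon")$value,
                      ncdf4::ncatt_get(nc, 0, "origin_lat")$value))
  current_field(g, u, v, matrix(as.integer(mask), g$ny, g$nx))
}

#' Write a tiltmeter or wind series as CSV with ISO-8601 timestamps
#'
#' @param series Data frame with a `time_s` column (seconds).
#' @param path Output path.
#' @param t0 Origin timestamp (POSIXct; default 2022-12-01 00:00 UTC).
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path,
                             t0 = as.POSIXct("2022-12-01 00:00:00",
                                             tz = "UTC")) {
  out <- series
  out$timestamp <- format(t0 + out$time_s, "%Y-%m-%dT%H:%M:%SZ")
  out <- out[, c("timestamp", setdiff(names(out), "timestamp"))]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
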