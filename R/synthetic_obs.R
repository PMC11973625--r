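#' Generate a synthetic wind time series
#'
#' Steady mean wind plus AR(1) gust fluctuations, the forcing used for
#' surface windage scenarios. The default mean wind blows toward the
#' west-northwest, the direction trade winds push buoyant material in the
#' region this package emulates.
#'
#' @param duration_h Series length in hours.
#' @param dt_s Sampling interval in seconds (default 600).
#' @param mean_wind Length-2 `c(u, v)` mean wind in m/s.
#' @param gust_sd Standard deviation of the AR(1) fluctuation per component
#'   (m/s).
#' @param ar Autocorrelation of the fluctuation between consecutive samples.
#' @param seed Integer seed.
#'
#' @return Data frame with `time_s`, `wind_u`, `wind_v`.
#' @export
make_wind_series <- function(duration_h, dt_s = 600, mean_wind = c(-4, 2),
                             gust_sd = 1, ar = 0.95, seed = 1L) {
  tt <- seq(0, duration_h * 3600, by = dt_s)
  n <- length(tt)
  set.seed(seed)
  innov_sd <- gust_sd * sqrt(1 - ar^2)
  gu <- stats::filter(stats::rnorm(n, 0, innov_sd), ar, "recursive")
  gv <- stats::filter(stats::rnorm(n, 0, innov_sd), ar, "recursive")
  data.frame(time_s = tt,
             wind_u = mean_wind[1] + as.numeric(gu),
             wind_v = mean_wind[2] + as.numeric(gv))
}

#' Sample a virtual surface drifter from a current field
#'
#' Advects a single near-surface (nominal 1-m depth) particle through the
#' field with a fine internal integration step and samples its position at
#' GPS-like fixes spaced 5--10 min apart, adding Gaussian position noise per
#' fix. This emulates the satellite-tracked drifters used to validate
#' near-surface model drift.
#'
#' @param field A [current_field()].
#' @param start Length-2 `c(x, y)` start position in metres (must be water).
#' @param duration_h Deployment length in hours.
#' @param start_time Deployment start in seconds on the field time axis.
#' @param fix_interval Fix spacing in seconds; a scalar in `[300, 600]` for
#'   regular fixes, or `NULL` (default) to draw each interval uniformly from
#'   that range.
#' @param gps_sigma GPS position noise standard deviation in metres per
#'   coordinate (accuracy of the tracker; a free parameter of the emulator).
#' @param internal_dt Internal integration step in seconds (default 60).
#' @param seed Integer seed.
#'
#' @return Data frame of fixes (`time_s`, `x`, `y`, `lon`, `lat`) of class
#'   `drifter_track` with attribute `nominal_depth = 1`.
#' @export
sample_drifter <- function(field, start, duration_h, start_time = 0,
                           fix_interval = NULL, gps_sigma = 3,
                           internal_dt = 60, seed = 1L) {
  g <- field$grid
  ci <- cell_index(g, start[1], start[2])
  if (is.na(ci$i) || field$mask[ci$j, ci$i] != 0L)
    stop("drifter start position must lie on a water cell")
  cfg <- tracking_config(duration_h = duration_h, release_depth = 1,
                         dt = internal_dt, n_particles = 1, seed = seed,
                         release_jitter = FALSE)
  seeds <- data.frame(x = start[1], y = start[2], t_release = start_time)
  ens <- advect_ensemble(field, seeds, cfg)

  set.seed(seed)
  end_t <- start_time + duration_h * 3600
  if (is.null(fix_interval)) {
    ft <- start_time
    while (ft[length(ft)] < end_t)
      ft <- c(ft, ft[length(ft)] + stats::runif(1, 300, 600))
    ft <- ft[ft <= end_t]
  } else {
    stopifnot(fix_interval >= 300, fix_interval <= 600)
    ft <- seq(start_time, end_t, by = fix_interval)
  }
  fx <- stats::approx(ens$times, ens$x[, 1], xout = ft)$y
  fy <- stats::approx(ens$times, ens$y[, 1], xout = ft)$y
  if (gps_sigma > 0) {
    fx <- fx + stats::rnorm(length(ft), 0, gps_sigma)
    fy <- fy + stats::rnorm(length(ft), 0, gps_sigma)
  }
  ll <- local_to_lonlat(g, fx, fy)
  structure(data.frame(time_s = ft, x = fx, y = fy,
                       lon = ll$lon, lat = ll$lat),
            class = c("drifter_track", "data.frame"), nominal_depth = 1)
}

#' Sample a virtual tilt current meter from a current field
#'
#' Emulates a benthic tilt current meter logging speed and direction at
#' fixed (typically 1-s) intervals from the nearest grid cell, with
#' instrument noise and optional sub-grid placement bias: meters on exposed
#' reef tops see roughly the cell-scale flow (`gain` near 1), meters down in
#' grooves between reef structures see attenuated, more directionally
#' scattered flow (`gain < 1`, `heading_scatter > 0`).
#'
#' @param field A [current_field()].
#' @param site Length-2 `c(x, y)` metres (must be water).
#' @param depth Instrument depth in metres (nearest stored layer is sampled).
#' @param duration_h Record length in hours.
#' @param sample_interval Sampling interval in seconds (default 1).
#' @param noise_sigma Speed noise SD in m/s.
#' @param gain Multiplicative sub-grid speed gain.
#' @param heading_offset Systematic rotation of the sampled heading, degrees.
#' @param heading_scatter SD of random heading scatter, degrees.
#' @param start_time Record start on the field time axis, seconds.
#' @param site_id,habitat Metadata labels stored as attributes.
#' @param seed Integer seed.
#'
#' @return Data frame (`time_s`, `speed`, `heading`) of class
#'   `tiltmeter_series` with attributes `site_id`, `depth`, `habitat`.
#' @export
sample_tiltmeter <- function(field, site, depth, duration_h,
                             sample_interval = 1, noise_sigma = 0,
                             gain = 1, heading_offset = 0,
                             heading_scatter = 0, start_time = 0,
                             site_id = "site", habitat = "reef_top",
                             seed = 1L) {
  g <- field$grid
  ci <- cell_index(g, site[1], site[2])
  if (is.na(ci$i) || field$mask[ci$j, ci$i] != 0L)
    stop("tiltmeter site must lie on a water cell")
  cs <- field_cell_series(field, ci$i, ci$j, depth)
  n <- round(duration_h * 3600 / sample_interval)
  tt <- start_time + (seq_len(n) - 1) * sample_interval
  u <- stats::approx(cs$time_s, cs$u, xout = tt, rule = 2)$y
  v <- stats::approx(cs$time_s, cs$v, xout = tt, rule = 2)$y
  sh <- uv_to_heading(u, v)
  set.seed(seed)
  speed <- gain * sh$speed
  if (noise_sigma > 0) speed <- pmax(speed + stats::rnorm(n, 0, noise_sigma), 0)
  heading <- sh$heading + heading_offset
  if (heading_scatter > 0) heading <- heading + stats::rnorm(n, 0, heading_scatter)
  structure(data.frame(time_s = tt, speed = speed, heading = heading %% 360),
            class = c("tiltmeter_series", "data.frame"),
            site_id = site_id, depth = depth, habitat = habitat)
}

#' Generate non-overlapping coral release polygons on water
#'
#' Places `n` rectangular reef polygons with live-coral cover drawn uniformly
#' from `cover_range`, rejecting placements whose corners or centre fall on
#' land or that overlap an existing polygon. A stand-in for mapped reef
#' habitat polygons.
#'
#' @param field A [current_field()] providing the water mask.
#' @param n Number of polygons (>= 1).
#' @param cover_range Live coral cover range in percent, `c(lo, hi)`.
#' @param area_range Polygon area range in square metres.
#' @param seed Integer seed.
#' @param max_tries Placement attempts before giving up.
#'
#' @return List of [release_polygon()] objects.
#' @export
make_coral_polygons <- function(field, n, cover_range = c(5, 80),
                                area_range = c(2000, 20000), seed = 1L,
                                max_tries = 500L * n) {
  stopifnot(n >= 1)
  g <- field$grid
  set.seed(seed)
  polys <- list()
  boxes <- matrix(numeric(0), 0, 4)
  tries <- 0L
  while (length(polys) < n && tries < max_tries) {
    tries <- tries + 1L
    area <- stats::runif(1, area_range[1], area_range[2])
    aspect <- stats::runif(1, 0.5, 2)
    w <- sqrt(area * aspect); h <- area / w
    x0 <- stats::runif(1, 0, g$nx * g$cell_size - w)
    y0 <- stats::runif(1, 0, g$ny * g$cell_size - h)
    px <- c(x0, x0 + w, x0 + w, x0)
    py <- c(y0, y0, y0 + h, y0 + h)
    ci <- cell_index(g, c(px, x0 + w / 2), c(py, y0 + h / 2))
    if (any(is.na(ci$i)) || any(field$mask[cbind(ci$j, ci$i)] != 0L)) next
    if (nrow(boxes) && any(x0 < boxes[, 2] & x0 + w > boxes[, 1] &
                           y0 < boxes[, 4] & y0 + h > boxes[, 3])) next
    boxes <- rbind(boxes, c(x0, x0 + w, y0, y0 + h))
    id <- sprintf("reef_%02d", length(polys) + 1L)
    polys[[id]] <- release_polygon(
      id = id, vertices = cbind(px, py),
      cover_pct = stats::runif(1, cover_range[1], cover_range[2]))
  }
  if (length(polys) < n)
    stop("could not pack ", n, " non-overlapping polygons on water after ",
         max_tries, " tries")
  polys
}
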