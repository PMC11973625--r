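#' Demo pipeline configuration
#'
#' A self-contained synthetic scenario exercising every stage: a tidally
#' dominated 4 x 4 km domain with a sheltered retention zone and a 500-m
#' eddy, coral release polygons, a two-night-scale slick run, a small
#' residency sweep, drifter/tiltmeter validation and slack detection. All
#' sizes are kept small so the full pipeline runs in seconds.
#'
#' @param seed Master seed; every stage derives its sub-seeds from it.
#' @param out_dir Output directory (default: a fresh directory under
#'   `tempdir()`).
#' @return Nested configuration list for [run_pipeline()].
#' @export
demo_run_config <- function(seed = 1L, out_dir = NULL) {
  if (is.null(out_dir))
    out_dir <- file.path(tempdir(), paste0("larvaflow_demo_", seed))
  shelter <- cbind(c(500, 1700, 1700, 500), c(500, 500, 1500, 1500))
  list(
    name = "demo",
    seed = as.integer(seed),
    out_dir = out_dir,
    field = list(nx = 80, ny = 80, cell_size = 50,
                 depth_layers = c(0.25, 3.6), time_step = 720,
                 n_steps = 191,   # 38 h
                 tidal_amp = 0.12, tidal_period_h = 12.42,
                 tidal_axis_deg = 90, mean_flow = c(0.01, -0.03),
                 shelter = list(polygon = shelter, attenuation = 0.08),
                 eddy = list(center = c(3000, 3000), radius = 250,
                             v_max = 0.08)),
    wind = list(mean_wind = c(-4, 2), gust_sd = 1),
    polygons = list(n = 5, cover_range = c(5, 60),
                    area_range = c(5000, 20000)),
    slick = list(release_start_h = 19, duration_h = 16, drag_pcts = c(0, 3),
                 target_per_subpolygon = 150, total_budget = 1500),
    residency = list(sites = list(sheltered = c(1100, 1000),
                                  open = c(2600, 1000)),
                     day_starts_s = c(day1 = 0), release_hours = 10:12,
                     n_particles = 200, duration_h = 12),
    validation = list(drifter_start = c(1900, 2200), drifter_hours = 4,
                      n_particles = 200, gps_sigma = 3,
                      tiltmeter_site = c(2600, 1400), tiltmeter_depth = 3.6,
                      tiltmeter_gain = 0.9, tiltmeter_noise = 0.01),
    slack = list(site = c(1100, 1400), depth = 3.6, avg_interval_s = 60,
                 threshold = 0.022, penalty = NULL))
}

.stage_deps <- c(slick = "fields", residency = "fields",
                 validation = "fields", slack = "fields")

#' Run the dispersal analysis pipeline
#'
#' Executes the requested stages in dependency order -- synthetic field and
#' observation generation, spawn-slick density mapping, residency survey,
#' validation, slack detection -- and writes all outputs plus a manifest
#' (inputs, parameters, seed, file checksums, versions) under
#' `config$out_dir`.
#'
#' @param config Configuration list, e.g. from [demo_run_config()].
#' @param stages Character subset of
#'   `c("fields", "slick", "residency", "validation", "slack")`.
#'
#' @return The manifest list, invisibly. Stage results are stored in the
#'   manifest element `results`.
#' @export
run_pipeline <- function(config,
                         stages = c("fields", "slick", "residency",
                                    "validation", "slack")) {
  stages <- match.arg(stages, several.ok = TRUE)
  for (s in intersect(stages, names(.stage_deps)))
    if (!.stage_deps[[s]] %in% stages)
      stop("stage '", s, "' requires stage '", .stage_deps[[s]], "'")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  res <- list()
  files <- character(0)

  fld <- NULL; wind <- NULL; polys <- NULL
  if ("fields" %in% stages) {
    fc <- config$field
    g <- grid_spec(nx = fc$nx, ny = fc$ny, cell_size = fc$cell_size,
                   depth_layers = fc$depth_layers,
                   time_step = fc$time_step, n_steps = fc$n_steps)
    fld <- build_tidal_field(g, tidal_amp = fc$tidal_amp,
                             tidal_period_h = fc$tidal_period_h,
                             tidal_axis_deg = fc$tidal_axis_deg,
                             mean_flow = fc$mean_flow)
    if (!is.null(fc$shelter))
      fld <- apply_shelter(fld, fc$shelter$polygon, fc$shelter$attenuation)
    if (!is.null(fc$eddy))
      fld <- add_eddy(fld, fc$eddy$center, fc$eddy$radius, fc$eddy$v_max)
    wind <- make_wind_series(duration_h = (fc$n_steps - 1) * fc$time_step / 3600,
                             mean_wind = config$wind$mean_wind,
                             gust_sd = config$wind$gust_sd, seed = seed)
    polys <- make_coral_polygons(fld, n = config$polygons$n,
                                 cover_range = config$polygons$cover_range,
                                 area_range = config$polygons$area_range,
                                 seed = seed + 1L)
    f <- file.path(config$out_dir, "polygons.geojson")
    write_polygons_geojson(polys, g, f); files <- c(files, f)
    f <- file.path(config$out_dir, "wind.csv")
    write_series_csv(wind, f); files <- c(files, f)
    res$fields <- list(field = fld, wind = wind, polygons = polys)
  }

  if ("slick" %in% stages) {
    sc <- config$slick
    subs <- allocate_release_polygons(
      polys, target_per_subpolygon = sc$target_per_subpolygon,
      total_budget = sc$total_budget)
    runs <- run_slick_scenario(fld, wind, subs,
                               release_start_s = sc$release_start_h * 3600,
                               drag_pcts = sc$drag_pcts,
                               duration_h = sc$duration_h, seed = seed + 2L)
    dens <- lapply(runs, slick_density, grid = fld$grid)
    for (nm in names(dens)) {
      f <- file.path(config$out_dir, paste0("density_", nm, ".asc"))
      write_ascii_grid(dens[[nm]], f); files <- c(files, f)
    }
    f <- file.path(config$out_dir, "tracks_demo.json")
    write_tracks_json(runs[[1]][[1]], f); files <- c(files, f)
    res$slick <- list(subpolygons = subs, density = dens)
  }

  if ("residency" %in% stages) {
    rc <- config$residency
    prt <- prt_survey(fld, sites = rc$sites, days = rc$day_starts_s,
                      release_hours = rc$release_hours,
                      n_particles = rc$n_particles,
                      duration_h = rc$duration_h, seed = seed + 3L)
    f <- file.path(config$out_dir, "prt_table.csv")
    utils::write.csv(prt, f, row.names = FALSE); files <- c(files, f)
    res$residency <- list(prt = prt, summary = summarize_prt(prt))
  }

  if ("validation" %in% stages) {
    vc <- config$validation
    dr <- sample_drifter(fld, vc$drifter_start, duration_h = vc$drifter_hours,
                         gps_sigma = vc$gps_sigma, seed = seed + 4L)
    ang <- seq(0, 2 * pi, length.out = 17)[-17]
    poly50 <- cbind(vc$drifter_start[1] + 50 * cos(ang),
                    vc$drifter_start[2] + 50 * sin(ang))
    cfg <- tracking_config(duration_h = vc$drifter_hours, release_depth = 1,
                           n_particles = vc$n_particles, seed = seed + 4L,
                           release_jitter = FALSE)
    seeds <- seed_particles(poly50, vc$n_particles, seed = seed + 4L,
                            field = fld)
    ens <- advect_ensemble(fld, seeds, cfg)
    cmp <- track_errors(dr, ensemble_mean_track(ens))
    f <- file.path(config$out_dir, "track_errors.csv")
    utils::write.csv(cmp, f, row.names = FALSE); files <- c(files, f)

    dur_h <- (config$field$n_steps - 1) * config$field$time_step / 3600
    obs <- sample_tiltmeter(fld, vc$tiltmeter_site, vc$tiltmeter_depth,
                            duration_h = dur_h, sample_interval = 60,
                            noise_sigma = vc$tiltmeter_noise,
                            gain = vc$tiltmeter_gain, seed = seed + 5L)
    ci <- cell_index(fld$grid, vc$tiltmeter_site[1], vc$tiltmeter_site[2])
    mod <- field_cell_series(fld, ci$i, ci$j, vc$tiltmeter_depth)
    fit <- hourly_uv_regression(mod, obs)
    cat_ <- categorize_fit(fit, wind = wind)
    f <- file.path(config$out_dir, "uv_assessment.csv")
    utils::write.csv(data.frame(site = attr(obs, "site_id"), n = fit$n,
                                r2_u = fit$r2_u, r2_v = fit$r2_v,
                                rmse_u = fit$rmse_u, rmse_v = fit$rmse_v,
                                category = cat_$category),
                     f, row.names = FALSE)
    files <- c(files, f)
    res$validation <- list(track_comparison = cmp, fit = fit,
                           category = cat_$category)
  }

  if ("slack" %in% stages) {
    kc <- config$slack
    dur_h <- (config$field$n_steps - 1) * config$field$time_step / 3600
    tm <- sample_tiltmeter(fld, kc$site, kc$depth, duration_h = dur_h,
                           sample_interval = kc$avg_interval_s,
                           seed = seed + 6L)
    scfg <- slack_config(slack_threshold = kc$threshold,
                         penalty = kc$penalty)
    cps <- segment_speed_series(tm$speed, scfg)
    ev <- extract_slack_events(tm$speed, cps, scfg, times = tm$time_s,
                               site_id = attr(tm, "site_id"))
    f <- file.path(config$out_dir, "slack_events.csv")
    utils::write.csv(ev, f, row.names = FALSE); files <- c(files, f)
    res$slack <- list(events = ev, summary = summarize_slack(ev))
  }

  cfg_file <- file.path(config$out_dir, "config.yaml")
  yaml::write_yaml(config[setdiff(names(config), "out_dir")], cfg_file)
  manifest <- list(
    name = config$name, seed = seed, stages = stages,
    config_md5 = unname(tools::md5sum(cfg_file)),
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f))),
    r_version = as.character(getRversion()),
    package_version =
      as.character(utils::packageVersion("larvaflow")))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$results <- res
  invisible(manifest)
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file with the same structure as [demo_run_config()].
#' @return Configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (nm in c("mean_flow")) if (!is.null(cfg$field[[nm]]))
    cfg$field[[nm]] <- as.numeric(cfg$field[[nm]])
  if (!is.null(cfg$field$shelter$polygon))
    cfg$field$shelter$polygon <- matrix(unlist(cfg$field$shelter$polygon),
                                        ncol = 2)
  cfg
}
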