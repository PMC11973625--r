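#' Residency analysis configuration
#'
#' @param buffer_radius Counting buffer radius around the delivery source in
#'   metres (default 200; the operational definition of "around the delivery
#'   site" used throughout).
#' @param efold_censor_h Censoring horizon for the e-folding residence time in
#'   hours (default 24, the tracking duration).
#' @param stationary_window_h Immobility window that triggers artifact removal
#'   in hours; a particle must stay put *strictly longer* than this (default 1).
#' @param stationary_eps Displacement below which a particle counts as "not
#'   moving", metres (default 1).
#' @param count_interval Counting interval in seconds (default 720; hourly
#'   series are derived from the on-the-hour steps).
#'
#' @return An object of class `residency_config`.
#' @export
residency_config <- function(buffer_radius = 200, efold_censor_h = 24,
                             stationary_window_h = 1, stationary_eps = 1,
                             count_interval = 720) {
  if (buffer_radius <= 0) stop("buffer_radius must be > 0")
  if (efold_censor_h <= 0) stop("efold_censor_h must be > 0")
  if (stationary_eps < 0) stop("stationary_eps must be >= 0")
  structure(list(buffer_radius = buffer_radius,
                 efold_censor_h = efold_censor_h,
                 stationary_window_h = stationary_window_h,
                 stationary_eps = stationary_eps,
                 count_interval = count_interval),
            class = "residency_config")
}

#' Remove particles frozen by model artifacts
#'
#' Particles whose position stays within `stationary_eps` metres of a fixed
#' point for strictly longer than `stationary_window_h` hours are marked
#' `removed_stationary` and excluded from all counting, so that every counted
#' particle was always mobile. Legitimate open-boundary freezing (status
#' `boundary_hit`) is not treated as stationary behaviour; it is handled by
#' [trim_boundary_artifacts()].
#'
#' @param ensemble A [advect_ensemble()] result.
#' @param config A [residency_config()].
#'
#' @return The ensemble with offending particles' status set to
#'   `removed_stationary` from their release onward, plus attribute
#'   `removed_count`.
#' @export
filter_stationary <- function(ensemble, config = residency_config()) {
  stopifnot(inherits(ensemble, "track_ensemble"))
  dt <- diff(ensemble$times[1:2])
  # a window strictly longer than the threshold spans this many steps + 1
  w <- floor(config$stationary_window_h * 3600 / dt) + 1L
  nT <- nrow(ensemble$x); np <- ncol(ensemble$x)
  if (nT <= w) {
    attr(ensemble, "removed_count") <- 0L
    return(ensemble)
  }
  bad <- logical(np)
  started <- outer(ensemble$times, ensemble$t_release, ">=")
  bhit <- ensemble$status == .STATUS_BOUNDARY
  eps2 <- config$stationary_eps^2
  for (a in seq_len(nT - w)) {
    span <- a:(a + w)
    # window must be fully post-release and free of boundary freezing
    elig <- started[a, ] & !colSums(bhit[span, , drop = FALSE])
    if (!any(elig & !bad)) next
    xa <- ensemble$x[a, ]; ya <- ensemble$y[a, ]
    maxd2 <- numeric(np)
    for (r in span[-1])
      maxd2 <- pmax(maxd2,
                    (ensemble$x[r, ] - xa)^2 + (ensemble$y[r, ] - ya)^2)
    bad <- bad | (elig & maxd2 < eps2)
  }
  if (any(bad)) {
    rel_step <- outer(ensemble$times, ensemble$t_release[bad], ">=")
    ensemble$status[, bad][rel_step] <- .STATUS_STATIONARY
  }
  attr(ensemble, "removed_count") <- sum(bad)
  ensemble
}

#' Count particles within a buffer of the delivery source
#'
#' Streaming count, at every stored step from release completion onward, of
#' retained particles whose Euclidean distance to `center` is at most the
#' buffer radius. Particles removed as stationary artifacts are excluded;
#' timepoints flagged by [trim_boundary_artifacts()] are dropped from the end
#' of the series.
#'
#' @param ensemble A (filtered) [advect_ensemble()] result.
#' @param center Length-2 `c(x, y)` of the delivery source in metres.
#' @param config A [residency_config()].
#'
#' @return Data frame with `step`, `time_s`, `elapsed_h` (since release
#'   completion) and `count`; attribute `hourly` holds the on-the-hour
#'   subseries.
#' @export
count_within_radius <- function(ensemble, center, config = residency_config()) {
  stopifnot(inherits(ensemble, "track_ensemble"))
  k0 <- ensemble$release_complete_step
  kmax <- nrow(ensemble$x)
  if (!is.na(ensemble$excluded_from_step))
    kmax <- min(kmax, ensemble$excluded_from_step - 1L)
  if (kmax < k0) stop("no counting steps remain after boundary trimming")
  steps <- k0:kmax
  r2 <- config$buffer_radius^2
  keep <- ensemble$status[steps, , drop = FALSE] != .STATUS_STATIONARY
  d2 <- (ensemble$x[steps, , drop = FALSE] - center[1])^2 +
    (ensemble$y[steps, , drop = FALSE] - center[2])^2
  cnt <- as.integer(rowSums(keep & d2 <= r2))
  el_h <- (ensemble$times[steps] - ensemble$times[k0]) / 3600
  out <- data.frame(step = steps, time_s = ensemble$times[steps],
                    elapsed_h = el_h, count = cnt)
  on_hour <- abs(el_h - round(el_h)) < 1e-9
  attr(out, "hourly") <- out[on_hour, ]
  out
}

#' e-folding threshold count
#'
#' The particle count defining the e-folding crossing for an initial
#' concentration `N0`: residence ends when the in-buffer count first falls
#' below `N0 / e`, i.e. below this (integer) threshold level.
#'
#' @param N0 Initial particle count.
#' @return `ceiling(N0 / e)`.
#' @export
efold_threshold_count <- function(N0) as.integer(ceiling(N0 / exp(1)))

#' e-folding particle residence time
#'
#' Time until the in-buffer particle count first drops below `1/e` of its
#' initial value. The crossing is taken at the first discrete counting step
#' with `count < N0 / e` (no sub-step interpolation: counts are integers on
#' the counting lattice). Series that never cross within the censoring
#' horizon are reported at the horizon with `censored = TRUE`.
#'
#' @param counts Data frame from [count_within_radius()] (or any data frame
#'   with `elapsed_h` and `count`).
#' @param N0 Initial count; defaults to `counts$count[1]` (must be > 0).
#' @param config A [residency_config()].
#'
#' @return List with `prt_hours`, `censored`, `N0` and `threshold`
#'   (`N0 / e`).
#' @export
efolding_prt <- function(counts, N0 = NULL, config = residency_config()) {
  stopifnot(nrow(counts) > 0)
  if (is.null(N0)) N0 <- counts$count[1]
  if (is.na(N0) || N0 <= 0) stop("N0 must be > 0")
  thr <- N0 / exp(1)
  within <- counts$elapsed_h <= config$efold_censor_h + 1e-9
  k <- which(counts$count < thr & within)
  if (length(k)) {
    list(prt_hours = counts$elapsed_h[k[1]], censored = FALSE,
         N0 = N0, threshold = thr)
  } else {
    list(prt_hours = config$efold_censor_h, censored = TRUE,
         N0 = N0, threshold = thr)
  }
}

#' Enumerate the delivery-survey scenarios
#'
#' One scenario per site, day and hourly release time; the standard survey
#' (25 sites, releases on the hour from 06:00 to 16:00 inclusive, 5 days in
#' each of 2 years) gives 25 x 11 x 10 = 2750 scenarios.
#'
#' @param site_ids Vector of site identifiers.
#' @param days Vector of day identifiers (e.g. dates).
#' @param release_hours Release hours of day (default `6:16`).
#'
#' @return Data frame with one row per scenario (`site`, `day`, `hour`).
#' @export
enumerate_scenarios <- function(site_ids, days, release_hours = 6:16) {
  out <- expand.grid(hour = release_hours, day = days, site = site_ids,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out[, c("site", "day", "hour")]
}

#' Particle residence time survey over sites, days and release hours
#'
#' Delivery-phase sweep: for every site, day and release hour, releases
#' `n_particles` at the delivery depth inside a small circular release
#' polygon, tracks them for 24 h, removes stationary artifacts, trims
#' boundary-affected timepoints, counts particles within the buffer, and
#' computes the e-folding residence time.
#'
#' @param field A [current_field()] spanning every release plus 24 h.
#' @param sites Named list of site centres (`c(x, y)` metres) or a data frame
#'   with columns `site`, `x`, `y`.
#' @param days Data frame or vector of day start offsets in seconds on the
#'   field time axis (named, or a numeric vector; names become day labels).
#' @param release_hours Hours of day for releases (default `6:16`).
#' @param site_radius Radius of the circular release polygon, metres
#'   (default 25).
#' @param n_particles Particles per release (default 5000).
#' @param duration_h Tracking duration (default 24).
#' @param release_depth Delivery depth in metres (default 3.6).
#' @param config A [residency_config()].
#' @param seed Master seed; per-scenario sub-seeds are derived from it.
#' @param release_jitter Spread release times within the release hour.
#'
#' @return Data frame of class `prt_table` with one row per scenario: `site`,
#'   `day`, `hour`, `N0`, `prt_hours`, `censored`, `removed_stationary`,
#'   `boundary_trimmed`.
#' @export
prt_survey <- function(field, sites, days, release_hours = 6:16,
                       site_radius = 25, n_particles = 5000,
                       duration_h = 24, release_depth = 3.6,
                       config = residency_config(), seed = 1L,
                       release_jitter = TRUE) {
  if (is.data.frame(sites))
    sites <- stats::setNames(
      lapply(seq_len(nrow(sites)), function(k) c(sites$x[k], sites$y[k])),
      sites$site)
  if (is.null(names(days))) names(days) <- paste0("day", seq_along(days))
  scen <- enumerate_scenarios(names(sites), names(days), release_hours)
  n <- nrow(scen)
  res <- data.frame(scen, N0 = NA_integer_, prt_hours = NA_real_,
                    censored = NA, removed_stationary = NA_integer_,
                    boundary_trimmed = NA_integer_)
  ang <- seq(0, 2 * pi, length.out = 17)[-17]
  for (k in seq_len(n)) {
    ctr <- sites[[scen$site[k]]]
    poly <- cbind(ctr[1] + site_radius * cos(ang),
                  ctr[2] + site_radius * sin(ang))
    t_start <- days[[scen$day[k]]] + scen$hour[k] * 3600
    win <- c(t_start, if (release_jitter) t_start + 3600 else t_start)
    sub_seed <- (seed * 1000003L + k * 2147L) %% .Machine$integer.max
    cfg <- tracking_config(duration_h = duration_h,
                           release_depth = release_depth,
                           n_particles = n_particles, seed = sub_seed,
                           release_jitter = release_jitter)
    seeds <- seed_particles(poly, n_particles, release_window = win,
                            seed = sub_seed, field = field)
    ens <- advect_ensemble(field, seeds, cfg)
    ens <- filter_stationary(ens, config)
    ens <- trim_boundary_artifacts(ens)
    cnt <- count_within_radius(ens, ctr, config)
    prt <- efolding_prt(cnt, config = config)
    res$N0[k] <- cnt$count[1]
    res$prt_hours[k] <- prt$prt_hours
    res$censored[k] <- prt$censored
    res$removed_stationary[k] <- attr(ens, "removed_count")
    res$boundary_trimmed[k] <- attr(ens, "trim_report")$n_affected
  }
  class(res) <- c("prt_table", "data.frame")
  res
}

#' Summarize a PRT survey per site
#'
#' @param prt A [prt_survey()] result.
#' @return Data frame per site: scenario count, max and median PRT, number of
#'   censored scenarios and of scenarios with PRT of at least 5 h (the usual
#'   "long retention" benchmark).
#' @export
summarize_prt <- function(prt) {
  sp <- split(prt, prt$site)
  out <- do.call(rbind, lapply(names(sp), function(s) {
    d <- sp[[s]]
    data.frame(site = s, n = nrow(d),
               max_prt_h = max(d$prt_hours),
               median_prt_h = stats::median(d$prt_hours),
               n_censored = sum(d$censored),
               n_ge_5h = sum(d$prt_hours >= 5))
  }))
  rownames(out) <- NULL
  out
}
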