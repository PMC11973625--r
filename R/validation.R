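#' Signed circular difference in degrees
#'
#' `a - b` wrapped to `(-180, 180]`; used for bearing errors.
#' @param a,b Angles in degrees.
#' @return Difference in `(-180, 180]`.
#' @export
circular_diff <- function(a, b) {
  d <- ((a - b + 180) %% 360) - 180
  d[d == -180] <- 180
  d
}

#' Mean (centroid) track of a particle ensemble
#'
#' Per-step centroid of the positions of particles still active at that step,
#' the modelled counterpart compared against an observed drifter track.
#'
#' @param ensemble A [advect_ensemble()] result.
#' @return Data frame with `time_s`, `x`, `y`, `n_active`.
#' @export
ensemble_mean_track <- function(ensemble) {
  stopifnot(inherits(ensemble, "track_ensemble"))
  act <- ensemble$status == .STATUS_ACTIVE
  n <- rowSums(act)
  if (any(n == 0))
    stop("ensemble has steps with no active particle")
  data.frame(time_s = ensemble$times,
             x = rowSums(ensemble$x * act) / n,
             y = rowSums(ensemble$y * act) / n,
             n_active = n)
}

#' Hourly errors between an observed and a modelled track
#'
#' At every whole hour of the overlapping span (from one hour after its
#' start), both tracks are linearly interpolated to the hour and compared:
#' `distance_error` is the planar separation, `direction_error` the signed
#' circular difference (modelled minus observed) of the displacement bearings
#' over the trailing hour, and `speed_error` the modelled minus observed mean
#' speed over that trailing hour.
#'
#' @param observed A [sample_drifter()] track or data frame with `time_s`,
#'   `x`, `y`.
#' @param mean_track Modelled track data frame (`time_s`, `x`, `y`), e.g.
#'   from [ensemble_mean_track()].
#'
#' @return Data frame of class `track_comparison` with `time_s`,
#'   `distance_error` (m), `direction_error` (degrees in `(-180, 180]`) and
#'   `speed_error` (m/s); attribute `medians` holds the per-run medians.
#' @export
track_errors <- function(observed, mean_track) {
  t0 <- max(min(observed$time_s), min(mean_track$time_s))
  t1 <- min(max(observed$time_s), max(mean_track$time_s))
  if (t1 - t0 < 3600) stop("tracks must overlap by at least one hour")
  hours <- seq(ceiling(t0 / 3600) * 3600 + 3600, t1, by = 3600)
  if (!length(hours)) stop("tracks must overlap by at least one hour")
  ip <- function(tr, tt)
    list(x = stats::approx(tr$time_s, tr$x, xout = tt)$y,
         y = stats::approx(tr$time_s, tr$y, xout = tt)$y)
  o1 <- ip(observed, hours); o0 <- ip(observed, hours - 3600)
  m1 <- ip(mean_track, hours); m0 <- ip(mean_track, hours - 3600)
  bear <- function(p0, p1) (atan2(p1$x - p0$x, p1$y - p0$y) * 180 / pi) %% 360
  spd <- function(p0, p1) sqrt((p1$x - p0$x)^2 + (p1$y - p0$y)^2) / 3600
  out <- data.frame(
    time_s = hours,
    distance_error = sqrt((m1$x - o1$x)^2 + (m1$y - o1$y)^2),
    direction_error = circular_diff(bear(m0, m1), bear(o0, o1)),
    speed_error = spd(m0, m1) - spd(o0, o1))
  attr(out, "medians") <- list(
    distance = stats::median(out$distance_error),
    direction = stats::median(out$direction_error),
    speed = stats::median(out$speed_error))
  class(out) <- c("track_comparison", "data.frame")
  out
}

# coerce a (time_s, speed, heading) or (time_s, u, v) frame to u,v
.as_uv <- function(series) {
  if (all(c("u", "v") %in% names(series)))
    return(data.frame(time_s = series$time_s, u = series$u, v = series$v))
  uv <- heading_to_uv(series$speed, series$heading)
  data.frame(time_s = series$time_s, u = uv$u, v = uv$v)
}

#' Hourly u/v regression of modelled against observed currents
#'
#' Decomposes both series into u,v, averages them on aligned left-labelled
#' hourly bins `[t, t + 1h)`, and computes the squared Pearson correlation and
#' the RMSE of the raw aligned hourly values per component. The RMSE is
#' deliberately computed on paired values, not regression residuals, so
#' constant biases and amplitude errors remain visible. The observed series'
#' principal current axis is also estimated and both series rotated onto it,
#' yielding dominant-component metrics used for fit categorisation.
#'
#' @param modeled,observed Data frames with `time_s` plus either `u`,`v` or
#'   `speed`,`heading` (e.g. a [sample_tiltmeter()] series).
#' @param min_overlap Minimum number of aligned hourly bins (default 24).
#'
#' @return Object of class `fit_assessment`: list with `n`, `r2_u`, `r2_v`,
#'   `rmse_u`, `rmse_v`, observed SDs, principal-axis heading
#'   (`axis_deg`), dominant/secondary rotated metrics (`r2_dom`, `rmse_dom`,
#'   `sd_dom`, `r2_sec`), and the aligned hourly series (`hourly`).
#' @export
hourly_uv_regression <- function(modeled, observed, min_overlap = 24) {
  m <- .as_uv(modeled); o <- .as_uv(observed)
  hb <- function(d) {
    bin <- floor(d$time_s / 3600)
    agg <- stats::aggregate(d[, c("u", "v")], list(bin = bin), mean)
    agg
  }
  ma <- hb(m); oa <- hb(o)
  j <- merge(ma, oa, by = "bin", suffixes = c("_m", "_o"))
  if (nrow(j) < min_overlap)
    stop("need at least ", min_overlap, " overlapping hourly bins, got ",
         nrow(j))
  r2 <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
    stats::cor(a, b)^2
  }
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  # principal current axis of the observed series
  ev <- eigen(stats::cov(cbind(j$u_o, j$v_o)), symmetric = TRUE)
  ax <- ev$vectors[, 1]
  axis_deg <- (atan2(ax[1], ax[2]) * 180 / pi) %% 180
  rot <- function(u, v) list(dom = u * ax[1] + v * ax[2],
                             sec = -u * ax[2] + v * ax[1])
  rm_ <- rot(j$u_m, j$v_m); ro <- rot(j$u_o, j$v_o)
  structure(list(
    n = nrow(j),
    r2_u = r2(j$u_m, j$u_o), r2_v = r2(j$v_m, j$v_o),
    rmse_u = rmse(j$u_m, j$u_o), rmse_v = rmse(j$v_m, j$v_o),
    sd_u = stats::sd(j$u_o), sd_v = stats::sd(j$v_o),
    axis_deg = axis_deg,
    r2_dom = r2(rm_$dom, ro$dom), r2_sec = r2(rm_$sec, ro$sec),
    rmse_dom = rmse(rm_$dom, ro$dom), sd_dom = stats::sd(ro$dom),
    hourly = data.frame(bin = j$bin, dom_m = rm_$dom, dom_o = ro$dom,
                        sec_m = rm_$sec, sec_o = ro$sec)),
    class = "fit_assessment")
}

#' @export
print.fit_assessment <- function(x, ...) {
  cat(sprintf(paste0("<fit_assessment> n=%d  R2_u=%.3f R2_v=%.3f  ",
                     "RMSE_u=%.3f RMSE_v=%.3f  axis=%.0f deg R2_dom=%.3f\n"),
              x$n, x$r2_u, x$r2_v, x$rmse_u, x$rmse_v, x$axis_deg, x$r2_dom))
  invisible(x)
}

#' Ordered ranks of the fit categories
#' @return Named integer vector, worst (1) to best (5).
#' @export
fit_category_rank <- function() {
  c(no_fit = 1L, poor = 2L, good_wind = 3L, good = 4L, very_good = 5L)
}

# best r2 on the dominant component over integer-hour lags of the modelled
# series, within +/- max_lag_h
.lag_scan <- function(hourly, max_lag_h) {
  best <- 0; best_lag <- 0L
  for (lag in setdiff(seq(-max_lag_h, max_lag_h), 0L)) {
    a <- merge(data.frame(bin = hourly$bin + lag, dom_m = hourly$dom_m),
               hourly[, c("bin", "dom_o")], by = "bin")
    if (nrow(a) < 12 || stats::sd(a$dom_m) == 0 || stats::sd(a$dom_o) == 0) next
    r2 <- stats::cor(a$dom_m, a$dom_o)^2
    if (r2 > best) { best <- r2; best_lag <- lag }
  }
  list(r2 = best, lag = best_lag)
}

# harmonic fit at the tidal period: fitted series, amplitude, and the share
# of the series variance the harmonic explains
.tidal_harmonic <- function(bin, x, period_h = 12.42) {
  w <- 2 * pi * bin / period_h
  f <- stats::lm(x ~ sin(w) + cos(w))
  co <- stats::coef(f)
  vx <- stats::var(x)
  list(fitted = stats::fitted(f),
       amplitude = sqrt(co[2]^2 + co[3]^2),
       r2 = if (vx > 0) stats::var(stats::fitted(f)) / vx else 0)
}

#' Categorize a model-vs-observation fit
#'
#' Explicit rule set standing in for the expert visual judgement behind the
#' usual four fit groups, applied after rotation onto the observed principal
#' current axis:
#' \itemize{
#'   \item `very_good`: dominant-component R-squared above `r2_high` and
#'     dominant RMSE below the observed dominant-component SD -- the model
#'     captures the main ebb/flood signal at the right amplitude (a site
#'     whose misfit is confined to the weak cross-axis component still
#'     qualifies).
#'   \item `good`: moderate dominant R-squared (`r2_low`--`r2_high`), or the
#'     secondary component fits well, or the dominant component fits well
#'     only after a tidal lag correction of at most `max_lag_h` hours (flag
#'     `lag_detected`).
#'   \item `good_wind`: the `good` criterion holds only on a
#'     wind-direction-conditioned subset of hours (flag `wind_conditional`;
#'     requires `wind`).
#'   \item `poor`: coherent tidal-band signal but the modelled amplitude is
#'     off by more than a factor `amp_factor` -- understandable but not
#'     correctable.
#'   \item `no_fit`: none of the above.
#' }
#'
#' @param assessment A [hourly_uv_regression()] result, or a list with at
#'   least `r2_u` and `r2_v` (tabulated metrics; rotation diagnostics are then
#'   unavailable and the dominant component is taken from `dominant`).
#' @param wind Optional wind series (`time_s`, `wind_u`, `wind_v`) enabling
#'   the wind-conditioned check.
#' @param dominant Optional `"u"` or `"v"` naming the dominant flow component
#'   when `assessment` carries no principal-axis information.
#' @param r2_high,r2_low R-squared thresholds (defaults 0.4, 0.2).
#' @param max_lag_h Maximum tidal lag correction in hours (default 2).
#' @param amp_factor Amplitude-error factor defining `poor` (default 2).
#'
#' @return List with `category` (factor level name), logical flags
#'   (`lag_detected`, `wind_conditional`) and the diagnostics used.
#' @export
categorize_fit <- function(assessment, wind = NULL, dominant = NULL,
                           r2_high = 0.4, r2_low = 0.2, max_lag_h = 2,
                           amp_factor = 2) {
  full <- inherits(assessment, "fit_assessment")
  if (full) {
    r2_dom <- assessment$r2_dom; r2_sec <- assessment$r2_sec
    rmse_ok <- assessment$rmse_dom < assessment$sd_dom
  } else {
    if (is.null(dominant))
      dominant <- if (assessment$r2_u >= assessment$r2_v) "u" else "v"
    r2_dom <- if (dominant == "u") assessment$r2_u else assessment$r2_v
    r2_sec <- if (dominant == "u") assessment$r2_v else assessment$r2_u
    rmse_ok <- TRUE   # amplitude diagnostics unavailable for tabulated input
  }
  lag <- list(r2 = 0, lag = 0L)
  tidal <- list(corr = 0, amp_ratio = NA_real_, obs_r2 = 0)
  wind_r2 <- 0
  if (full) {
    h <- assessment$hourly
    lag <- .lag_scan(h, max_lag_h)
    if (stats::sd(h$dom_o) > 0 && stats::sd(h$dom_m) > 0) {
      fm <- .tidal_harmonic(h$bin, h$dom_m)
      fo <- .tidal_harmonic(h$bin, h$dom_o)
      if (stats::sd(fm$fitted) > 0 && stats::sd(fo$fitted) > 0)
        tidal$corr <- stats::cor(fm$fitted, fo$fitted)
      if (fo$amplitude > 0) tidal$amp_ratio <- fm$amplitude / fo$amplitude
      tidal$obs_r2 <- fo$r2
    }
    if (!is.null(wind)) {
      wv <- stats::approx(wind$time_s, wind$wind_v, xout = h$bin * 3600,
                          rule = 2)$y
      for (sel in list(wv >= 0, wv < 0)) {
        if (sum(sel) >= 12 && stats::sd(h$dom_m[sel]) > 0 &&
            stats::sd(h$dom_o[sel]) > 0)
          wind_r2 <- max(wind_r2,
                         stats::cor(h$dom_m[sel], h$dom_o[sel])^2)
      }
    }
  }
  lag_detected <- r2_dom <= r2_high && lag$r2 > r2_high
  very_good <- r2_dom > r2_high && rmse_ok
  # amplitude misfit with a coherent tidal signal caps the category at poor:
  # the error is understood but cannot be compensated, however good R2 looks
  amp_off <- !is.na(tidal$amp_ratio) &&
    (tidal$amp_ratio > amp_factor || tidal$amp_ratio < 1 / amp_factor)
  # a tidal signal must be present in the observations themselves, or an
  # amplitude ratio computed on noise would outrank an honest no_fit
  poor <- !very_good && amp_off && tidal$corr > r2_high &&
    tidal$obs_r2 > r2_low
  good <- !very_good && !poor &&
    ((r2_dom > r2_low && r2_dom <= r2_high) || r2_sec > r2_high || lag_detected)
  good_wind <- !very_good && !poor && !good && wind_r2 > r2_high
  category <- if (very_good) "very_good" else if (poor) "poor" else
    if (good) "good" else if (good_wind) "good_wind" else "no_fit"
  list(category = category,
       lag_detected = lag_detected, wind_conditional = good_wind,
       r2_dom = r2_dom, r2_sec = r2_sec,
       lag_r2 = lag$r2, lag_h = lag$lag,
       tidal_corr = tidal$corr, amp_ratio = tidal$amp_ratio,
       tidal_obs_r2 = tidal$obs_r2)
}
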