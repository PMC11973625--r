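#' Slack-current detection configuration
#'
#' @param slack_threshold Mean-speed threshold in m/s under which a segment
#'   counts as slack current (default 0.022).
#' @param penalty Changepoint penalty in units of the normalised Gaussian
#'   cost; `NULL` (default) uses an MBIC-style `3 * log(n)`. Larger penalties
#'   give fewer, longer segments.
#' @param min_segment Minimum segment length in samples (default 2).
#' @param merge_adjacent Merge qualifying segments separated only by a
#'   changepoint boundary into one event (default `TRUE`).
#' @param cost Segment cost: `"mean"` (Gaussian mean-shift, pooled variance)
#'   or `"meanvar"` (Gaussian mean and variance change).
#'
#' @return An object of class `slack_config`.
#' @export
slack_config <- function(slack_threshold = 0.022, penalty = NULL,
                         min_segment = 2L, merge_adjacent = TRUE,
                         cost = c("mean", "meanvar")) {
  if (slack_threshold <= 0) stop("slack_threshold must be > 0")
  if (!is.null(penalty) && penalty <= 0) stop("penalty must be > 0")
  structure(list(slack_threshold = slack_threshold, penalty = penalty,
                 min_segment = as.integer(min_segment),
                 merge_adjacent = merge_adjacent,
                 cost = match.arg(cost)),
            class = "slack_config")
}

# robust noise variance from lag-1 differences (invariant to level shifts)
.noise_var <- function(x) {
  s <- stats::mad(diff(x)) / sqrt(2)
  if (s == 0) s <- stats::sd(x)
  if (is.na(s) || s == 0) s <- 1
  s^2
}

#' Penalized optimal segmentation of a speed series
#'
#' Exact penalized changepoint detection by optimal partitioning with PELT
#' pruning: minimises the sum of per-segment Gaussian costs plus `penalty`
#' per changepoint. The default cost is a mean-shift cost (residual sum of
#' squares around the segment mean, normalised by a robust pooled noise
#' variance estimated from first differences); `"meanvar"` uses the Gaussian
#' likelihood cost sensitive to both mean and variance changes. The pruning
#' never discards an optimal candidate, so the result equals exhaustive
#' dynamic programming at a fraction of the cost.
#'
#' @param speeds Numeric vector, typically 1-min averaged current speeds.
#' @param config A [slack_config()].
#'
#' @return Integer vector of changepoint positions: the index of the last
#'   sample of each segment except the final one (empty when the optimal
#'   segmentation is a single segment).
#' @export
segment_speed_series <- function(speeds, config = slack_config()) {
  x <- as.numeric(speeds)
  n <- length(x)
  minseg <- config$min_segment
  if (n <= 2L * minseg)
    stop("series must be longer than 2 * min_segment samples")
  beta <- if (is.null(config$penalty)) 3 * log(n) else config$penalty

  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
  if (config$cost == "mean") {
    s2 <- .noise_var(x)
    segcost <- function(a, b) {   # vectorised over a
      nn <- b - a + 1
      sx <- cs[b + 1] - cs[a]
      ((cs2[b + 1] - cs2[a]) - sx^2 / nn) / s2
    }
  } else {
    segcost <- function(a, b) {
      nn <- b - a + 1
      sx <- cs[b + 1] - cs[a]
      rss <- (cs2[b + 1] - cs2[a]) - sx^2 / nn
      sig <- pmax(rss / nn, 1e-12)
      nn * (log(2 * pi * sig) + 1)
    }
  }

  FF <- rep(Inf, n + 1)   # FF[t + 1] = optimal cost of x[1..t]
  FF[1] <- -beta
  prev <- integer(n)
  cand <- 0L
  # a candidate dominated at time t0 may still be required while the
  # dominating point is itself too recent to start a full segment; it is
  # provably safe to discard it only from t0 + min_segment onward
  prune_at <- Inf
  for (t in seq_len(n)) {
    drop <- t >= prune_at + minseg
    if (any(drop)) { cand <- cand[!drop]; prune_at <- prune_at[!drop] }
    ok <- t - cand >= minseg
    allowed <- cand[ok]
    if (!length(allowed)) { cand <- c(cand, t); prune_at <- c(prune_at, Inf); next }
    vals <- FF[allowed + 1L] + segcost(allowed + 1L, t) + beta
    j <- which.min(vals)
    FF[t + 1L] <- vals[j]
    prev[t] <- allowed[j]
    newly <- ok
    newly[ok] <- vals - beta > FF[t + 1L]
    prune_at[newly & !is.finite(prune_at)] <- t
    cand <- c(cand, t); prune_at <- c(prune_at, Inf)
  }
  if (!is.finite(FF[n + 1L]))
    stop("no valid segmentation: series shorter than 2 * min_segment?")
  cps <- integer(0)
  t <- n
  while (t > 0L) {
    s <- prev[t]
    if (s > 0L) cps <- c(s, cps)
    t <- s
  }
  cps
}

#' Extract slack-current events from a segmented speed series
#'
#' Segments whose mean speed is below the slack threshold become events;
#' adjacent qualifying segments are merged when configured. Each event
#' carries its start/end time, duration and the mean and SD of the speeds it
#' covers.
#'
#' @param speeds Numeric speed vector (m/s).
#' @param boundaries Changepoints from [segment_speed_series()].
#' @param config A [slack_config()].
#' @param times Sample times in seconds (default a 1-min lattice).
#' @param site_id Identifier attached to the events.
#'
#' @return Data frame with `site_id`, `start_idx`, `end_idx`, `start_s`,
#'   `end_s`, `duration_min`, `mean_speed`, `sd_speed` (zero rows when
#'   nothing qualifies).
#' @export
extract_slack_events <- function(speeds, boundaries,
                                 config = slack_config(),
                                 times = NULL, site_id = "site") {
  n <- length(speeds)
  if (is.null(times)) times <- (seq_len(n) - 1) * 60
  dt <- if (n > 1) times[2] - times[1] else 60
  starts <- c(1L, boundaries + 1L)
  ends <- c(boundaries, n)
  means <- vapply(seq_along(starts),
                  function(k) mean(speeds[starts[k]:ends[k]]), numeric(1))
  ok <- means < config$slack_threshold
  ev <- data.frame(start_idx = integer(0), end_idx = integer(0))
  k <- 1L
  while (k <= length(starts)) {
    if (ok[k]) {
      e <- k
      if (config$merge_adjacent)
        while (e + 1L <= length(starts) && ok[e + 1L]) e <- e + 1L
      ev <- rbind(ev, data.frame(start_idx = starts[k], end_idx = ends[e]))
      k <- e + 1L
    } else k <- k + 1L
  }
  if (!nrow(ev))
    return(data.frame(site_id = character(0), start_idx = integer(0),
                      end_idx = integer(0), start_s = numeric(0),
                      end_s = numeric(0), duration_min = numeric(0),
                      mean_speed = numeric(0), sd_speed = numeric(0)))
  data.frame(
    site_id = site_id,
    start_idx = ev$start_idx, end_idx = ev$end_idx,
    start_s = times[ev$start_idx], end_s = times[ev$end_idx],
    duration_min = (ev$end_idx - ev$start_idx + 1L) * dt / 60,
    mean_speed = vapply(seq_len(nrow(ev)), function(k)
      mean(speeds[ev$start_idx[k]:ev$end_idx[k]]), numeric(1)),
    sd_speed = vapply(seq_len(nrow(ev)), function(k)
      stats::sd(speeds[ev$start_idx[k]:ev$end_idx[k]]), numeric(1)))
}

#' Summarize slack events per site
#'
#' @param events Data frame from [extract_slack_events()] (rows from several
#'   sites may be concatenated).
#' @param bin_width_min Histogram bin width in minutes (default 30).
#'
#' @return List with `per_site` (site, count, mean/min/max duration) and
#'   `histogram` (pooled duration frequency table: `bin_start_min`,
#'   `bin_end_min`, `count`).
#' @export
summarize_slack <- function(events, bin_width_min = 30) {
  if (!nrow(events)) {
    return(list(per_site = data.frame(site_id = character(0), count = integer(0),
                                      mean_duration_min = numeric(0),
                                      min_duration_min = numeric(0),
                                      max_duration_min = numeric(0)),
                histogram = data.frame(bin_start_min = numeric(0),
                                       bin_end_min = numeric(0),
                                       count = integer(0))))
  }
  sp <- split(events, events$site_id)
  per_site <- do.call(rbind, lapply(names(sp), function(s) {
    d <- sp[[s]]
    data.frame(site_id = s, count = nrow(d),
               mean_duration_min = mean(d$duration_min),
               min_duration_min = min(d$duration_min),
               max_duration_min = max(d$duration_min))
  }))
  rownames(per_site) <- NULL
  brk <- seq(0, (max(events$duration_min) %/% bin_width_min + 1) * bin_width_min,
             by = bin_width_min)
  h <- hist(events$duration_min, breaks = brk, plot = FALSE)
  list(per_site = per_site,
       histogram = data.frame(bin_start_min = utils::head(brk, -1),
                              bin_end_min = brk[-1], count = h$counts))
}

#' Tide-timing alignment table for slack events
#'
#' Pairs each slack event midpoint with the nearest provided high/low tide
#' time; emitted for descriptive plotting only (tide timing is typically a
#' poor predictor of slack conditions on sheltered reefs).
#'
#' @param events Data frame from [extract_slack_events()].
#' @param tide_times_s Numeric vector of high/low tide times in seconds.
#' @return The events with `nearest_tide_s` and `offset_min` columns added.
#' @export
slack_tide_alignment <- function(events, tide_times_s) {
  if (!nrow(events)) {
    events$nearest_tide_s <- numeric(0); events$offset_min <- numeric(0)
    return(events)
  }
  mid <- (events$start_s + events$end_s) / 2
  nearest <- vapply(mid, function(m)
    tide_times_s[which.min(abs(tide_times_s - m))], numeric(1))
  events$nearest_tide_s <- nearest
  events$offset_min <- (mid - nearest) / 60
  events
}
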