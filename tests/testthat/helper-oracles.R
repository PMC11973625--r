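# Independent oracles used by the test suite. These deliberately share no
# code with the package implementation they check.

# Exhaustive O(n^2) penalized optimal partitioning with the same objective
# definition as segment_speed_series (Gaussian mean-shift cost normalised by
# a robust noise variance), computed by plain dynamic programming without any
# pruning or cumulative-sum tricks.
oracle_changepoints <- function(x, penalty = NULL, min_segment = 2L) {
  n <- length(x)
  beta <- if (is.null(penalty)) 3 * log(n) else penalty
  s <- stats::mad(diff(x)) / sqrt(2)
  if (s == 0) s <- stats::sd(x)
  if (is.na(s) || s == 0) s <- 1
  s2 <- s^2
  segcost <- function(a, b) {
    seg <- x[a:b]
    sum((seg - mean(seg))^2) / s2
  }
  FF <- rep(Inf, n + 1)
  FF[1] <- -beta
  prev <- integer(n)
  for (t in seq_len(n)) {
    if (t < min_segment) next
    for (ss in 0:(t - min_segment)) {
      if (ss > 0 && !is.finite(FF[ss + 1])) next
      val <- FF[ss + 1] + segcost(ss + 1, t) + beta
      if (val < FF[t + 1]) { FF[t + 1] <- val; prev[t] <- ss }
    }
  }
  cps <- integer(0)
  t <- n
  while (t > 0) {
    if (prev[t] > 0) cps <- c(prev[t], cps)
    t <- prev[t]
  }
  cps
}

# Brute-force in-buffer count: plain double loop over particles and steps.
oracle_buffer_counts <- function(ensemble, center, radius) {
  steps <- ensemble$release_complete_step:nrow(ensemble$x)
  out <- integer(length(steps))
  for (si in seq_along(steps)) {
    k <- steps[si]
    c0 <- 0L
    for (p in seq_len(ncol(ensemble$x))) {
      if (ensemble$status[k, p] == 2L) next   # removed_stationary
      d <- sqrt((ensemble$x[k, p] - center[1])^2 +
                  (ensemble$y[k, p] - center[2])^2)
      if (d <= radius) c0 <- c0 + 1L
    }
    out[si] <- c0
  }
  out
}

# Forward-Euler single-particle integrator on a current field (for the
# integrator-quality ordering check).
oracle_euler_track <- function(field, start, depth, dt, n_steps) {
  x <- numeric(n_steps + 1); y <- numeric(n_steps + 1)
  x[1] <- start[1]; y[1] <- start[2]
  for (k in seq_len(n_steps)) {
    uv <- interpolate_velocity(field, x[k], y[k], depth, (k - 1) * dt)
    x[k + 1] <- x[k] + dt * uv$u
    y[k + 1] <- y[k] + dt * uv$v
  }
  data.frame(x = x, y = y)
}
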