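#' Tracking configuration
#'
#' Parameters for one advection run. Defaults mirror standard reef-scale
#' dispersal practice: a 12-min integration step, 5000 particles per release,
#' particles bound to their release depth, and optional surface windage given
#' as a percentage of the wind speed (0 for subsurface larvae, 3 for buoyant
#' spawn at the surface).
#'
#' @param duration_h Tracking duration per particle in hours (> 0).
#' @param release_depth Depth particles are bound to, in metres.
#' @param dt Integration step in seconds (default 720).
#' @param wind_drag_pct Windage as a percentage of wind speed (>= 0). Windage
#'   is a surface process; combining `wind_drag_pct > 0` with
#'   `release_depth > 2` m is refused because wind exerts little direct drag
#'   below the surface layer.
#' @param n_particles Particles per release (default 5000).
#' @param seed Integer seed controlling particle seeding (and release jitter).
#' @param release_jitter If `TRUE` (default), release times are drawn uniformly
#'   within the release window, emulating releases spread over the hour;
#'   `FALSE` releases every particle at the window start (deterministic runs).
#'
#' @return An object of class `tracking_config`.
#' @export
tracking_config <- function(duration_h, release_depth, dt = 720,
                            wind_drag_pct = 0, n_particles = 5000,
                            seed = 1L, release_jitter = TRUE) {
  if (dt <= 0) stop("dt must be > 0")
  if (duration_h <= 0) stop("duration_h must be > 0")
  if (wind_drag_pct < 0) stop("wind_drag_pct must be >= 0")
  if (n_particles < 1) stop("n_particles must be >= 1")
  if (wind_drag_pct > 0 && release_depth > 2)
    stop("windage (wind_drag_pct > 0) is only supported for surface releases ",
         "(release_depth <= 2 m)")
  structure(list(dt = dt, duration_h = duration_h,
                 release_depth = release_depth,
                 wind_drag_pct = wind_drag_pct,
                 n_particles = as.integer(n_particles),
                 seed = as.integer(seed), release_jitter = release_jitter),
            class = "tracking_config")
}

# particle status codes used in track ensembles
.STATUS_ACTIVE <- 0L
.STATUS_BOUNDARY <- 1L
.STATUS_STATIONARY <- 2L

# Core vectorised velocity sampler. x, y: positions (m); d_idx: depth layer
# index (scalar); time: scalar seconds. Bilinear over the 4 surrounding cell
# centres with water-only weight renormalisation, linear in time.
# Returns u, v and an integer status per position: 0 ok, 1 boundary (outside
# the grid extent or inside an open-boundary cell), 2 land-locked (all four
# neighbouring cells are land; u,v are 0 there).
.interp_uv <- function(field, x, y, d_idx, time) {
  g <- field$grid
  n <- length(x)
  nT <- g$n_steps; nD <- length(g$depth_layers); nY <- g$ny; nX <- g$nx
  cs <- g$cell_size

  status <- integer(n)
  out <- !is.finite(x) | !is.finite(y) |
    x < 0 | y < 0 | x >= nX * cs | y >= nY * cs
  status[out] <- .STATUS_BOUNDARY

  # containing cell: open-boundary cells signal boundary
  ic <- pmin(pmax(floor(x / cs) + 1, 1), nX)
  jc <- pmin(pmax(floor(y / cs) + 1, 1), nY)
  ic[out] <- 1L; jc[out] <- 1L
  inb <- !out & field$mask[cbind(jc, ic)] == 2L
  status[inb] <- .STATUS_BOUNDARY

  # neighbouring cell centres
  gx <- x / cs - 0.5; gy <- y / cs - 0.5
  i0 <- floor(gx) + 1; j0 <- floor(gy) + 1
  fx <- gx - (i0 - 1); fy <- gy - (j0 - 1)
  cl <- i0 < 1; i0[cl] <- 1; fx[cl] <- 0
  ch <- i0 >= nX; i0[ch] <- nX - 1; fx[ch] <- 1
  cl <- j0 < 1; j0[cl] <- 1; fy[cl] <- 0
  ch <- j0 >= nY; j0[ch] <- nY - 1; fy[ch] <- 1
  i0[out] <- 1L; j0[out] <- 1L; fx[out] <- 0; fy[out] <- 0
  i1 <- i0 + 1; j1 <- j0 + 1

  # water-only weights (open-boundary cells carry velocities and interpolate)
  land <- field$mask == 1L
  a11 <- 1 - land[cbind(j0, i0)]; a21 <- 1 - land[cbind(j0, i1)]
  a12 <- 1 - land[cbind(j1, i0)]; a22 <- 1 - land[cbind(j1, i1)]
  w11 <- (1 - fx) * (1 - fy) * a11; w21 <- fx * (1 - fy) * a21
  w12 <- (1 - fx) * fy * a12;       w22 <- fx * fy * a22
  wt <- w11 + w21 + w12 + w22
  locked <- !out & !inb & (a11 + a21 + a12 + a22) == 0
  status[locked] <- .STATUS_STATIONARY
  wt[wt == 0] <- 1

  # time bracketing
  ft <- time / g$time_step
  k0 <- min(max(floor(ft) + 1, 1), max(nT - 1, 1))
  at <- if (nT > 1) min(max(ft - (k0 - 1), 0), 1) else 0
  k1 <- min(k0 + 1, nT)

  strideD <- nT; strideY <- nT * nD; strideX <- nT * nD * nY
  base0 <- k0 + strideD * (d_idx - 1)
  gather <- function(arr, kbase, jj, ii) {
    arr[kbase + strideY * (jj - 1) + strideX * (ii - 1)]
  }
  bl <- function(arr, kbase) {
    (w11 * gather(arr, kbase, j0, i0) + w21 * gather(arr, kbase, j0, i1) +
     w12 * gather(arr, kbase, j1, i0) + w22 * gather(arr, kbase, j1, i1)) / wt
  }
  u <- (1 - at) * bl(field$u, base0) + at * bl(field$u, base0 + 1 * (k1 > k0))
  v <- (1 - at) * bl(field$v, base0) + at * bl(field$v, base0 + 1 * (k1 > k0))
  u[status != 0L] <- 0; v[status != 0L] <- 0
  u[locked] <- 0; v[locked] <- 0
  list(u = u, v = v, status = status)
}

#' Interpolate the current velocity at arbitrary positions and times
#'
#' Bilinear interpolation in space over the four surrounding cell centres
#' (land cells are excluded from the stencil and the weights renormalised over
#' water cells), nearest stored depth layer, linear interpolation in time.
#'
#' @param field A [current_field()].
#' @param x,y Positions in metres (vectors of equal length).
#' @param depth Depth in metres (nearest stored layer is used).
#' @param time Time in seconds since field start (scalar, or vector matching
#'   `x`).
#'
#' @return A data frame with `u`, `v` (m/s) and `status` (`"ok"`,
#'   `"boundary"` for positions outside the domain or in an open-boundary
#'   cell, `"land"` where all four neighbouring cells are land).
#' @export
interpolate_velocity <- function(field, x, y, depth, time) {
  d_idx <- which.min(abs(field$grid$depth_layers - depth))
  if (length(time) == 1L) {
    r <- .interp_uv(field, x, y, d_idx, time)
  } else {
    stopifnot(length(time) == length(x))
    r <- list(u = numeric(length(x)), v = numeric(length(x)),
              status = integer(length(x)))
    for (tu in unique(time)) {
      sel <- time == tu
      ri <- .interp_uv(field, x[sel], y[sel], d_idx, tu)
      r$u[sel] <- ri$u; r$v[sel] <- ri$v; r$status[sel] <- ri$status
    }
  }
  data.frame(u = r$u, v = r$v,
             status = c("ok", "boundary", "land")[r$status + 1L])
}

#' Seed particles uniformly over a release polygon
#'
#' Positions are drawn uniformly over the polygon (restricted to water cells
#' when a field is supplied); release times uniformly over the release window.
#'
#' @param polygon Either an `m x 2` vertex matrix (metres) or a
#'   [release_polygon()].
#' @param n Number of particles.
#' @param release_window Length-2 seconds `c(start, end)` (equal values give a
#'   simultaneous release).
#' @param seed Integer seed (reproducible draws).
#' @param field Optional [current_field()]; when given, positions falling on
#'   land cells are rejected.
#'
#' @return Data frame with `x`, `y` (metres) and `t_release` (seconds).
#' @export
seed_particles <- function(polygon, n, release_window = c(0, 0), seed = 1L,
                           field = NULL) {
  verts <- if (inherits(polygon, "release_polygon")) polygon$vertices else polygon
  stopifnot(is.matrix(verts), ncol(verts) == 2, n >= 1)
  bnd <- rbind(verts, verts[1, ])
  xr <- range(verts[, 1]); yr <- range(verts[, 2])
  set.seed(seed)
  xs <- numeric(0); ys <- numeric(0)
  for (round in 1:200) {
    m <- max(4L * (n - length(xs)), 64L)
    cx <- stats::runif(m, xr[1], xr[2]); cy <- stats::runif(m, yr[1], yr[2])
    keep <- mgcv::in.out(bnd, cbind(cx, cy))
    if (!is.null(field)) {
      ci <- cell_index(field$grid, cx, cy)
      keep <- keep & !is.na(ci$i) & field$mask[cbind(ci$j, ci$i)] == 0L
    }
    xs <- c(xs, cx[keep]); ys <- c(ys, cy[keep])
    if (length(xs) >= n) break
  }
  if (length(xs) < n)
    stop("could not place particles: polygon has no usable water area")
  t_rel <- if (diff(release_window) > 0)
    stats::runif(n, release_window[1], release_window[2])
  else rep(release_window[1], n)
  data.frame(x = xs[seq_len(n)], y = ys[seq_len(n)], t_release = t_rel)
}

#' Advect a particle ensemble through a current field
#'
#' Integrates each particle with fourth-order Runge--Kutta at step `dt`,
#' holding its depth fixed at the release depth. The effective velocity is the
#' interpolated current plus `wind_drag_pct`/100 of the wind vector when
#' windage is enabled. Particles crossing the open boundary freeze in place
#' with status `boundary_hit`; steps that would carry a particle onto land are
#' resolved by free slip (the motion component along the coast is retained,
#' the onshore component dropped), so particles are never beached
#' artificially.
#'
#' @param field A [current_field()].
#' @param seeds Data frame from [seed_particles()] (`x`, `y`, `t_release`).
#' @param config A [tracking_config()].
#' @param wind Optional wind series data frame (`time_s`, `wind_u`, `wind_v`);
#'   required when `config$wind_drag_pct > 0`.
#' @param polygon_id Identifier recorded on the ensemble.
#'
#' @return An object of class `track_ensemble`: list with `times` (seconds),
#'   matrices `x`, `y`, `status` (`n_times x n_particles`; status 0 = active,
#'   1 = boundary_hit, 2 = removed_stationary), the depth, config, and release
#'   metadata. `release_complete_step` marks the first step at which every
#'   particle has been released; residency counting starts there.
#' @export
advect_ensemble <- function(field, seeds, config, wind = NULL,
                            polygon_id = NA_character_) {
  stopifnot(inherits(field, "current_field"), inherits(config, "tracking_config"))
  g <- field$grid
  dt <- config$dt
  np <- nrow(seeds)
  if (config$wind_drag_pct > 0 && is.null(wind))
    stop("wind series required when wind_drag_pct > 0")

  d_idx <- which.min(abs(g$depth_layers - config$release_depth))
  t_rel <- floor(seeds$t_release / dt) * dt     # snap releases to the lattice
  t0 <- min(t_rel)
  t_end <- max(t_rel) + config$duration_h * 3600
  span <- (g$n_steps - 1) * g$time_step
  if (t_end > span + 1e-9)
    stop(sprintf("field spans %.1f h but the run needs %.1f h",
                 span / 3600, t_end / 3600))
  times <- seq(t0, t_end, by = dt)
  nT <- length(times)

  wfun <- if (config$wind_drag_pct > 0) {
    fu <- stats::approxfun(wind$time_s, wind$wind_u, rule = 2)
    fv <- stats::approxfun(wind$time_s, wind$wind_v, rule = 2)
    drag <- config$wind_drag_pct / 100
    function(t) c(drag * fu(t), drag * fv(t))
  } else function(t) c(0, 0)

  X <- matrix(NA_real_, nT, np); Y <- matrix(NA_real_, nT, np)
  S <- matrix(.STATUS_ACTIVE, nT, np)
  X[1, ] <- seeds$x; Y[1, ] <- seeds$y
  frozen <- logical(np)

  for (k in seq_len(nT - 1)) {
    t <- times[k]
    x <- X[k, ]; y <- Y[k, ]
    move <- !frozen & (t_rel <= t + 1e-9)
    xn <- x; yn <- y
    hit <- logical(np)
    if (any(move)) {
      mi <- which(move)
      xm <- x[mi]; ym <- y[mi]
      w1 <- wfun(t); w2 <- wfun(t + dt / 2); w3 <- wfun(t + dt)
      e1 <- .interp_uv(field, xm, ym, d_idx, t)
      hmi <- e1$status == .STATUS_BOUNDARY
      u1 <- e1$u + w1[1]; v1 <- e1$v + w1[2]
      x2 <- xm + dt / 2 * u1; y2 <- ym + dt / 2 * v1
      e2 <- .interp_uv(field, x2, y2, d_idx, t + dt / 2)
      hmi <- hmi | e2$status == .STATUS_BOUNDARY
      u2 <- e2$u + w2[1]; v2 <- e2$v + w2[2]
      x3 <- xm + dt / 2 * u2; y3 <- ym + dt / 2 * v2
      e3 <- .interp_uv(field, x3, y3, d_idx, t + dt / 2)
      hmi <- hmi | e3$status == .STATUS_BOUNDARY
      u3 <- e3$u + w2[1]; v3 <- e3$v + w2[2]
      x4 <- xm + dt * u3; y4 <- ym + dt * v3
      e4 <- .interp_uv(field, x4, y4, d_idx, t + dt)
      hmi <- hmi | e4$status == .STATUS_BOUNDARY
      u4 <- e4$u + w3[1]; v4 <- e4$v + w3[2]
      xp <- xm + dt / 6 * (u1 + 2 * u2 + 2 * u3 + u4)
      yp <- ym + dt / 6 * (v1 + 2 * v2 + 2 * v3 + v4)

      # free-slip resolution of land-impinging steps
      ci <- cell_index(g, xp, yp)
      onland <- !is.na(ci$i) & field$mask[cbind(ci$j, ci$i)] == 1L
      offgrid <- is.na(ci$i)
      if (any(onland)) {
        li <- which(onland)
        cx <- cell_index(g, xp[li], ym[li])   # x-move only
        okx <- !is.na(cx$i) & field$mask[cbind(cx$j, cx$i)] != 1L
        cy <- cell_index(g, xm[li], yp[li])   # y-move only
        oky <- !is.na(cy$i) & field$mask[cbind(cy$j, cy$i)] != 1L
        yp[li[okx]] <- ym[li[okx]]
        sel <- !okx & oky
        xp[li[sel]] <- xm[li[sel]]
        stay <- !okx & !oky
        xp[li[stay]] <- xm[li[stay]]; yp[li[stay]] <- ym[li[stay]]
      }
      hmi <- hmi | offgrid
      xp[hmi] <- xm[hmi]; yp[hmi] <- ym[hmi]   # boundary hits freeze in place
      xn[mi] <- xp; yn[mi] <- yp
      hit[mi] <- hmi
    }
    frozen <- frozen | hit
    X[k + 1, ] <- xn; Y[k + 1, ] <- yn
    S[k + 1, ] <- ifelse(frozen, .STATUS_BOUNDARY, .STATUS_ACTIVE)
    S[k + 1, S[k, ] == .STATUS_BOUNDARY] <- .STATUS_BOUNDARY
  }

  structure(list(times = times, x = X, y = Y, status = S,
                 depth = g$depth_layers[d_idx], config = config,
                 polygon_id = polygon_id, t_release = t_rel,
                 release_complete_step =
                   which(times >= max(t_rel) - 1e-9)[1],
                 excluded_from_step = NA_integer_),
            class = "track_ensemble")
}

#' @export
print.track_ensemble <- function(x, ...) {
  cat(sprintf("<track_ensemble> %d particles x %d steps (dt %g s), depth %g m\n",
              ncol(x$x), nrow(x$x), x$config$dt, x$depth))
  fin <- x$status[nrow(x$status), ]
  cat(sprintf("  final status: %d active, %d boundary_hit, %d removed\n",
              sum(fin == 0L), sum(fin == 1L), sum(fin == 2L)))
  invisible(x)
}

#' Flag timepoints affected by open-boundary hits
#'
#' When any particle of a plume reaches the open boundary it freezes there and
#' would contaminate downstream counts; following standard practice the
#' timepoints from one step before the first hit until the end of the run are
#' flagged excluded for counting. Ensembles with no hits pass through
#' unchanged.
#'
#' @param ensemble A [advect_ensemble()] result.
#' @return The ensemble with `excluded_from_step` set, plus an attribute
#'   `trim_report`: list with `first_hit_step`, `first_hit_time_s` and
#'   `n_affected` (particles that ever hit the boundary); all `NA`/0 when no
#'   particle hit.
#' @export
trim_boundary_artifacts <- function(ensemble) {
  stopifnot(inherits(ensemble, "track_ensemble"))
  hits <- which(ensemble$status == .STATUS_BOUNDARY, arr.ind = TRUE)
  if (!nrow(hits)) {
    attr(ensemble, "trim_report") <-
      list(first_hit_step = NA_integer_, first_hit_time_s = NA_real_,
           n_affected = 0L)
    return(ensemble)
  }
  k <- min(hits[, 1])
  ensemble$excluded_from_step <- max(k - 1L, 1L)
  attr(ensemble, "trim_report") <-
    list(first_hit_step = k,
         first_hit_time_s = ensemble$times[k],
         n_affected = length(unique(hits[, 2])))
  ensemble
}
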