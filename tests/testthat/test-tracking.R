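test_that("velocity interpolation is exact at nodes and linear between them", {
  g <- tiny_grid(nx = 5, ny = 4, n_steps = 3)
  dm <- c(3, 1, 4, 5)
  # u increases linearly with cell-centre x: u(xc) = 0.002 * xc
  ux <- 0.002 * (seq_len(5) - 0.5) * 50
  u <- array(rep(ux, each = 3 * 1 * 4), dim = dm)
  v <- array(0.02, dim = dm)
  f <- current_field(g, u, v)
  # node identity at a stored time
  r <- interpolate_velocity(f, 125, 75, 3.6, 720)
  expect_equal(r$u, 0.002 * 125)
  expect_equal(r$status, "ok")
  # halfway between two centres
  r2 <- interpolate_velocity(f, 150, 75, 3.6, 0)
  expect_equal(r2$u, 0.002 * 150)
  # off the grid -> boundary signal
  r3 <- interpolate_velocity(f, -10, 75, 3.6, 0)
  expect_equal(r3$status, "boundary")
  # past the last centre but inside the grid: clamped to the edge value
  r4 <- interpolate_velocity(f, 240, 75, 3.6, 0)
  expect_equal(r4$status, "ok")
  expect_equal(r4$u, 0.002 * 225)
})

test_that("land-adjacent interpolation renormalises over water cells", {
  g <- tiny_grid(nx = 4, ny = 4, n_steps = 2)
  mask <- matrix(0L, 4, 4); mask[, 3:4] <- 1L   # eastern half land
  f <- build_tidal_field(g, tidal_amp = 0, mean_flow = c(0.1, 0), mask = mask)
  # between water column 2 (u = 0.1) and land column 3 (u = 0): water-only
  # weights must return the water value, not a blend
  r <- interpolate_velocity(f, 100, 75, 3.6, 0)
  expect_equal(r$u, 0.1)
  # fully inside land columns: all four neighbours are land
  expect_equal(interpolate_velocity(f, 165, 75, 3.6, 0)$status, "land")
})

test_that("particles seed uniformly inside the polygon and on water only", {
  g <- tiny_grid()
  f <- uniform_field(0.1, 0, g)
  poly <- square_poly(1000, 1000, 200)
  s <- seed_particles(poly, 5000, seed = 5, field = f)
  expect_identical(nrow(s), 5000L)
  expect_true(all(s$x >= 800 & s$x <= 1200 & s$y >= 800 & s$y <= 1200))
  # empirical centroid of many uniform draws sits at the rectangle centre
  s2 <- seed_particles(poly, 1e5, seed = 6)
  expect_equal(mean(s2$x), 1000, tolerance = 0.005)   # ~3 SE of the mean
  expect_equal(mean(s2$y), 1000, tolerance = 0.005)
  mask <- matrix(1L, g$ny, g$nx); mask[1, 1] <- 0L
  fland <- build_tidal_field(g, tidal_amp = 0, mean_flow = c(0, 0),
                             mask = mask)
  expect_error(seed_particles(poly, 10, seed = 1, field = fland),
               "water")
})

test_that("uniform advection and windage drift match the analytic values", {
  g <- tiny_grid(depths = c(0.25, 3.6))
  f <- uniform_field(0.1, 0, g)
  poly <- square_poly(600, 1000, 50)
  cfg <- tracking_config(duration_h = 1, release_depth = 3.6,
                         n_particles = 50, seed = 2, release_jitter = FALSE)
  seeds <- seed_particles(poly, 50, seed = 2)
  ens <- advect_ensemble(f, seeds, cfg)
  disp <- ens$x[nrow(ens$x), ] - ens$x[1, ]
  expect_equal(disp, rep(360, 50), tolerance = 1e-6 * 360)
  expect_equal(ens$y[nrow(ens$y), ], ens$y[1, ])

  # zero drag is invariant to any wind series
  wind <- make_wind_series(2, mean_wind = c(10, 0), gust_sd = 2, seed = 9)
  ens0 <- advect_ensemble(f, seeds, cfg, wind = wind)
  expect_identical(ens0$x, ens$x)

  # 3% of a 10 m/s wind in still water drifts 1.08 km in an hour
  fstill <- uniform_field(0, 0, g)
  wind10 <- data.frame(time_s = c(0, 7200), wind_u = c(10, 10),
                       wind_v = c(0, 0))
  cfg3 <- tracking_config(duration_h = 1, release_depth = 0.25,
                          wind_drag_pct = 3, n_particles = 50, seed = 2,
                          release_jitter = FALSE)
  ens3 <- advect_ensemble(fstill, seeds, cfg3, wind = wind10)
  expect_equal(ens3$x[nrow(ens3$x), ] - ens3$x[1, ], rep(1080, 50),
               tolerance = 1e-9)
  expect_error(tracking_config(duration_h = 1, release_depth = 3.6,
                               wind_drag_pct = 3), "surface")
})

test_that("ensembles are deterministic and conserve particle counts", {
  g <- tiny_grid()
  f <- build_tidal_field(g, tidal_amp = 0.08, mean_flow = c(0.02, -0.01))
  poly <- square_poly(1000, 1500, 100)
  cfg <- tracking_config(duration_h = 3, release_depth = 3.6,
                         n_particles = 80, seed = 4)
  run <- function() {
    s <- seed_particles(poly, 80, release_window = c(0, 3600), seed = 4,
                        field = f)
    advect_ensemble(f, s, cfg)
  }
  a <- run(); b <- run()
  expect_identical(a, b)
  # active + boundary_hit + removed = n at every step
  tab <- apply(a$status, 1, function(s) sum(s %in% c(0L, 1L, 2L)))
  expect_true(all(tab == 80))
})

test_that("halving dt changes endpoints by under 1% of path length", {
  g <- grid_spec(nx = 60, ny = 60, depth_layers = 3.6, time_step = 720,
                 n_steps = 130)
  f <- build_tidal_field(g, tidal_amp = 0.1, mean_flow = c(0.01, 0.005))
  # start far enough west that the full tidal excursion stays in the domain
  seeds <- data.frame(x = 1000, y = 1500, t_release = 0)
  run_dt <- function(dt) {
    cfg <- tracking_config(duration_h = 24, release_depth = 3.6, dt = dt,
                           n_particles = 1, release_jitter = FALSE)
    advect_ensemble(f, seeds, cfg)
  }
  a <- run_dt(720); b <- run_dt(360)
  pa <- cbind(a$x[, 1], a$y[, 1])
  path_len <- sum(sqrt(rowSums(diff(pa)^2)))
  dend <- sqrt((a$x[nrow(a$x), 1] - b$x[nrow(b$x), 1])^2 +
                 (a$y[nrow(a$y), 1] - b$y[nrow(b$y), 1])^2)
  expect_lt(dend, 0.01 * path_len)
})

test_that("RK4 conserves the orbit radius in a vortex core; Euler drifts more", {
  g <- tiny_grid(n_steps = 40)
  f <- build_tidal_field(g, tidal_amp = 0, mean_flow = c(0, 0))
  ctr <- c(1025, 1025)
  f <- add_eddy(f, ctr, radius = 400, v_max = 0.2)
  r0 <- 150   # inside the solid-body core, where the field is linear
  omega <- 0.2 / 400
  t_rev <- 2 * pi / omega
  n_rev_steps <- ceiling(t_rev / 720)
  cfg <- tracking_config(duration_h = n_rev_steps * 720 / 3600,
                         release_depth = 3.6, n_particles = 1,
                         release_jitter = FALSE)
  seeds <- data.frame(x = ctr[1] + r0, y = ctr[2], t_release = 0)
  ens <- advect_ensemble(f, seeds, cfg)
  r_rk4 <- sqrt((ens$x[, 1] - ctr[1])^2 + (ens$y[, 1] - ctr[2])^2)
  expect_lt(max(abs(r_rk4 - r0)) / r0, 0.01)
  eu <- oracle_euler_track(f, c(ctr[1] + r0, ctr[2]), 3.6, 720, n_rev_steps)
  r_eu <- sqrt((eu$x - ctr[1])^2 + (eu$y - ctr[2])^2)
  expect_gt(max(abs(r_eu - r0)), max(abs(r_rk4 - r0)))
})

test_that("boundary hits freeze particles and trimming flags timepoints", {
  g <- tiny_grid(nx = 10, ny = 10, n_steps = 31)
  f <- uniform_field(0.2, 0, g)   # 500-m domain, fast eastward flow
  seeds <- data.frame(x = c(50, 400), y = c(250, 250), t_release = 0)
  cfg <- tracking_config(duration_h = 2, release_depth = 3.6,
                         n_particles = 2, release_jitter = FALSE)
  ens <- advect_ensemble(f, seeds, cfg)
  fin <- ens$status[nrow(ens$status), ]
  expect_identical(fin[2], 1L)   # the eastern particle leaves first
  # once hit, the position freezes and the status persists
  k <- min(which(ens$status[, 2] == 1L))
  expect_true(all(ens$status[k:nrow(ens$status), 2] == 1L))
  expect_true(all(ens$x[k:nrow(ens$x), 2] == ens$x[k, 2]))

  tr <- trim_boundary_artifacts(ens)
  rep_ <- attr(tr, "trim_report")
  expect_identical(rep_$first_hit_step, k)
  expect_identical(tr$excluded_from_step, k - 1L)

  # a no-hit ensemble passes through unchanged
  slow <- uniform_field(0.001, 0, g)
  ens2 <- advect_ensemble(slow, seeds, cfg)
  tr2 <- trim_boundary_artifacts(ens2)
  expect_identical(tr2$excluded_from_step, NA_integer_)
  expect_identical(attr(tr2, "trim_report")$n_affected, 0L)
})
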