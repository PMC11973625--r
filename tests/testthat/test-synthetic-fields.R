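test_that("tidal field builder reproduces constant-flow and symmetry cases", {
  g <- tiny_grid(n_steps = 63, time_step = 720)
  f <- build_tidal_field(g, tidal_amp = 0, mean_flow = c(0.05, 0))
  expect_true(all(f$u == 0.05) && all(f$v == 0))

  # one full period of a pure tide has zero time-mean at every cell
  period_h <- 12.4
  g2 <- tiny_grid(n_steps = 63, time_step = period_h * 3600 / 62)
  f2 <- build_tidal_field(g2, tidal_amp = 0.1, tidal_period_h = period_h,
                          mean_flow = c(0, 0))
  um <- mean(f2$u[-1, 1, 5, 5])   # steps 2..63 span exactly one period
  expect_lt(abs(um), 1e-12)
  expect_error(build_tidal_field(g, tidal_period_h = 0), "period")
})

test_that("default tidal conditions reach the observed peak lagoon speeds", {
  g <- tiny_grid(n_steps = 63)
  f <- build_tidal_field(g)
  speed <- sqrt(f$u[, 1, 5, 5]^2 + f$v[, 1, 5, 5]^2)
  expect_gt(max(speed), 0.2)
})

test_that("shelter attenuation is multiplicative, local and bounded", {
  g <- tiny_grid()
  f <- uniform_field(0.1, 0, g)
  poly <- square_poly(500, 500, 200)
  expect_identical(apply_shelter(f, poly, 1)$u, f$u)
  f0 <- apply_shelter(f, poly, 0)
  expect_true(all(f0$u[, 1, 10, 10] == 0))       # cell (475,475) inside
  expect_true(all(f0$u[, 1, 30, 30] == 0.1))     # outside untouched
  f01 <- apply_shelter(f, poly, 0.1)
  # attenuated speed falls below the slack threshold 0.022 m/s
  expect_equal(f01$u[1, 1, 10, 10], 0.01)
  expect_lt(sqrt(f01$u[1, 1, 10, 10]^2 + f01$v[1, 1, 10, 10]^2), 0.022)
  expect_error(apply_shelter(f, poly, 1.5), "attenuation")
})

test_that("Rankine eddy has solid-body core and 1/r tail", {
  g <- tiny_grid()
  f <- build_tidal_field(g, tidal_amp = 0, mean_flow = c(0, 0))
  ctr <- c(1025, 1025)   # a cell centre, so radii to other centres are exact
  f <- add_eddy(f, ctr, radius = 250, v_max = 0.2)
  sp <- function(x, y) {
    ci <- cell_index(g, x, y)
    sqrt(f$u[1, 1, ci$j, ci$i]^2 + f$v[1, 1, ci$j, ci$i]^2)
  }
  expect_equal(sp(1025, 1025), 0)                    # vortex centre
  expect_equal(sp(1025 + 250, 1025), 0.2)            # r = R
  expect_equal(sp(1025 + 500, 1025), 0.1)            # r = 2R -> v_max/2
  expect_equal(sp(1175, 1025), 0.2 * 150 / 250)      # solid body at r = 150
  expect_equal(sp(1025 + 800, 1025), 0)              # truncated beyond 3R
  expect_error(add_eddy(f, c(-10, 0)), "water")
})

test_that("drifter sampling follows the field and respects fix spacing", {
  g <- tiny_grid()
  f <- uniform_field(0.1, 0, g)
  d <- sample_drifter(f, c(500, 1000), duration_h = 1, gps_sigma = 0,
                      fix_interval = 600, seed = 7)
  expect_equal(max(d$x) - d$x[1], 360, tolerance = 1e-6)
  expect_equal(d$y, rep(1000, nrow(d)))
  d2 <- sample_drifter(f, c(500, 1000), duration_h = 2, gps_sigma = 5,
                       seed = 11)
  expect_true(all(diff(d2$time_s) >= 300 - 1e-9 & diff(d2$time_s) <= 600 + 1e-9))
  d3 <- sample_drifter(f, c(500, 1000), duration_h = 2, gps_sigma = 5,
                       seed = 11)
  expect_identical(d2, d3)   # bit-reproducible under a fixed seed
  expect_error(sample_drifter(f, c(-5, 0), duration_h = 1), "water")
})

test_that("tiltmeter sampling reproduces the cell series and sub-grid bias", {
  g <- tiny_grid(n_steps = 11)
  f <- uniform_field(0.06, 0.08, g)   # speed 0.1, heading 36.87
  tm <- sample_tiltmeter(f, c(1000, 1000), 3.6, duration_h = 1,
                         sample_interval = 60)
  expect_equal(tm$speed, rep(0.1, 60), tolerance = 1e-12)
  expect_equal(tm$heading, rep(uv_to_heading(0.06, 0.08)$heading, 60),
               tolerance = 1e-9)
  grooved <- sample_tiltmeter(f, c(1000, 1000), 3.6, duration_h = 1,
                              sample_interval = 60, gain = 0.3)
  expect_equal(mean(grooved$speed), 0.03, tolerance = 1e-12)
  # 1-s sampling over 24 h yields 86,400 samples
  g24 <- tiny_grid(n_steps = 121)
  f24 <- uniform_field(0.1, 0, g24)
  tm24 <- sample_tiltmeter(f24, c(1000, 1000), 3.6, duration_h = 24,
                           sample_interval = 1)
  expect_identical(nrow(tm24), 86400L)
})

test_that("coral polygon generator respects water, ranges and seeds", {
  g <- tiny_grid()
  mask <- matrix(0L, g$ny, g$nx)
  mask[, 1:8] <- 1L   # western land strip
  f <- build_tidal_field(g, tidal_amp = 0, mean_flow = c(0, 0), mask = mask)
  ps <- make_coral_polygons(f, n = 6, cover_range = c(0, 50),
                            area_range = c(5000, 15000), seed = 3)
  expect_length(ps, 6)
  for (p in ps) {
    expect_true(p$cover_pct >= 0 && p$cover_pct <= 50)
    ci <- cell_index(g, p$vertices[, 1], p$vertices[, 2])
    expect_true(all(f$mask[cbind(ci$j, ci$i)] == 0L))
  }
  ps2 <- make_coral_polygons(f, n = 6, cover_range = c(0, 50),
                             area_range = c(5000, 15000), seed = 3)
  expect_identical(ps, ps2)
  # downstream >= 10% cover filter drops exactly the sub-threshold polygons
  n_low <- sum(vapply(ps, function(p) p$cover_pct < 10, logical(1)))
  kept <- allocate_release_polygons(ps, 100, 600)
  parents <- unique(vapply(kept, function(p) p$parent_id, character(1)))
  expect_identical(length(unique(parents)), length(ps) - n_low)
})

test_that("a particle in a pure tide returns to its start after one period", {
  period_h <- 12.42
  g <- grid_spec(nx = 60, ny = 60, depth_layers = 3.6, time_step = 720,
                 n_steps = 70)
  f <- build_tidal_field(g, tidal_amp = 0.1, tidal_period_h = period_h,
                         mean_flow = c(0, 0))
  cfg <- tracking_config(duration_h = period_h, release_depth = 3.6, dt = 720,
                         n_particles = 1, release_jitter = FALSE)
  seeds <- data.frame(x = 1500, y = 1500, t_release = 0)
  ens <- advect_ensemble(f, seeds, cfg)
  nT <- nrow(ens$x)
  disp <- sqrt((ens$x[nT, 1] - 1500)^2 + (ens$y[nT, 1] - 1500)^2)
  expect_lt(disp, g$cell_size)   # closed ebb/flood orbit up to step error
})
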