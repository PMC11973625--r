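test_that("mean track is the active-particle centroid", {
  x <- matrix(c(0, 10, 20, 100, 110, 120), 3, 2)
  y <- matrix(c(0, 0, 0, 50, 50, 50), 3, 2)
  ens <- manual_ensemble(x, y)
  mt <- ensemble_mean_track(ens)
  expect_equal(mt$x, c(50, 60, 70))
  expect_equal(mt$y, c(25, 25, 25))
  # single particle: the mean track is its track
  mt1 <- ensemble_mean_track(manual_ensemble(x[, 1, drop = FALSE],
                                             y[, 1, drop = FALSE]))
  expect_equal(mt1$x, x[, 1])
})

test_that("a released plume in uniform flow drifts at the analytic rate", {
  g <- tiny_grid()
  f <- uniform_field(0.08, -0.03, g)
  ang <- seq(0, 2 * pi, length.out = 17)[-17]
  poly <- cbind(600 + 50 * cos(ang), 1500 + 50 * sin(ang))
  cfg <- tracking_config(duration_h = 2, release_depth = 0.25,
                         n_particles = 1000, seed = 12,
                         release_jitter = FALSE)
  seeds <- seed_particles(poly, 1000, seed = 12)
  mt <- ensemble_mean_track(advect_ensemble(f, seeds, cfg))
  nT <- nrow(mt)
  expect_equal(mt$x[nT] - mt$x[1], 0.08 * 7200, tolerance = 1e-9)
  expect_equal(mt$y[nT] - mt$y[1], -0.03 * 7200, tolerance = 1e-9)
})

test_that("track errors vanish on identity and respect circular bearings", {
  tt <- seq(0, 4 * 3600, 300)
  obs <- data.frame(time_s = tt, x = 0.05 * tt, y = 1000 + 0.02 * tt)
  cmp0 <- track_errors(obs, obs)
  expect_true(all(cmp0$distance_error == 0))
  expect_true(all(cmp0$direction_error == 0))
  expect_true(all(cmp0$speed_error == 0))

  # constant 100-m northward offset, same motion
  mod <- transform(obs, y = y + 100)
  cmp1 <- track_errors(obs, mod)
  expect_true(all(abs(cmp1$distance_error - 100) < 1e-9))
  expect_true(all(cmp1$direction_error == 0))
  expect_true(all(abs(cmp1$speed_error) < 1e-12))

  # observed bearing 10 deg, modelled 350 deg -> error is -20, not +340
  mk <- function(bearing) {
    th <- bearing * pi / 180
    data.frame(time_s = tt, x = sin(th) * 0.1 * tt, y = cos(th) * 0.1 * tt)
  }
  cmp2 <- track_errors(mk(10), mk(350))
  expect_true(all(abs(cmp2$direction_error + 20) < 1e-9))
  # antisymmetric under swapping the tracks
  cmp3 <- track_errors(mk(350), mk(10))
  expect_equal(cmp3$direction_error, -cmp2$direction_error)
  expect_true(all(cmp2$direction_error > -180 & cmp2$direction_error <= 180))
  expect_error(track_errors(obs[obs$time_s < 1800, ], mod), "hour")
})

test_that("hourly u/v regression has the closed-form limits", {
  tt <- seq(0, 72 * 3600 - 1, 600)
  u <- 0.1 * sin(2 * pi * tt / (12.42 * 3600))
  v <- 0.04 * cos(2 * pi * tt / (12.42 * 3600))
  mod <- data.frame(time_s = tt, u = u, v = v)
  fit <- hourly_uv_regression(mod, mod)
  expect_equal(fit$r2_u, 1); expect_equal(fit$r2_v, 1)
  expect_equal(fit$rmse_u, 0); expect_equal(fit$rmse_v, 0)

  obs <- transform(mod, u = u + 0.05)
  fit2 <- hourly_uv_regression(mod, obs)
  expect_equal(fit2$r2_u, 1)
  expect_equal(fit2$rmse_u, 0.05)

  # r2 is invariant to affine rescaling of either series; rmse is not
  obs3 <- transform(mod, u = 2 * u + 0.01, v = 2 * v - 0.01)
  fit3 <- hourly_uv_regression(mod, obs3)
  expect_equal(fit3$r2_u, 1)
  expect_gt(fit3$rmse_u, 0)

  # independent white noise: r2 near zero
  set.seed(33)
  nz <- function() data.frame(time_s = seq(0, 300 * 3600 - 1, 1200),
                              u = rnorm(900, 0, 0.05),
                              v = rnorm(900, 0, 0.05))
  fit4 <- hourly_uv_regression(nz(), nz())
  expect_lt(fit4$r2_u, 0.05)
  expect_lt(fit4$r2_v, 0.05)
  expect_error(hourly_uv_regression(mod[1:12, ], mod[1:12, ]), "overlap")
})

test_that("fit categories reproduce the published-style rule set", {
  # both components strong -> very good
  expect_identical(categorize_fit(list(r2_u = 0.660, r2_v = 0.797))$category,
                   "very_good")
  # east-west tidal site dominated by u: weak v does not demote the fit
  expect_identical(categorize_fit(list(r2_u = 0.548, r2_v = 0.014),
                                  dominant = "u")$category, "very_good")
  # one strong component on the secondary axis -> good
  expect_identical(categorize_fit(list(r2_u = 0.003, r2_v = 0.469),
                                  dominant = "u")$category, "good")
  # moderate dominant fit -> good
  expect_identical(categorize_fit(list(r2_u = 0.30, r2_v = 0.10),
                                  dominant = "u")$category, "good")
  # white-noise metrics -> no fit
  expect_identical(categorize_fit(list(r2_u = 0.02, r2_v = 0.01))$category,
                   "no_fit")
  ranks <- fit_category_rank()
  expect_true(ranks["very_good"] > ranks["good"] &&
                ranks["good"] > ranks["good_wind"] &&
                ranks["good_wind"] > ranks["poor"] &&
                ranks["poor"] > ranks["no_fit"])
})

test_that("full assessments detect lag, amplitude misfit and wind subsets", {
  hrs <- 0:119
  tide <- function(lag_h = 0, amp = 0.1)
    amp * sin(2 * pi * (hrs - lag_h) / 12.42)
  mk <- function(u) data.frame(time_s = hrs * 3600 + 1, u = u, v = 0)

  # pure 2-h lag: dominant r2 low at lag 0, recovered at lag <= 2 h
  set.seed(4)
  noise <- rnorm(120, 0, 0.01)
  fit_lag <- hourly_uv_regression(mk(tide(2)), mk(tide(0) + noise))
  cat_lag <- categorize_fit(fit_lag)
  expect_identical(cat_lag$category, "good")
  expect_true(cat_lag$lag_detected)

  # amplitude off by 3x with coherent tide -> poor
  fit_amp <- hourly_uv_regression(mk(tide(0, 0.3)), mk(tide(0, 0.1) + noise))
  cat_amp <- categorize_fit(fit_amp)
  expect_identical(cat_amp$category, "poor")
  expect_gt(cat_amp$amp_ratio, 2)
})
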