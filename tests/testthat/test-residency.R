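test_that("stationary-artifact filter removes only truly frozen particles", {
  # steady 0.05 m/s flow: nobody is stationary
  nT <- 26
  x <- matrix(0.05 * 720 * (0:(nT - 1)), nT, 5) + rep(1:5 * 10, each = nT)
  y <- matrix(1000, nT, 5)
  ens <- filter_stationary(manual_ensemble(x, y))
  expect_identical(attr(ens, "removed_count"), 0L)

  # one particle frozen for 2 h mid-track is removed
  x2 <- x; x2[10:20, 3] <- x2[10, 3]
  ens2 <- filter_stationary(manual_ensemble(x2, y))
  expect_identical(attr(ens2, "removed_count"), 1L)
  expect_true(all(ens2$status[, 3] == 2L))
  expect_true(all(ens2$status[, -3] == 0L))

  # immobility of exactly 1 h is retained (the rule is strictly > 1 h)
  x3 <- x; x3[10:15, 3] <- x3[10, 3]   # 5 steps = exactly 60 min
  ens3 <- filter_stationary(manual_ensemble(x3, y))
  expect_identical(attr(ens3, "removed_count"), 0L)
  # one step more (72 min > 1 h) tips it over
  x4 <- x; x4[10:16, 3] <- x4[10, 3]
  ens4 <- filter_stationary(manual_ensemble(x4, y))
  expect_identical(attr(ens4, "removed_count"), 1L)

  # boundary-frozen particles are not treated as stationary artifacts
  x5 <- x; st <- matrix(0L, nT, 5)
  x5[12:nT, 2] <- x5[12, 2]; st[12:nT, 2] <- 1L
  ens5 <- filter_stationary(manual_ensemble(x5, y, status = st))
  expect_identical(attr(ens5, "removed_count"), 0L)
})

test_that("buffer counts match analytic crossing and brute-force recounts", {
  g <- tiny_grid()
  f <- uniform_field(0.1, 0, g)
  ctr <- c(500, 1000)
  seeds <- data.frame(x = rep(500, 40), y = rep(1000, 40), t_release = 0)
  cfg <- tracking_config(duration_h = 2, release_depth = 3.6,
                         n_particles = 40, release_jitter = FALSE)
  ens <- advect_ensemble(f, seeds, cfg)
  cnt <- count_within_radius(ens, ctr)
  # 200 m / 0.1 m/s = 2000 s: the first lattice step past it is 2160 s
  expect_true(all(cnt$count[cnt$time_s <= 2000] == 40L))
  expect_true(all(cnt$count[cnt$time_s > 2160 - 1] == 0L))

  # zero current: the count never moves
  ens0 <- advect_ensemble(uniform_field(0, 0, g), seeds, cfg)
  cnt0 <- count_within_radius(ens0, ctr)
  expect_true(all(cnt0$count == 40L))

  # streaming counter equals a brute-force recount on random fixtures
  set.seed(42)
  for (rep_i in 1:10) {
    nT <- 15; np <- 500
    ens_r <- manual_ensemble(
      matrix(runif(nT * np, 0, 2000), nT, np),
      matrix(runif(nT * np, 0, 2000), nT, np),
      status = matrix(sample(c(0L, 0L, 0L, 2L), nT * np, TRUE), nT, np))
    ctr_r <- runif(2, 400, 1600)
    got <- count_within_radius(ens_r, ctr_r)$count
    expect_identical(got, oracle_buffer_counts(ens_r, ctr_r, 200))
  }
})

test_that("e-folding PRT crosses at the first sub-threshold step", {
  cfg <- residency_config()
  # printed threshold pair: N0 = 3500 crosses below ceiling(3500/e) = 1288
  expect_identical(efold_threshold_count(3500), 1288L)
  counts <- data.frame(elapsed_h = seq(0, 24, 0.2),
                       count = c(3500, rep(1288, 30), rep(1287, 90)))
  prt <- efolding_prt(counts, config = cfg)
  expect_false(prt$censored)
  # 1288 is still at/above N0/e = 1287.65; 1287 is the first crossing
  expect_equal(prt$prt_hours, counts$elapsed_h[32])

  # constant counts never cross: censored at the horizon
  const <- data.frame(elapsed_h = seq(0, 24, 0.2), count = rep(100, 121))
  prt_c <- efolding_prt(const, config = cfg)
  expect_true(prt_c$censored)
  expect_equal(prt_c$prt_hours, 24)

  # exponential-decay self-consistency: tau = 5 h recovered within one step
  tt <- seq(0, 24, 0.2)
  expo <- data.frame(elapsed_h = tt, count = round(4000 * exp(-tt / 5)))
  prt_e <- efolding_prt(expo, config = cfg)
  expect_lt(abs(prt_e$prt_hours - 5), 0.2 + 1e-9)
  expect_error(efolding_prt(data.frame(elapsed_h = 0, count = 0)), "N0")
})

test_that("PRT survey enumerates scenarios and separates sheltered sites", {
  sc <- enumerate_scenarios(paste0("s", 1:25), paste0("d", 1:10))
  expect_identical(nrow(sc), 2750L)
  expect_identical(sort(unique(sc$hour)), 6:16)

  g <- grid_spec(nx = 60, ny = 60, depth_layers = 3.6, time_step = 720,
                 n_steps = 171)   # 34 h
  f <- build_tidal_field(g, tidal_amp = 0.09, mean_flow = c(0.03, 0))
  f <- apply_shelter(f, square_poly(800, 2000, 400), 0.07)
  sites <- list(sheltered = c(800, 2000), open = c(2200, 2000))
  prt <- prt_survey(f, sites, days = c(d1 = 0), release_hours = c(2, 4),
                    n_particles = 120, duration_h = 6, seed = 3,
                    release_jitter = FALSE)
  expect_identical(nrow(prt), 4L)
  sh <- prt[prt$site == "sheltered", ]
  op <- prt[prt$site == "open", ]
  expect_true(all(sh$prt_hours >= 5))
  expect_true(all(op$prt_hours < 1))
  expect_true(all(prt$N0 == 120L))
  summ <- summarize_prt(prt)
  expect_identical(summ$n_ge_5h[summ$site == "sheltered"], 2L)

  # PRT is invariant to particle labelling
  set.seed(1); nT <- 10; np <- 60
  xs <- matrix(runif(nT * np, 850, 1150), nT, np)
  ys <- matrix(runif(nT * np, 850, 1150), nT, np)
  perm <- sample(np)
  p1 <- efolding_prt(count_within_radius(manual_ensemble(xs, ys), c(1000, 1000)))
  p2 <- efolding_prt(count_within_radius(manual_ensemble(xs[, perm], ys[, perm]),
                                         c(1000, 1000)))
  expect_identical(p1, p2)
})
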