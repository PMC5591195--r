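# Two-state trajectory simulation, substep integration, stack rendering.

test_that("trajectories have exponential dwells at the configured rates", {
  m <- kinetic_model(k_on = 50, k_off = 130, bright_rate = 30)
  ev <- simulate_state_trajectory(m, duration_ms = 1e5, seed = 7)
  bright <- trajectory_dwells(ev, 2)
  # sample mean within 3 standard errors of 1/k_off
  mu <- 1000 / 130
  se <- mu / sqrt(length(bright))
  expect_gt(length(bright), 3000)
  expect_lt(abs(mean(bright) - mu), 3 * se)
  dark <- trajectory_dwells(ev, 1)
  mu_d <- 1000 / 50
  expect_lt(abs(mean(dark) - mu_d) / (mu_d / sqrt(length(dark))), 3)

  # Kolmogorov-Smirnov against the exponential law, n = 5000 dwells
  m2 <- kinetic_model(k_on = 100, k_off = 100, bright_rate = 30)
  ev2 <- simulate_state_trajectory(m2, duration_ms = 1.1e5, seed = 8)
  d <- trajectory_dwells(ev2, 2)
  expect_gt(length(d), 5000)
  ks <- suppressWarnings(stats::ks.test(d[1:5000], stats::pexp, rate = 0.1))
  expect_gt(ks$p.value, 0.01)
})

test_that("absorbing and degenerate trajectories behave as documented", {
  m0 <- kinetic_model(k_on = 0, k_off = 0, bright_rate = 30)
  ev <- simulate_state_trajectory(m0, 1000, seed = 1, initial_state = 2)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$state, 2L)
  expect_equal(ev$t_end - ev$t_start, 1000)
  # k_on = 0: once dark, absorbed
  m1 <- kinetic_model(k_on = 0, k_off = 100, bright_rate = 30)
  ev1 <- simulate_state_trajectory(m1, 1e4, seed = 2, initial_state = 2)
  expect_lte(nrow(ev1), 2)
  expect_equal(ev1$state[nrow(ev1)], 1L)
})

test_that("symmetric FRET model occupies both states equally", {
  fm <- fret_model(k_12 = 80, k_21 = 80, E_1 = 0.25, E_2 = 0.75,
                   total_rate = 30)
  ev <- simulate_state_trajectory(fm, 2e5, seed = 3)
  t2 <- sum((ev$t_end - ev$t_start)[ev$state == 2])
  frac <- t2 / 2e5
  n_sw <- nrow(ev)
  expect_lt(abs(frac - 0.5), 3 / sqrt(n_sw))
})

test_that("substep integration matches piecewise closed forms", {
  cfg <- default_config()
  # constant bright rate: every substep r * dt/N
  m <- kinetic_model(0, 0, bright_rate = 30)
  ev <- simulate_state_trajectory(m, 5 * 21.7, seed = 1, initial_state = 2)
  lam <- integrate_substeps(ev, cfg, 5)
  expect_equal(dim(lam), c(5, 5))
  expect_equal(as.vector(lam), rep(30 * 4, 25))

  # hand-built switch exactly at a substep boundary (frame 1, after substep 2)
  ev2 <- data.frame(state = c(2L, 1L), t_start = c(0, 8), t_end = c(8, 50))
  attr(ev2, "model") <- m
  attr(ev2, "duration_ms") <- 50
  lam2 <- integrate_substeps(ev2, sweep_config(5, 96, frame_lag_ms = 0), 2)
  expect_equal(lam2[1, ], c(120, 120, 0, 0, 0))

  # mid-substep switch at fraction q of substep 3
  q <- 0.3
  ev3 <- data.frame(state = c(2L, 1L), t_start = c(0, 8 + q * 4),
                    t_end = c(8 + q * 4, 50))
  attr(ev3, "model") <- m
  attr(ev3, "duration_ms") <- 50
  lam3 <- integrate_substeps(ev3, sweep_config(5, 96, frame_lag_ms = 0), 2)
  expect_equal(lam3[1, 3], q * 30 * 4 + (1 - q) * 0 * 4)

  # too-short trajectory refused
  expect_error(integrate_substeps(ev2, cfg, 100),
               class = "smsweep_invalid_argument")
})

test_that("photons arriving during the inter-frame lag are discarded", {
  # bright only during the lag window between frames 1 and 2
  m <- kinetic_model(0, 0, bright_rate = 10)
  ev <- data.frame(state = c(1L, 2L, 1L), t_start = c(0, 20, 21.7),
                   t_end = c(20, 21.7, 43.4))
  attr(ev, "model") <- m
  attr(ev, "duration_ms") <- 43.4
  lam <- integrate_substeps(ev, default_config(), 2)
  expect_equal(as.vector(lam), rep(0, 10))
})

test_that("noiseless rendering conserves the photon budget", {
  r <- tiny_swept(n_frames = 4)
  budget <- sum(r$truth$expected)  # photons entering the splitter
  total <- sum(vapply(r$stack$frames, sum, numeric(1)))
  expect_lt(abs(total - budget) / budget, 1e-6)
  # 30:70 split between the channels
  lay <- r$stack$layout
  conv <- sum(vapply(r$stack$frames, function(f)
    sum(channel_image(f, lay, "conventional")), numeric(1)))
  swpt <- sum(vapply(r$stack$frames, function(f)
    sum(channel_image(f, lay, "swept")), numeric(1)))
  expect_lt(abs(conv - 0.3 * budget) / budget, 1e-6)
  expect_lt(abs(swpt - 0.7 * budget) / budget, 1e-6)
})

test_that("zero molecules with baseline give a flat baseline image", {
  r <- render_swept_stack(data.frame(x = numeric(0), y = numeric(0)),
                          kinetic_model(0, 0, 30), default_config(),
                          camera_model(em_gain = 1, read_noise_sd = 0,
                                       baseline = 7),
                          channel_layout(32, 16), n_frames = 2, seed = 1,
                          background_rate = 0, noise = FALSE)
  for (f in r$stack$frames) expect_true(all(f == 7))
})

test_that("a single-step sweep renders like a conventional channel", {
  cfg1 <- sweep_config(1, 0)
  r <- render_swept_stack(data.frame(x = 12, y = 12), kinetic_model(0, 0, 30),
                          cfg1, ideal_camera(), channel_layout(48, 24),
                          n_frames = 2, seed = 1, background_rate = 0,
                          noise = FALSE)
  lay <- r$stack$layout
  conv <- channel_image(r$stack$frames[[1]], lay, "conventional")
  swpt <- channel_image(r$stack$frames[[1]], lay, "swept")
  expect_equal(swpt * 0.3, conv * 0.7, tolerance = 1e-12)
})

test_that("identical seeds give bit-identical stacks", {
  m <- kinetic_model(217, 80, 30)
  a <- tiny_swept(m, n_frames = 3, seed = 99, noise = TRUE,
                  camera = camera_model(), background_rate = 0.05)
  b <- tiny_swept(m, n_frames = 3, seed = 99, noise = TRUE,
                  camera = camera_model(), background_rate = 0.05)
  expect_identical(a$stack$frames, b$stack$frames)
  c <- tiny_swept(m, n_frames = 3, seed = 100, noise = TRUE,
                  camera = camera_model(), background_rate = 0.05)
  expect_false(identical(a$stack$frames, c$stack$frames))
})

test_that("molecules sweeping out of the sub-region are refused by name", {
  expect_error(
    render_swept_stack(data.frame(x = 40, y = 12), kinetic_model(0, 0, 30),
                       default_config(), ideal_camera(),
                       channel_layout(48, 24), n_frames = 1, seed = 1),
    "molecule\\(s\\) 1", class = "smsweep_invalid_argument")
})

test_that("FRET rendering partitions photons by efficiency and leakage", {
  cfg <- sweep_config(4, 96)
  # E_1 = E_2 = 0.5 is disallowed by the model (states must differ), so use
  # a one-state occupancy: k_12 = 0 keeps the molecule in state 1
  fm <- fret_model(0, 1e-9, E_1 = 0.5, E_2 = 0.9, total_rate = 30)
  r <- render_fret_stack(data.frame(x = 12, y = 12), fm, cfg, ideal_camera(),
                         n_frames = 3, n_unswept_lead_frames = 1, seed = 4,
                         background_rate = 0, noise = FALSE,
                         region_px = c(48, 24))
  lay <- r$stack$layout
  don <- sum(vapply(r$stack$frames, function(f)
    sum(channel_image(f, lay, "donor")), numeric(1)))
  acc <- sum(vapply(r$stack$frames, function(f)
    sum(channel_image(f, lay, "acceptor")), numeric(1)))
  expect_equal(acc / don, 1, tolerance = 1e-6)  # E = 0.5: equal masses

  # pure leakage: E = 0 puts all photons in the donor, acceptor = leak * donor
  fm0 <- fret_model(0, 1e-9, E_1 = 0, E_2 = 0.9, total_rate = 30,
                    leakage = 0.12)
  r0 <- render_fret_stack(data.frame(x = 12, y = 12), fm0, cfg,
                          ideal_camera(), n_frames = 3,
                          n_unswept_lead_frames = 1, seed = 4,
                          background_rate = 0, noise = FALSE,
                          region_px = c(48, 24))
  don0 <- sum(vapply(r0$stack$frames, function(f)
    sum(channel_image(f, lay, "donor")), numeric(1)))
  acc0 <- sum(vapply(r0$stack$frames, function(f)
    sum(channel_image(f, lay, "acceptor")), numeric(1)))
  expect_equal(acc0 / don0, 0.12, tolerance = 1e-6)
})

test_that("two-state FRET occupancy matches the stationary distribution", {
  fm <- fret_model(k_12 = 40, k_21 = 120, E_1 = 0.25, E_2 = 0.75,
                   total_rate = 30)
  ev <- simulate_state_trajectory(fm, 1.5e5, seed = 5)
  occ <- state_occupancy(ev, sweep_config(4, 96), 6000)
  frac2 <- mean(occ)
  expected <- 40 / 160
  n_sw <- nrow(ev)
  expect_lt(abs(frac2 - expected), 3 * 0.5 / sqrt(n_sw))
})
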