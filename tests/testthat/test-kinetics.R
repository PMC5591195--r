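# SNR, autocorrelation, dwell detection and fitting, FRET efficiency, HMM.

test_that("SNR ratios follow their definitions", {
  set.seed(1)
  on <- rnorm(200, 100, 9)
  off <- rnorm(200, 10, 5)
  v <- c(on, off)
  s <- compute_snr(v, c(rep(TRUE, 200), rep(FALSE, 200)))
  expect_equal(s$snr_b, (mean(on) - mean(off)) / sd(off))
  expect_equal(s$snr_s, (mean(on) - mean(off)) / sd(on))
  # constant trace split arbitrarily: zero SNR
  s0 <- compute_snr(rep(5, 10), c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE,
                                  FALSE, FALSE, TRUE, FALSE))
  expect_equal(s0$snr_b, 0)
  expect_error(compute_snr(v, rep(TRUE, 400)),
               class = "smsweep_insufficient_data")
})

test_that("simulated SNR sits in the expected regime and drops with speed", {
  # slow blinking so that 20-ms blocks still contain pure ON/OFF samples
  r <- tiny_swept(kinetic_model(20, 10, 30), n_frames = 200, seed = 23,
                  noise = TRUE, camera = camera_model(),
                  background_rate = 0.05)
  dec <- decode_stack(r$stack)
  tr <- dec$traces[[1]]
  occ <- as.vector(t(r$truth$occupancy[, , 1]))
  mask4 <- occ > 0.99
  off4 <- occ < 0.01
  s4 <- compute_snr(tr$values[mask4 | off4], mask4[mask4 | off4])
  expect_gt(s4$snr_b, 3)
  expect_lt(s4$snr_b, 60)
  # block-averaged 20-ms trace has higher per-sample SNR
  tr20 <- block_average_trace(tr)
  occ20 <- block_average(occ, 5)
  keep <- occ20 > 0.99 | occ20 < 0.01
  s20 <- compute_snr(tr20$values[keep], (occ20 > 0.99)[keep])
  expect_gt(s20$snr_b, s4$snr_b)
})

test_that("autocorrelation equals the O(n^2) definition to 1e-10", {
  set.seed(2)
  for (x in list(rnorm(400), cumsum(rnorm(300)), rep(c(1, 1, 0, 0), 100))) {
    a <- autocorrelation(x, 30)
    b <- acf_bruteforce(x, 30)
    expect_lt(max(abs(a - b)), 1e-10)
    a2 <- autocorrelation(x, 30, normalize = "mean2")
    b2 <- acf_bruteforce(x, 30, normalize = "mean2")
    expect_lt(max(abs(a2 - b2)), 1e-10)
  }
})

test_that("autocorrelation behaves on white noise and periodic traces", {
  set.seed(3)
  x <- rnorm(4000)
  a <- autocorrelation(x, 20)
  expect_equal(a[1], 1)
  expect_lt(max(abs(a[-1])), 3 / sqrt(4000))
  sq <- rep(c(rep(1, 10), rep(0, 10)), 50)  # period 20
  asq <- autocorrelation(sq, 40)
  expect_gt(asq[21], 0.9)
  expect_error(autocorrelation(rep(1, 100), 10),
               class = "smsweep_insufficient_data")
  expect_error(autocorrelation(rnorm(20), 15),
               class = "smsweep_invalid_argument")
})

test_that("blinking ACF fit recovers parameters from the exact curve", {
  t <- seq(0, 60, by = 2)
  y <- (80 / 217) * exp(-((217 + 80) / 1000) * t)
  f <- fit_blinking_acf(y, t)
  expect_equal(f$k_on, 217, tolerance = 1e-6)
  expect_equal(f$k_off, 80, tolerance = 1e-6)
  expect_equal(f$amplitude, 80 / 217, tolerance = 1e-6)
  expect_equal(f$off_time_ms, 1000 / 217, tolerance = 1e-6)
  expect_error(fit_blinking_acf(y[1:3], t[1:3]),
               class = "smsweep_insufficient_data")
})

test_that("rates are recovered from long simulated telegraph traces", {
  cfg <- default_config()
  set.seed(4)
  m <- kinetic_model(150, 100, 30)
  traces <- lapply(1:10, function(i) {
    ev <- simulate_state_trajectory(m, 800 * 21.7)
    ideal_trace(ev, cfg, 800)
  })
  a <- blinking_acf(traces, 15, frame_lag_ms = cfg$frame_lag_ms)
  f <- fit_blinking_acf(a$acf, a$lags_ms, binning_correction = TRUE,
                        bin_ms = a$bin_ms)
  expect_lt(abs(f$k_on - 150) / 150, 0.1)
  expect_lt(abs(f$k_off - 100) / 100, 0.1)
})

test_that("reported off-time tracks 1/k_on across a rate grid", {
  cfg <- default_config()
  set.seed(5)
  offs <- vapply(c(100, 200, 300), function(k_on) {
    m <- kinetic_model(k_on, 80, 30)
    traces <- lapply(1:6, function(i)
      ideal_trace(simulate_state_trajectory(m, 600 * 21.7), cfg, 600))
    a <- blinking_acf(traces, 12, frame_lag_ms = cfg$frame_lag_ms)
    fit_blinking_acf(a$acf, a$lags_ms, binning_correction = TRUE,
                     bin_ms = a$bin_ms)$off_time_ms
  }, numeric(1))
  expect_true(all(diff(offs) < 0))
  expect_equal(offs, 1000 / c(100, 200, 300), tolerance = 0.15)
})

test_that("threshold dwell detection is hand-checkable", {
  d <- detect_dwells_threshold(c(0, 0, 50, 50, 50, 0), i_b = 0, sigma_b = 1,
                               substep_ms = 4)
  expect_equal(d$state, c("OFF", "ON", "OFF"))
  expect_equal(d$duration_ms, c(8, 12, 4))
  expect_equal(d$censored, c(TRUE, FALSE, TRUE))
  expect_equal(d$start_ms, c(0, 8, 20))
  # all-below threshold: one censored OFF dwell
  d0 <- detect_dwells_threshold(rep(0, 10), i_b = 0, sigma_b = 1,
                                substep_ms = 4)
  expect_equal(nrow(d0), 1)
  expect_equal(d0$state, "OFF")
  expect_true(d0$censored)
  expect_error(detect_dwells_threshold(1:5, i_b = 0, sigma_b = 0,
                                       substep_ms = 4),
               class = "smsweep_invalid_argument")
})

test_that("exponential dwell MLE is unbiased on continuous samples", {
  set.seed(6)
  d <- data.frame(molecule_id = 1, state = "ON",
                  start_ms = 0, duration_ms = rexp(12500, 1 / 7.7),
                  censored = FALSE)
  f <- fit_dwell_histogram(d, "ON")
  se <- 7.7 / sqrt(12500)
  expect_lt(abs(f$tau_ms - 7.7), 3 * se)
  # bias < 2% at n = 5000
  taus <- vapply(1:20, function(i) {
    di <- data.frame(molecule_id = 1, state = "ON", start_ms = 0,
                     duration_ms = rexp(5000, 1 / 10), censored = FALSE)
    fit_dwell_histogram(di, "ON", n_boot = 0)$tau_ms
  }, numeric(1))
  expect_lt(abs(mean(taus) - 10) / 10, 0.02)
  # single repeated value collapses to that value
  ds <- data.frame(molecule_id = 1, state = "ON", start_ms = 0,
                   duration_ms = rep(6, 100), censored = FALSE)
  expect_equal(fit_dwell_histogram(ds, "ON")$tau_ms, 6)
  expect_error(fit_dwell_histogram(d[1:10, ], "ON"),
               class = "smsweep_insufficient_data")
})

test_that("binding dwells decode to the configured on-time", {
  cfg <- sweep_config(5, 112)
  set.seed(7)
  m <- kinetic_model(3, 130, 30)
  dwells <- do.call(rbind, lapply(1:12, function(i) {
    ev <- simulate_state_trajectory(m, 800 * 21.7)
    detect_dwells_threshold(ideal_trace(ev, cfg, 800), molecule_id = i)
  }))
  f <- fit_dwell_histogram(dwells, "ON", discrete_ms = 4)
  expect_gt(f$n, 200)
  expect_lt(abs(f$tau_ms - 1000 / 130) / (1000 / 130), 0.15)
})

test_that("FRET efficiency handles trivial and invalid cases", {
  expect_equal(fret_efficiency(c(10, 20), c(10, 20)), c(0.5, 0.5),
               ignore_attr = TRUE)
  # exact leakage null: corrected acceptor is zero
  id <- c(50, 80)
  ia <- 5 + 0.1 * (id - 2)
  e <- fret_efficiency(id, ia, leakage = 0.1, background_d = 2,
                       background_a = 5)
  expect_equal(as.numeric(e), c(0, 0))
  bad <- fret_efficiency(c(5, -5), c(5, 2))
  expect_true(is.na(bad[2]))
  expect_false(is.na(bad[1]))
  expect_equal(attr(bad, "n_invalid"), 1)
  expect_error(fret_efficiency(1:3, 1:2), class = "smsweep_invalid_argument")
})

test_that("decoded FRET efficiencies match the configured states within 0.05", {
  preset <- scenario_preset("fret")
  sim <- simulate_scenario("fret", n_frames = 200, seed = 8, n_molecules = 8)
  dec <- decode_fret_stack(sim$stack)
  expect_gt(dec$n_retained, 5)
  # match each retained peak to its ground-truth molecule by lane (y)
  mol <- vapply(dec$peaks$y, function(y)
    which.min(abs(sim$truth$positions$y - y)), integer(1))
  eff <- unlist(lapply(seq_along(dec$donor), function(i)
    fret_efficiency(dec$donor[[i]]$values, dec$acceptor[[i]]$values,
                    leakage = preset$model$leakage)))
  true_e <- unlist(lapply(mol, function(m)
    as.vector(t(sim$truth$fret$efficiency[, , m]))))
  # per-state means over substeps spent purely in one conformation
  pure1 <- true_e < 0.2501
  pure2 <- true_e > 0.7499
  expect_lt(abs(mean(eff[pure1], na.rm = TRUE) - 0.25), 0.05)
  expect_lt(abs(mean(eff[pure2], na.rm = TRUE) - 0.75), 0.05)
})

test_that("fret histograms resolve two modes only at high time resolution", {
  sim <- simulate_scenario("fret", n_frames = 250, seed = 9, n_molecules = 16)
  dec <- decode_fret_stack(sim$stack)
  eff <- unlist(lapply(seq_along(dec$donor), function(i)
    fret_efficiency(dec$donor[[i]]$values, dec$acceptor[[i]]$values,
                    leakage = 0.1)))
  h5 <- fret_histogram(eff, 25)
  h20 <- fret_histogram(block_average(eff, 4), 25)
  expect_true(is_bimodal(h5))
  expect_false(is_bimodal(h20))
  # degenerate: identical efficiencies occupy a single bin
  hd <- fret_histogram(rep(0.42, 200), 20)
  expect_equal(sum(hd$counts > 0), 1)
  expect_error(fret_histogram(runif(50)), class = "smsweep_insufficient_data")
})

test_that("temporal resolution contrast: fast blinking needs fast sampling", {
  sim <- simulate_scenario("blinking", n_frames = 250, seed = 10,
                           n_molecules = 6)
  dec <- decode_stack(sim$stack)
  n_fast <- 0; n_slow <- 0
  for (tr in dec$traces) {
    df <- detect_dwells_threshold(tr)
    n_fast <- n_fast + sum(df$state == "OFF" & !df$censored)
    ds <- detect_dwells_threshold(block_average_trace(tr))
    n_slow <- n_slow + sum(ds$state == "OFF" & !ds$censored)
  }
  # >= 10 OFF dwells per 10-s trace at 4 ms; < 10% as many at 20 ms
  expect_gt(n_fast / length(dec$traces) / (250 * 21.7 / 1e4), 10)
  expect_lt(n_slow, 0.1 * n_fast)
})
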