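# Spot detection, channel mapping, trace extraction, overlap filtering.

test_that("spot detection localizes a noiseless Gaussian to < 0.1 px", {
  img <- spot_image(20.4, 30.7)
  p <- detect_spots(img)
  expect_equal(nrow(p), 1)
  expect_lt(abs(p$x - 20.4), 0.1)
  expect_lt(abs(p$y - 30.7), 0.1)
})

test_that("blank or invalid images are handled", {
  expect_equal(nrow(detect_spots(matrix(0, 20, 20))), 0)
  expect_error(detect_spots(matrix(NA_real_, 5, 5)),
               class = "smsweep_invalid_argument")
  expect_error(detect_spots(matrix(numeric(0), 0, 0)),
               class = "smsweep_invalid_argument")
})

test_that("peaks closer than the separation limit are both discarded", {
  img <- spot_image(15, 20) + spot_image(17, 20)
  # the two spots 2 px apart merge or resolve; either way nothing survives
  p <- detect_spots(img, min_separation_px = 10)
  img2 <- spot_image(10, 10) + spot_image(30, 30)
  p2 <- detect_spots(img2, min_separation_px = 10)
  expect_lte(nrow(p), 1)  # merged blob may appear as one peak
  expect_equal(nrow(p2), 2)
  # with two clearly resolved but near peaks, both must go
  img3 <- spot_image(14, 20) + spot_image(22, 20)
  p3 <- detect_spots(img3, min_separation_px = 10)
  expect_equal(nrow(p3), 0)
})

test_that("channel map recovers identity, translation and affine warps", {
  set.seed(11)
  beads <- data.frame(x = runif(12, 10, 50), y = runif(12, 10, 50))
  id <- fit_channel_map(beads, beads)
  expect_equal(id$A, diag(2), tolerance = 1e-8)
  expect_equal(id$b, c(0, 0), tolerance = 1e-8)
  expect_lt(id$residual_rms, 1e-8)

  shifted <- transform(beads, x = x + 256)
  tr <- fit_channel_map(beads, shifted)
  expect_equal(tr$A, diag(2), tolerance = 1e-8)
  expect_equal(tr$b, c(256, 0), tolerance = 1e-6)

  A <- matrix(c(1.01, 0.004, -0.003, 0.995), 2, 2, byrow = TRUE)
  b <- c(128.5, -2.2)
  warped <- as.data.frame(t(A %*% t(as.matrix(beads[, c("x", "y")])) + b))
  names(warped) <- c("x", "y")
  warped$x <- warped$x + rnorm(12, 0, 0.05)
  warped$y <- warped$y + rnorm(12, 0, 0.05)
  af <- fit_channel_map(beads, warped)
  expect_lt(max(abs(af$A - A)), 1e-2)
  expect_lt(max(abs(af$b - b)), 1.5)  # offset trades against the linear part
  # the map must predict bead positions to well under a pixel
  pred <- apply_channel_map(af, beads)
  expect_lt(sqrt(mean((pred$x - warped$x)^2 + (pred$y - warped$y)^2)), 0.2)

  expect_error(fit_channel_map(beads[1:2, ], beads[1:2, ]),
               class = "smsweep_insufficient_data")
})

test_that("noiseless always-bright extraction gives near-constant samples", {
  r <- tiny_swept(n_frames = 6)
  dec <- decode_stack(r$stack)
  expect_equal(dec$n_retained, 1)
  tr <- dec$traces[[1]]
  expect_length(tr$values, 6 * 5)
  expect_lt(diff(range(tr$values)) / mean(tr$values), 0.02)
  # < 1% of the PSF mass escapes the 7x7 window (FWHM 2.56 px)
  expect_gt(mean(tr$values), 0.99 * 0.7 * 30 * 4 * 0.99)
})

test_that("ground-truth dark substeps decode to background level", {
  r <- tiny_swept(kinetic_model(217, 80, 30), n_frames = 40, seed = 5)
  dec <- decode_stack(r$stack)
  tr <- dec$traces[[1]]
  truth <- as.vector(t(r$truth$expected[, , 1])) * 0.7
  bright <- truth > 0.999 * max(truth)
  dark <- truth == 0
  expect_gt(sum(dark), 0)
  expect_gt(sum(bright), 0)
  # dark samples sit at background; a dark substep flanked by two bright
  # neighbours picks up ~2% of their mass through inter-spot crosstalk
  # (spacing is ~2 FWHM), so allow up to 4% of the bright level there
  expect_lt(max(abs(tr$values[dark])), 0.04 * max(truth))
  expect_lt(max(abs(tr$values[bright] - truth[bright]) / truth[bright]), 0.02)
})

test_that("a single-step sweep reduces to per-frame photometry", {
  cfg1 <- sweep_config(1, 0)
  r <- render_swept_stack(data.frame(x = 12, y = 12),
                          kinetic_model(0, 0, 30), cfg1, ideal_camera(),
                          channel_layout(48, 24), n_frames = 4, seed = 2,
                          background_rate = 0, noise = FALSE)
  off <- channel_offset(r$stack$layout, "swept")
  tr <- extract_trace(r$stack, data.frame(x = 12 + off, y = 12), cfg1)
  expect_length(tr$values, 4)
  manual <- vapply(r$stack$frames, function(f)
    sum(f[9:15, (off + 9):(off + 15)]), numeric(1))
  expect_equal(tr$raw, manual)
})

test_that("extraction rejects bad windows and even boxes", {
  r <- tiny_swept(n_frames = 2)
  off <- channel_offset(r$stack$layout, "swept")
  expect_error(extract_trace(r$stack, data.frame(x = 12 + off, y = 12),
                             default_config(), box_px = 6),
               class = "smsweep_invalid_argument")
  expect_error(extract_trace(r$stack, data.frame(x = 90, y = 12),
                             default_config()),
               class = "smsweep_invalid_argument")
})

test_that("overlap filter equals the brute-force pairwise oracle", {
  cfg <- default_config()
  # hand cases: same row 10 px apart with L = 24 -> both removed
  p1 <- data.frame(x = c(10, 20), y = c(15, 15))
  expect_equal(nrow(filter_overlaps(p1, cfg)), 0)
  # vertically separated -> both kept
  p2 <- data.frame(x = c(10, 10), y = c(10, 30))
  expect_equal(nrow(filter_overlaps(p2, cfg)), 2)
  # randomized agreement with the O(n^2) oracle
  set.seed(21)
  for (i in 1:3) {
    peaks <- data.frame(x = runif(120, 1, 200), y = runif(120, 1, 200))
    fast <- filter_overlaps(peaks, cfg)
    slow <- overlap_bruteforce(peaks, cfg)
    expect_equal(fast, slow)
  }
  expect_equal(nrow(filter_overlaps(p1[0, ], cfg)), 0)
})

test_that("throughput crossover: sweeping wins at low density only", {
  cfg <- default_config()
  W <- 240; H <- 240; N <- cfg$n_steps
  set.seed(31)
  usable_swept <- function(n) {
    peaks <- data.frame(x = runif(n, 1, W), y = runif(n, 1, H))
    nrow(filter_overlaps(peaks, cfg))
  }
  usable_cropped <- function(n) {
    # 1/N of the field at full frame rate, no sweep footprint to collide
    sum(runif(n, 1, H) <= H / N)
  }
  reps <- function(f, n) mean(vapply(1:30, function(i) f(n), numeric(1)))
  lo_s <- reps(usable_swept, 20); lo_c <- reps(usable_cropped, 20)
  hi_s <- reps(usable_swept, 2000); hi_c <- reps(usable_cropped, 2000)
  expect_gt(lo_s, lo_c)   # low density: full swept FOV sees more molecules
  expect_lt(hi_s, hi_c)   # high density: overlap filtering reverses it
  # survivor count decays monotonically (on average) as density grows
  mids <- vapply(c(50, 200, 800, 2000), function(n)
    reps(usable_swept, n), numeric(1))
  expect_gt(mids[2], mids[4])
})

test_that("decoded length is always n_frames x n_steps", {
  for (n_steps in c(2, 4, 5)) {
    cfg <- sweep_config(n_steps, 96)
    r <- render_swept_stack(data.frame(x = 12, y = 12),
                            kinetic_model(217, 80, 30), cfg, camera_model(),
                            channel_layout(48, 24), n_frames = 7, seed = 3,
                            noise = TRUE)
    dec <- decode_stack(r$stack)
    if (dec$n_retained > 0)
      expect_length(dec$traces[[1]]$values, 7 * n_steps)
  }
})

test_that("noisy decoding still correlates > 0.95 with ground truth", {
  # a bright molecule (60 detected photons/ms in the on state)
  r <- tiny_swept(kinetic_model(217, 80, 60), n_frames = 150, seed = 17,
                  noise = TRUE, camera = camera_model(),
                  background_rate = 0.05)
  dec <- decode_stack(r$stack)
  expect_equal(dec$n_retained, 1)
  tr <- dec$traces[[1]]
  truth <- as.vector(t(r$truth$expected[, , 1]))
  expect_gt(stats::cor(tr$values, truth), 0.95)
})
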