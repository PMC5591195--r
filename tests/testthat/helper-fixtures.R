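# Shared fixture builders. Everything is generated in code at test time.

# noise-free camera: counts = photons (gain 1), no read noise, no baseline
ideal_camera <- function() {
  camera_model(em_gain = 1, read_noise_sd = 0, baseline = 0)
}

default_config <- function() sweep_config(n_steps = 5, voltage_mV = 96)

# one molecule, two-channel layout, small field
tiny_swept <- function(model = kinetic_model(0, 0, 30), n_frames = 5,
                       seed = 1, noise = FALSE, camera = ideal_camera(),
                       background_rate = 0, config = default_config()) {
  render_swept_stack(data.frame(x = 12, y = 12), model, config, camera,
                     channel_layout(48, 24), n_frames, seed = seed,
                     background_rate = background_rate, noise = noise)
}

# a single noiseless Gaussian spot on a blank field
spot_image <- function(x0, y0, sigma = 1.1, h = 40, w = 40, mass = 1000) {
  sp <- gaussian_spot(x0, y0, sigma)
  img <- matrix(0, h, w)
  img[sp$rows, sp$cols] <- mass * sp$mass
  img
}

# ideal decoded trace straight from a trajectory (no rendering)
ideal_trace <- function(events, config, n_frames) {
  lam <- integrate_substeps(events, config, n_frames)
  structure(list(values = as.vector(t(lam)), raw = as.vector(t(lam)),
                 i_b = 0, sigma_b = 1, substep_ms = substep_ms(config),
                 n_steps = config$n_steps, n_frames = n_frames,
                 box_px = 7, slide_px = round(spot_spacing_px(config)),
                 peak = NULL),
            class = "spot_trace")
}

# direct O(n^2) autocorrelation oracle (textbook definition)
acf_bruteforce <- function(x, max_lag, normalize = "variance") {
  n <- length(x)
  xb <- mean(x)
  out <- numeric(max_lag + 1)
  for (k in 0:max_lag) {
    s <- 0
    for (t in seq_len(n - k)) s <- s + (x[t] - xb) * (x[t + k] - xb)
    out[k + 1] <- s / n
  }
  if (normalize == "variance") out / out[1] else out / xb^2
}

# brute-force pairwise overlap filter oracle
overlap_bruteforce <- function(peaks, config, box_px = 7) {
  n <- nrow(peaks)
  if (n <= 1) return(peaks)
  r <- (box_px - 1) / 2
  L <- sweep_length_px(config)
  bad <- rep(FALSE, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      xi <- c(peaks$x[i] - r, peaks$x[i] + L + r)
      xj <- c(peaks$x[j] - r, peaks$x[j] + L + r)
      yi <- c(peaks$y[i] - r, peaks$y[i] + r)
      yj <- c(peaks$y[j] - r, peaks$y[j] + r)
      if (xi[1] <= xj[2] && xi[2] >= xj[1] && yi[1] <= yj[2] && yi[2] >= yj[1]) {
        bad[i] <- TRUE
        bad[j] <- TRUE
      }
    }
  }
  peaks[!bad, , drop = FALSE]
}
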