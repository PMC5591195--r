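# Pixel-integrated Gaussian PSF rendering and the EMCCD noise chain.

#' Pixel-integrated Gaussian spot
#'
#' Fraction of a unit-mass isotropic 2-D Gaussian PSF falling in each pixel
#' of a window around `(x0, y0)`, computed from error-function differences
#' (pixel `(r, c)` covers `[c - 0.5, c + 0.5) x [r - 0.5, r + 0.5)`), not
#' point sampling — required for photon conservation. The window spans
#' `truncate_sigma` standard deviations; mass outside is dropped
#' (about 4e-9 at the default 6 sigma).
#'
#' @param x0,y0 Spot centre (pixel units, 1-based column/row).
#' @param sigma Gaussian standard deviation (px): FWHM / 2.3548.
#' @param truncate_sigma Window half-size in sigmas (default 6).
#' @return A list with the mass matrix `mass` and its pixel index vectors
#'   `rows`, `cols`.
#' @export
gaussian_spot <- function(x0, y0, sigma, truncate_sigma = 6) {
  .check_scalar(sigma, "sigma", min = 0, strict = TRUE)
  r <- ceiling(truncate_sigma * sigma)
  cols <- seq.int(round(x0) - r, round(x0) + r)
  rows <- seq.int(round(y0) - r, round(y0) + r)
  fx <- diff(stats::pnorm(c(cols[1] - 0.5, cols + 0.5), mean = x0, sd = sigma))
  fy <- diff(stats::pnorm(c(rows[1] - 0.5, rows + 0.5), mean = y0, sd = sigma))
  list(mass = outer(fy, fx), rows = rows, cols = cols)
}

fwhm_to_sigma <- function(fwhm_px) fwhm_px / (2 * sqrt(2 * log(2)))

# Apply the EMCCD detection chain to a matrix of expected photon counts.
# noise = FALSE gives the deterministic expectation: E * gain + baseline.
.apply_camera <- function(expected, camera, noise = TRUE) {
  if (!noise) return(expected * camera$em_gain + camera$baseline)
  n <- stats::rpois(length(expected), expected)
  out <- numeric(length(n))
  pos <- n > 0L
  if (any(pos))
    out[pos] <- stats::rgamma(sum(pos), shape = n[pos], scale = camera$em_gain)
  out <- out + camera$baseline
  if (camera$read_noise_sd > 0)
    out <- out + stats::rnorm(length(out), 0, camera$read_noise_sd)
  matrix(out, nrow(expected), ncol(expected))
}

.molecule_models <- function(model, n) {
  if (inherits(model, "kinetic_model") || inherits(model, "fret_model"))
    return(rep(list(model), n))
  if (is.list(model) && length(model) == n) return(model)
  invalid_arg("`model` must be a single model or a list with one model per molecule")
}

.check_positions <- function(molecules, layout, L, r_tr, n_extra_right = 0) {
  if (!is.data.frame(molecules) || !all(c("x", "y") %in% names(molecules)))
    invalid_arg("`molecules` must be a data frame with columns x and y")
  W <- layout$width_px
  H <- layout$height_px
  bad <- which(molecules$x - r_tr < 1 | molecules$x + L + r_tr > W |
                 molecules$y - r_tr < 1 | molecules$y + r_tr > H)
  if (length(bad))
    invalid_arg(sprintf(
      "molecule(s) %s sweep outside the channel sub-region (need %g px clearance)",
      paste(bad, collapse = ", "), L + r_tr))
  invisible(TRUE)
}

#' Render a swept (and optionally conventional) single-molecule movie
#'
#' Simulates each molecule's two-state trajectory, integrates expected photon
#' counts per sub-exposure, and renders frames: in the swept channel each
#' molecule appears as `n_steps` Gaussian spots at
#' `x + (s - 1) * spacing`, one per substep; in the conventional channel (if
#' the layout has one) as a single spot carrying the whole-exposure
#' integral. The beamsplitter fractions of the layout thin the photon flux
#' per channel (independent Poisson thinning). Pixel values then pass
#' through the EMCCD chain: Poisson photons, Gamma EM multiplication,
#' Gaussian read noise, baseline offset.
#'
#' @param molecules Data frame with columns `x`, `y`: spot positions in
#'   channel-local pixel coordinates (1-based, x = column). Every molecule
#'   needs `sweep_length + PSF` clearance from the channel's right edge.
#' @param model A [kinetic_model()] shared by all molecules, or a list of
#'   models, one per molecule.
#' @param config A [sweep_config()].
#' @param camera A [camera_model()].
#' @param layout A [channel_layout()] containing a `"swept"` channel and
#'   optionally a `"conventional"` one.
#' @param n_frames Number of frames to render.
#' @param seed Optional integer seed (set once; trajectories and noise then
#'   draw from one stream, so identical seeds give bit-identical stacks).
#' @param fwhm_px PSF full width at half maximum (px; default 2.56).
#' @param background_rate Background photon rate per pixel
#'   (photons/ms/px; default 0.05). Applied per channel without splitting.
#' @param noise Render stochastically (`TRUE`, default) or return expected
#'   values (`FALSE`).
#' @param psf_truncate_sigma PSF rendering window half-size in sigmas
#'   (default 6, keeping truncation error below 1e-8).
#' @return A list with `stack` (a [frame_stack()]) and `truth` (ground
#'   truth: positions, per-substep expected photons `expected`
#'   (n_frames x n_steps x n_molecules, before channel splitting),
#'   occupancies, trajectories, config, seed).
#' @export
render_swept_stack <- function(molecules, model, config, camera, layout,
                               n_frames, seed = NULL, fwhm_px = 2.56,
                               background_rate = 0.05, noise = TRUE,
                               psf_truncate_sigma = 6) {
  stopifnot(inherits(config, "sweep_config"), inherits(camera, "camera_model"),
            inherits(layout, "channel_layout"))
  if (!"swept" %in% layout$channels)
    invalid_arg("layout must contain a 'swept' channel")
  .check_scalar(n_frames, "n_frames", min = 1, integerish = TRUE)
  if (!is.null(seed)) set.seed(seed)

  M <- nrow(molecules)
  sigma <- fwhm_to_sigma(fwhm_px)
  r_tr <- ceiling(psf_truncate_sigma * sigma)
  L <- sweep_length_px(config)
  spacing <- spot_spacing_px(config)
  N <- config$n_steps
  .check_positions(molecules, layout, L, r_tr)
  models <- .molecule_models(model, M)

  period <- config$exposure_ms + config$frame_lag_ms
  duration <- n_frames * period
  trajectories <- lapply(models, simulate_state_trajectory,
                         duration_ms = duration)
  lam <- array(0, dim = c(n_frames, N, M))
  occ <- array(0, dim = c(n_frames, N, M))
  for (m in seq_len(M)) {
    lm_ <- integrate_substeps(trajectories[[m]], config, n_frames)
    lam[, , m] <- lm_
    occ[, , m] <- attr(lm_, "occupancy")
  }

  has_conv <- "conventional" %in% layout$channels
  f_swept <- layout$fractions[["swept"]]
  f_conv <- if (has_conv) layout$fractions[["conventional"]] else 0
  off_swept <- channel_offset(layout, "swept")
  off_conv <- if (has_conv) channel_offset(layout, "conventional") else NA

  # spot positions are static: precompute pixel masses once per molecule
  swept_spots <- lapply(seq_len(M), function(m) {
    lapply(seq_len(N), function(s) {
      sp <- gaussian_spot(molecules$x[m] + (s - 1) * spacing + off_swept,
                          molecules$y[m], sigma, psf_truncate_sigma)
      sp
    })
  })
  conv_spots <- if (has_conv) {
    lapply(seq_len(M), function(m)
      gaussian_spot(molecules$x[m] + off_conv, molecules$y[m], sigma,
                    psf_truncate_sigma))
  }

  H <- layout$height_px
  W_total <- length(layout$channels) * layout$width_px
  bg <- background_rate * config$exposure_ms
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    E <- matrix(bg, H, W_total)
    for (m in seq_len(M)) {
      if (has_conv) {
        sp <- conv_spots[[m]]
        E[sp$rows, sp$cols] <- E[sp$rows, sp$cols] +
          f_conv * sum(lam[f, , m]) * sp$mass
      }
      for (s in seq_len(N)) {
        sp <- swept_spots[[m]][[s]]
        E[sp$rows, sp$cols] <- E[sp$rows, sp$cols] +
          f_swept * lam[f, s, m] * sp$mass
      }
    }
    frames[[f]] <- .apply_camera(E, camera, noise)
  }

  stack <- frame_stack(frames, exposure_ms = config$exposure_ms,
                       pixel_size_um = camera$pixel_size_um, layout = layout,
                       sweep = config,
                       meta = list(seed = seed, kind = "swept"))
  truth <- structure(
    list(positions = data.frame(molecule = seq_len(M), x = molecules$x,
                                y = molecules$y,
                                x_abs = molecules$x + off_swept,
                                y_abs = molecules$y),
         expected = lam, occupancy = occ, trajectories = trajectories,
         config = config, camera = camera, layout = layout,
         fwhm_px = fwhm_px, background_rate = background_rate, seed = seed),
    class = "ground_truth")
  list(stack = stack, truth = truth)
}

#' Render a swept two-colour FRET movie
#'
#' Donor and acceptor channels side by side, both swept. Each substep's total
#' photons are partitioned by the window's true FRET efficiency (donor
#' `1 - E`, acceptor `E`), then `leakage` times the detected donor photons
#' are added to the acceptor channel. The first `n_unswept_lead_frames`
#' frames are rendered without sweeping (single spot per molecule carrying
#' the whole-frame integral); they are used downstream for mapping and
#' molecule selection.
#'
#' @inheritParams render_swept_stack
#' @param model A [fret_model()] or list of them.
#' @param layout A [channel_layout()] with `"donor"` and `"acceptor"`
#'   channels; default built from `region_px`.
#' @param region_px Width/height (px) of each channel when `layout` is NULL.
#' @param n_frames Number of swept frames (excluding the lead frames).
#' @param n_unswept_lead_frames Unswept frames rendered first (default 10).
#' @return A list with `stack` and `truth`; `truth$fret` holds per-substep
#'   expected donor/acceptor photons and true efficiency for the swept
#'   frames, `truth$lead` the per-frame expectations of the lead frames.
#' @export
render_fret_stack <- function(molecules, model, config, camera,
                              n_frames, n_unswept_lead_frames = 10,
                              seed = NULL, fwhm_px = 2.56,
                              background_rate = 0.05, noise = TRUE,
                              psf_truncate_sigma = 6, layout = NULL,
                              region_px = c(64, 64)) {
  stopifnot(inherits(config, "sweep_config"), inherits(camera, "camera_model"))
  if (is.null(layout))
    layout <- channel_layout(region_px[1], region_px[2],
                             c("donor", "acceptor"), c(1, 1))
  if (!all(c("donor", "acceptor") %in% layout$channels))
    invalid_arg("FRET layout needs 'donor' and 'acceptor' channels")
  .check_scalar(n_frames, "n_frames", min = 1, integerish = TRUE)
  .check_scalar(n_unswept_lead_frames, "n_unswept_lead_frames", min = 0,
                integerish = TRUE)
  if (!is.null(seed)) set.seed(seed)

  M <- nrow(molecules)
  sigma <- fwhm_to_sigma(fwhm_px)
  r_tr <- ceiling(psf_truncate_sigma * sigma)
  L <- sweep_length_px(config)
  spacing <- spot_spacing_px(config)
  N <- config$n_steps
  .check_positions(molecules, layout, L, r_tr)
  models <- .molecule_models(model, M)

  period <- config$exposure_ms + config$frame_lag_ms
  n_total <- n_frames + n_unswept_lead_frames
  duration <- n_total * period
  trajectories <- lapply(models, simulate_state_trajectory,
                         duration_ms = duration)
  donor <- array(0, dim = c(n_total, N, M))
  acceptor <- array(0, dim = c(n_total, N, M))
  eff <- array(0, dim = c(n_total, N, M))
  for (m in seq_len(M)) {
    fx <- fret_expected_photons(trajectories[[m]], config, n_total)
    donor[, , m] <- fx$donor
    acceptor[, , m] <- fx$acceptor
    eff[, , m] <- fx$efficiency
  }

  off_d <- channel_offset(layout, "donor")
  off_a <- channel_offset(layout, "acceptor")
  spot_at <- function(xoff, m, s) {
    gaussian_spot(molecules$x[m] + (s - 1) * spacing + xoff, molecules$y[m],
                  sigma, psf_truncate_sigma)
  }
  d_spots <- lapply(seq_len(M), function(m)
    lapply(seq_len(N), function(s) spot_at(off_d, m, s)))
  a_spots <- lapply(seq_len(M), function(m)
    lapply(seq_len(N), function(s) spot_at(off_a, m, s)))

  H <- layout$height_px
  W_total <- length(layout$channels) * layout$width_px
  bg <- background_rate * config$exposure_ms
  frames <- vector("list", n_total)
  for (f in seq_len(n_total)) {
    E <- matrix(bg, H, W_total)
    lead <- f <= n_unswept_lead_frames
    for (m in seq_len(M)) {
      if (lead) {
        spd <- d_spots[[m]][[1]]
        spa <- a_spots[[m]][[1]]
        E[spd$rows, spd$cols] <- E[spd$rows, spd$cols] +
          sum(donor[f, , m]) * spd$mass
        E[spa$rows, spa$cols] <- E[spa$rows, spa$cols] +
          sum(acceptor[f, , m]) * spa$mass
      } else {
        for (s in seq_len(N)) {
          spd <- d_spots[[m]][[s]]
          spa <- a_spots[[m]][[s]]
          E[spd$rows, spd$cols] <- E[spd$rows, spd$cols] +
            donor[f, s, m] * spd$mass
          E[spa$rows, spa$cols] <- E[spa$rows, spa$cols] +
            acceptor[f, s, m] * spa$mass
        }
      }
    }
    frames[[f]] <- .apply_camera(E, camera, noise)
  }

  swept_idx <- n_unswept_lead_frames + seq_len(n_frames)
  stack <- frame_stack(frames, exposure_ms = config$exposure_ms,
                       pixel_size_um = camera$pixel_size_um, layout = layout,
                       sweep = config,
                       meta = list(seed = seed, kind = "fret",
                                   n_unswept_lead_frames = n_unswept_lead_frames))
  truth <- structure(
    list(positions = data.frame(molecule = seq_len(M), x = molecules$x,
                                y = molecules$y,
                                x_abs = molecules$x + off_d,
                                y_abs = molecules$y),
         fret = list(donor = donor[swept_idx, , , drop = FALSE],
                     acceptor = acceptor[swept_idx, , , drop = FALSE],
                     efficiency = eff[swept_idx, , , drop = FALSE]),
         lead = list(donor = donor[seq_len(n_unswept_lead_frames), , ,
                                   drop = FALSE],
                     acceptor = acceptor[seq_len(n_unswept_lead_frames), , ,
                                         drop = FALSE]),
         trajectories = trajectories, config = config, camera = camera,
         layout = layout, fwhm_px = fwhm_px,
         background_rate = background_rate, seed = seed),
    class = "ground_truth")
  list(stack = stack, truth = truth)
}
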