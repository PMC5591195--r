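# Voltage-to-pixel calibration from bead stacks swept at several voltages.

#' Render a calibration bead stack
#'
#' Fluorescent beads are constantly bright; swept at voltage `voltage_mV`
#' they draw the full N-spot ladder whose first-to-last distance measures
#' the sweep length.
#'
#' @param positions Data frame `x`, `y` of bead positions (channel-local).
#' @param voltage_mV Sweep voltage (mV).
#' @param config Base [sweep_config()] whose voltage is replaced.
#' @param camera A [camera_model()].
#' @param layout Single-channel layout; default sized to fit.
#' @param n_frames Frames to render (default 5).
#' @param seed,photon_rate,fwhm_px,background_rate,noise Rendering controls.
#' @return A [frame_stack()].
#' @export
render_bead_stack <- function(positions, voltage_mV, config, camera,
                              layout = NULL, n_frames = 5, seed = NULL,
                              photon_rate = 50, fwhm_px = 2.56,
                              background_rate = 0.05, noise = TRUE) {
  cfg <- sweep_config(config$n_steps, voltage_mV, config$slope_px_per_mV,
                      config$exposure_ms, config$frame_lag_ms)
  if (is.null(layout)) {
    r <- ceiling(6 * fwhm_to_sigma(fwhm_px)) + 2
    layout <- channel_layout(
      ceiling(max(positions$x) + sweep_length_px(cfg) + r),
      ceiling(max(positions$y) + r), "swept", 1)
  }
  beads <- kinetic_model(k_on = 0, k_off = 0, bright_rate = photon_rate)
  render_swept_stack(positions, beads, cfg, camera, layout, n_frames,
                     seed = seed, fwhm_px = fwhm_px,
                     background_rate = background_rate, noise = noise)$stack
}

#' Calibrate the voltage-to-pixel sweep slope from bead stacks
#'
#' For each voltage the average image is spot-detected, spots are grouped
#' into per-bead sweep ladders (single-linkage clustering on proximity),
#' and the total sweep length L is measured as the first-to-last spot
#' distance along x, averaged over beads. L is then regressed on voltage
#' through the origin; the slope is the calibration constant in pixel/mV.
#'
#' @param bead_stacks Named list mapping voltage (names, mV) to
#'   [frame_stack()] objects (or plain matrices). At least 3 voltages
#'   including 0 are required.
#' @param detect_args Extra arguments for [detect_spots()].
#' @param residual_tol Maximum allowed residual RMS relative to the largest
#'   measured L (default 0.05) before the fit is declared nonlinear.
#' @param cluster_gap_px Spot-to-spot linking distance when grouping a
#'   bead's ladder (default 1.5 x the largest expected spacing, estimated
#'   from the data).
#' @param min_rel_brightness Peaks dimmer than this fraction of the
#'   brightest peak in the image are discarded as noise (default 0.3;
#'   beads are uniformly bright, camera-noise maxima are much dimmer).
#' @return A list of class `sweep_calibration`: `slope_px_per_mV`,
#'   `residual_rms_px`, `per_voltage` (data frame voltage, L, n_beads).
#' @export
calibrate_sweep <- function(bead_stacks, detect_args = list(),
                            residual_tol = 0.05, cluster_gap_px = NULL,
                            min_rel_brightness = 0.3) {
  if (is.null(names(bead_stacks)) || any(names(bead_stacks) == ""))
    invalid_arg("`bead_stacks` must be a named list, names = voltage in mV")
  voltages <- as.numeric(names(bead_stacks))
  if (any(is.na(voltages))) invalid_arg("stack names must be numeric voltages")
  if (length(voltages) < 3)
    insufficient_data("need bead stacks at >= 3 voltages")
  if (!any(voltages == 0))
    insufficient_data("a 0 mV reference stack is required")

  measure_L <- function(stack) {
    img <- if (inherits(stack, "frame_stack")) average_frames(stack) else stack
    peaks <- do.call(detect_spots, c(list(img, min_separation_px = 0),
                                     detect_args))
    if (nrow(peaks) > 0)
      peaks <- peaks[peaks$peak_value >=
                       min_rel_brightness * max(peaks$peak_value), ,
                     drop = FALSE]
    if (nrow(peaks) == 0) return(c(NA_real_, 0))
    # single-linkage grouping of each bead's spot ladder
    gap <- cluster_gap_px
    if (is.null(gap)) gap <- max(8, diff(range(peaks$x)) / 2)
    if (nrow(peaks) == 1) {
      grp <- 1L
    } else {
      d <- stats::dist(cbind(peaks$x / gap, peaks$y / 3))
      grp <- stats::cutree(stats::hclust(d, method = "single"), h = 1)
    }
    Ls <- tapply(peaks$x, grp, function(x) max(x) - min(x))
    c(mean(Ls), length(Ls))
  }

  meas <- t(vapply(bead_stacks, measure_L, numeric(2)))
  per_voltage <- data.frame(voltage_mV = voltages, L_px = meas[, 1],
                            n_beads = as.integer(meas[, 2]))
  if (any(!is.finite(per_voltage$L_px)))
    calibration_failure("no beads detected in at least one stack")

  fit <- stats::lm(L_px ~ 0 + voltage_mV, data = per_voltage)
  slope <- as.numeric(stats::coef(fit))
  rms <- sqrt(mean(stats::residuals(fit)^2))
  Lmax <- max(per_voltage$L_px)
  if (Lmax > 0 && rms > residual_tol * Lmax)
    calibration_failure(sprintf(
      "sweep length is not linear in voltage (residual RMS %.3g px over L_max %.3g px)",
      rms, Lmax))
  structure(list(slope_px_per_mV = slope, residual_rms_px = rms,
                 per_voltage = per_voltage),
            class = "sweep_calibration")
}

#' @export
print.sweep_calibration <- function(x, ...) {
  cat(sprintf("<sweep_calibration> slope = %.4g px/mV (residual RMS %.3g px)\n",
              x$slope_px_per_mV, x$residual_rms_px))
  print(x$per_voltage, row.names = FALSE)
  invisible(x)
}
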