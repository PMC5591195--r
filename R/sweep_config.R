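#' Sweep configuration
#'
#' Geometry and timing of the spatial encoding. During one camera exposure of
#' `exposure_ms` milliseconds the galvo mirror is stepped `n_steps` times,
#' displacing the image horizontally (towards increasing column index). The
#' mirror deflection is proportional to the applied voltage with calibration
#' slope `slope_px_per_mV`, so the total sweep length in pixels is
#' `slope_px_per_mV * voltage_mV` and adjacent sub-exposure spots are
#' `slope_px_per_mV * voltage_mV / (n_steps - 1)` pixels apart.
#'
#' @param n_steps Number of mirror steps N per exposure (integer, >= 1).
#' @param voltage_mV Voltage amplitude of the final step (mV, >= 0).
#' @param slope_px_per_mV Calibration slope converting galvo voltage to image
#'   displacement (pixel/mV; default 0.25, the value measured with fluorescent
#'   beads on the reference instrument).
#' @param exposure_ms Camera exposure per frame (ms, > 0; default 20).
#' @param frame_lag_ms Inter-frame dead time during which no photons are
#'   collected (ms, >= 0; default 1.7).
#'
#' @return An object of class `sweep_config`.
#' @seealso [substep_ms()], [sweep_length_px()], [spot_spacing_px()],
#'   [separation_ok()]
#' @export
#' @examples
#' cfg <- sweep_config(n_steps = 5, voltage_mV = 96)
#' substep_ms(cfg)       # 4 ms sub-frame resolution
#' sweep_length_px(cfg)  # 24 px total sweep
#' spot_spacing_px(cfg)  # 6 px between adjacent spots
sweep_config <- function(n_steps, voltage_mV, slope_px_per_mV = 0.25,
                         exposure_ms = 20, frame_lag_ms = 1.7) {
  .check_scalar(n_steps, "n_steps", min = 1, integerish = TRUE)
  .check_scalar(voltage_mV, "voltage_mV", min = 0)
  .check_scalar(slope_px_per_mV, "slope_px_per_mV", min = 0)
  .check_scalar(exposure_ms, "exposure_ms", min = 0, strict = TRUE)
  .check_scalar(frame_lag_ms, "frame_lag_ms", min = 0)
  structure(
    list(n_steps = as.integer(n_steps), voltage_mV = voltage_mV,
         slope_px_per_mV = slope_px_per_mV, exposure_ms = exposure_ms,
         frame_lag_ms = frame_lag_ms, sweep_axis = "x"),
    class = "sweep_config")
}

#' @export
print.sweep_config <- function(x, ...) {
  cat(sprintf(
    "<sweep_config> N = %d steps, V = %g mV, slope = %g px/mV\n", x$n_steps,
    x$voltage_mV, x$slope_px_per_mV))
  cat(sprintf("  exposure %g ms + lag %g ms; substep %g ms; sweep %g px; spacing %g px\n",
              x$exposure_ms, x$frame_lag_ms, substep_ms(x),
              sweep_length_px(x), spot_spacing_px(x)))
  invisible(x)
}

#' Sub-frame time resolution of a sweep configuration
#'
#' @param config A [sweep_config()].
#' @return Duration of one sub-exposure, `exposure_ms / n_steps` (ms).
#' @export
substep_ms <- function(config) {
  stopifnot(inherits(config, "sweep_config"))
  config$exposure_ms / config$n_steps
}

#' Total sweep length of a configuration (pixels)
#'
#' @param config A [sweep_config()].
#' @return `slope_px_per_mV * voltage_mV` (px).
#' @export
sweep_length_px <- function(config) {
  stopifnot(inherits(config, "sweep_config"))
  voltage_to_sweep_px(config$voltage_mV, config$slope_px_per_mV)
}

#' Spacing between adjacent swept spots (pixels)
#'
#' @param config A [sweep_config()].
#' @return `sweep_length_px(config) / (n_steps - 1)`, or 0 for a single step.
#' @export
spot_spacing_px <- function(config) {
  stopifnot(inherits(config, "sweep_config"))
  if (config$n_steps < 2L) return(0)
  sweep_length_px(config) / (config$n_steps - 1L)
}

#' Staircase voltage waveform driving the galvo mirror
#'
#' The function generator raises the voltage from 0 to `voltage_mV` in
#' `voltage_mV / (n_steps - 1)` increments, one step per sub-exposure.
#'
#' @param n_steps Number of steps N (integer, >= 1).
#' @param voltage_mV Final-step voltage V (mV, >= 0).
#' @return Numeric vector of length `n_steps`, equally spaced from 0 to
#'   `voltage_mV` inclusive; `0` alone when `n_steps == 1`.
#' @export
#' @examples
#' make_step_waveform(5, 96)  # 0 24 48 72 96
make_step_waveform <- function(n_steps, voltage_mV) {
  .check_scalar(n_steps, "n_steps", min = 1, integerish = TRUE)
  .check_scalar(voltage_mV, "voltage_mV", min = 0)
  if (n_steps == 1) return(0)
  seq(0, voltage_mV, length.out = n_steps)
}

#' Convert galvo voltage to sweep displacement
#'
#' @param voltage_mV Applied voltage (mV, >= 0).
#' @param slope_px_per_mV Calibration slope (pixel/mV, >= 0).
#' @return Displacement in pixels, `voltage_mV * slope_px_per_mV`.
#' @export
#' @examples
#' voltage_to_sweep_px(96, 0.25)   # 24 px
#' voltage_to_sweep_px(112, 0.25)  # 28 px
voltage_to_sweep_px <- function(voltage_mV, slope_px_per_mV) {
  .check_scalar(voltage_mV, "voltage_mV", min = 0)
  .check_scalar(slope_px_per_mV, "slope_px_per_mV", min = 0)
  voltage_mV * slope_px_per_mV
}

#' Sub-frame time resolution from exposure and step count
#'
#' @param exposure_ms Frame exposure (ms, > 0).
#' @param n_steps Number of mirror steps (integer, >= 1).
#' @return `exposure_ms / n_steps` (ms).
#' @export
#' @examples
#' substep_resolution_ms(20, 5)  # 4 ms
#' substep_resolution_ms(20, 4)  # 5 ms
substep_resolution_ms <- function(exposure_ms, n_steps) {
  .check_scalar(exposure_ms, "exposure_ms", min = 0, strict = TRUE)
  .check_scalar(n_steps, "n_steps", min = 1, integerish = TRUE)
  exposure_ms / n_steps
}

#' Spot-separation feasibility criterion
#'
#' Adjacent swept spots must be well separated for unambiguous decoding: the
#' spacing `slope * V / (N - 1)` should be at least `factor` times the PSF
#' full width at half maximum (by default double the FWHM). Equality counts as
#' separated, tested with a small relative tolerance so that exact boundary
#' configurations are accepted deterministically.
#'
#' @param config A [sweep_config()] with `n_steps >= 2`.
#' @param fwhm_px PSF full width at half maximum (px, > 0).
#' @param factor Required spacing in units of FWHM (default 2).
#' @param rel_tol Relative tolerance applied at the boundary (default 1e-9).
#' @return `TRUE` if the spacing satisfies the criterion, else `FALSE`.
#' @export
#' @examples
#' separation_ok(sweep_config(5, 96), fwhm_px = 2.56)  # TRUE: 6 px >= 5.12 px
separation_ok <- function(config, fwhm_px, factor = 2.0, rel_tol = 1e-9) {
  stopifnot(inherits(config, "sweep_config"))
  .check_scalar(fwhm_px, "fwhm_px", min = 0, strict = TRUE)
  .check_scalar(factor, "factor", min = 0, strict = TRUE)
  if (config$n_steps < 2L)
    invalid_arg("spot spacing is undefined for n_steps < 2")
  spot_spacing_px(config) >= factor * fwhm_px * (1 - rel_tol)
}

#' Serialize / deserialize a sweep configuration
#'
#' `sweep_config_to_list()` returns the flat list used in sidecar metadata and
#' YAML/JSON run configs; `sweep_config_from_list()` rebuilds the object and
#' validates it.
#'
#' @param config A [sweep_config()].
#' @param x A named list with keys `n_steps`, `voltage_mV`, `slope_px_per_mV`,
#'   `exposure_ms`, `frame_lag_ms`.
#' @return A plain named list, or a `sweep_config`.
#' @export
sweep_config_to_list <- function(config) {
  stopifnot(inherits(config, "sweep_config"))
  config[c("n_steps", "voltage_mV", "slope_px_per_mV", "exposure_ms",
           "frame_lag_ms")]
}

#' @rdname sweep_config_to_list
#' @export
sweep_config_from_list <- function(x) {
  need <- c("n_steps", "voltage_mV", "slope_px_per_mV", "exposure_ms",
            "frame_lag_ms")
  missing <- setdiff(need, names(x))
  if (length(missing))
    validation_error(paste0("sweep config block missing key(s): ",
                            paste(missing, collapse = ", ")))
  sweep_config(x$n_steps, x$voltage_mV, x$slope_px_per_mV, x$exposure_ms,
               x$frame_lag_ms)
}
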