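# Scenario presets mirroring the three reference experiments:
# dye photoblinking, transient DNA binding, Holliday-junction FRET.

#' Built-in simulation scenarios
#'
#' Three presets bundle the sweep configuration, kinetic model, camera and
#' channel layout of the experiments the method was demonstrated on:
#'
#' * `"blinking"` — dye photoblinking at low Trolox: N = 5 steps, 96 mV,
#'   20 ms exposure (4-ms substeps); k_on = 217 s^-1 (mean off-time
#'   4.6 ms), k_off = 80 s^-1; conventional|swept 30:70 layout.
#' * `"binding"` — transient hybridization of a 7-bp (1-mismatch) DNA
#'   strand: N = 5, 112 mV (28-px sweep, 7-px spacing); k_off = 130 s^-1
#'   (mean on-time 7.7 ms), sparse binding at k_on = 3 s^-1.
#' * `"fret"` — Holliday-junction conformational dynamics: N = 4, 96 mV
#'   (5-ms substeps), 10 unswept lead frames; symmetric two-state FRET
#'   with k_12 = k_21 = 61.1 s^-1, i.e. 61.1 conformational transitions
#'   per second (mean dwell 16.4 ms per conformer), E = 0.25/0.75.
#'
#' Photon-budget parameters (bright rate 30 photons/ms, background
#' 0.05 photons/ms/px, EM gain 30, read noise 10 counts) are chosen so the
#' 4-ms-substep signal-to-noise lands in the high-single-digit range
#' typical of fast EMCCD single-molecule imaging.
#'
#' @param scenario One of `"blinking"`, `"binding"`, `"fret"`.
#' @return A list with elements `config` ([sweep_config()]), `model`,
#'   `camera`, `layout_channels`, `layout_fractions`, `fwhm_px`,
#'   `background_rate`, and (FRET) `n_unswept_lead_frames`.
#' @export
scenario_preset <- function(scenario = c("blinking", "binding", "fret")) {
  scenario <- match.arg(scenario)
  camera <- camera_model(em_gain = 30, read_noise_sd = 10, baseline = 100)
  switch(scenario,
    blinking = list(
      scenario = "blinking",
      config = sweep_config(n_steps = 5, voltage_mV = 96),
      model = kinetic_model(k_on = 217, k_off = 80, bright_rate = 30),
      camera = camera,
      layout_channels = c("conventional", "swept"),
      layout_fractions = c(0.3, 0.7),
      fwhm_px = 2.56, background_rate = 0.05),
    binding = list(
      scenario = "binding",
      config = sweep_config(n_steps = 5, voltage_mV = 112),
      model = kinetic_model(k_on = 3, k_off = 130, bright_rate = 30),
      camera = camera,
      layout_channels = c("conventional", "swept"),
      layout_fractions = c(0.3, 0.7),
      fwhm_px = 2.56, background_rate = 0.05),
    fret = list(
      scenario = "fret",
      config = sweep_config(n_steps = 4, voltage_mV = 96),
      model = fret_model(k_12 = 61.1, k_21 = 61.1, E_1 = 0.25, E_2 = 0.75,
                         total_rate = 30, leakage = 0.1),
      camera = camera,
      layout_channels = c("donor", "acceptor"),
      layout_fractions = c(1, 1),
      fwhm_px = 2.56, background_rate = 0.05,
      n_unswept_lead_frames = 10))
}

#' Lay out a grid of well-separated molecules for a preset
#'
#' Places `n_molecules` in vertical lanes with `lane_px` spacing, all at
#' the same x so every molecule has full sweep clearance; sizes the channel
#' sub-region accordingly.
#'
#' @param preset A [scenario_preset()].
#' @param n_molecules Number of molecules.
#' @param lane_px Vertical lane spacing (default 10 px).
#' @return A list with `molecules` (data frame x, y) and `layout`
#'   (a [channel_layout()]).
#' @export
preset_geometry <- function(preset, n_molecules, lane_px = 10) {
  sigma <- fwhm_to_sigma(preset$fwhm_px)
  r_tr <- ceiling(6 * sigma) + 1
  L <- sweep_length_px(preset$config)
  x0 <- r_tr + 2
  width <- ceiling(x0 + L + r_tr + 2)
  height <- n_molecules * lane_px + lane_px
  molecules <- data.frame(x = rep(x0, n_molecules),
                          y = lane_px * seq_len(n_molecules))
  layout <- channel_layout(width, height, preset$layout_channels,
                           preset$layout_fractions)
  list(molecules = molecules, layout = layout)
}

#' Simulate a full scenario movie
#'
#' Convenience wrapper: builds the preset geometry and renders the stack.
#'
#' @param scenario `"blinking"`, `"binding"` or `"fret"`.
#' @param n_frames Number of (swept) frames.
#' @param seed Integer seed.
#' @param n_molecules Number of molecules (default 8).
#' @param noise Render stochastically (default TRUE).
#' @return As [render_swept_stack()] / [render_fret_stack()]: a list with
#'   `stack` and `truth`.
#' @export
simulate_scenario <- function(scenario, n_frames, seed, n_molecules = 8,
                              noise = TRUE) {
  preset <- scenario_preset(scenario)
  geom <- preset_geometry(preset, n_molecules)
  if (identical(preset$scenario, "fret")) {
    render_fret_stack(geom$molecules, preset$model, preset$config,
                      preset$camera, n_frames = n_frames,
                      n_unswept_lead_frames = preset$n_unswept_lead_frames,
                      seed = seed, fwhm_px = preset$fwhm_px,
                      background_rate = preset$background_rate, noise = noise,
                      layout = geom$layout)
  } else {
    render_swept_stack(geom$molecules, preset$model, preset$config,
                       preset$camera, geom$layout, n_frames = n_frames,
                       seed = seed, fwhm_px = preset$fwhm_px,
                       background_rate = preset$background_rate, noise = noise)
  }
}
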