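#' Two-state kinetic model of a blinking or binding molecule
#'
#' A continuous-time telegraph process alternating between a dark (or
#' unbound) state and a bright (bound) state. Dwell times are exponential:
#' mean dark dwell 1/k_on, mean bright dwell 1/k_off. The bright state emits
#' detected photons at `bright_rate` photons/ms, the dark state at
#' `dark_rate` (usually 0).
#'
#' @param k_on Dark-to-bright (unbound-to-bound) rate (s^-1, >= 0).
#' @param k_off Bright-to-dark rate (s^-1, >= 0); the mean on-time is
#'   `1000 / k_off` ms.
#' @param bright_rate Detected photon rate in the bright state (photons/ms;
#'   must exceed `dark_rate`).
#' @param dark_rate Photon rate in the dark state (photons/ms, default 0).
#' @return An object of class `kinetic_model`.
#' @export
#' @examples
#' kinetic_model(k_on = 217, k_off = 80, bright_rate = 30)
kinetic_model <- function(k_on, k_off, bright_rate, dark_rate = 0) {
  .check_scalar(k_on, "k_on", min = 0)
  .check_scalar(k_off, "k_off", min = 0)
  .check_scalar(bright_rate, "bright_rate", min = 0)
  .check_scalar(dark_rate, "dark_rate", min = 0)
  if (bright_rate <= dark_rate)
    invalid_arg("`bright_rate` must exceed `dark_rate`")
  structure(list(k_on = k_on, k_off = k_off, bright_rate = bright_rate,
                 dark_rate = dark_rate),
            class = "kinetic_model")
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat(sprintf("<kinetic_model> k_on = %g /s, k_off = %g /s (tau_on = %.3g ms, tau_off = %.3g ms)\n",
              x$k_on, x$k_off, 1000 / x$k_off, 1000 / x$k_on))
  cat(sprintf("  bright %g ph/ms, dark %g ph/ms\n", x$bright_rate, x$dark_rate))
  invisible(x)
}

#' Two-state FRET model
#'
#' A molecule interconverting between two conformations with true FRET
#' efficiencies `E_1` and `E_2` at rates `k_12` (1 -> 2) and `k_21` (2 -> 1).
#' Total detected photon flux (donor + acceptor) is `total_rate` photons/ms;
#' a fraction `leakage` of detected donor photons additionally appears in the
#' acceptor channel (spectral crosstalk).
#'
#' @param k_12,k_21 Interconversion rates between conformations (s^-1, >= 0).
#' @param E_1,E_2 True FRET efficiencies of the two states, in `[0, 1]` and
#'   distinct.
#' @param total_rate Summed donor + acceptor photon rate (photons/ms, > 0).
#' @param leakage Donor-to-acceptor crosstalk fraction in `[0, 1)`
#'   (default 0).
#' @return An object of class `fret_model`.
#' @export
#' @examples
#' fret_model(k_12 = 30.5, k_21 = 30.5, E_1 = 0.25, E_2 = 0.75,
#'            total_rate = 30, leakage = 0.1)
fret_model <- function(k_12, k_21, E_1, E_2, total_rate, leakage = 0) {
  .check_scalar(k_12, "k_12", min = 0)
  .check_scalar(k_21, "k_21", min = 0)
  .check_scalar(E_1, "E_1", min = 0)
  .check_scalar(E_2, "E_2", min = 0)
  if (E_1 > 1 || E_2 > 1) invalid_arg("FRET efficiencies must lie in [0, 1]")
  if (E_1 == E_2) invalid_arg("`E_1` and `E_2` must differ")
  .check_scalar(total_rate, "total_rate", min = 0, strict = TRUE)
  .check_scalar(leakage, "leakage", min = 0)
  if (leakage >= 1) invalid_arg("`leakage` must be < 1")
  structure(list(k_12 = k_12, k_21 = k_21, E_1 = E_1, E_2 = E_2,
                 total_rate = total_rate, leakage = leakage),
            class = "fret_model")
}

#' @export
print.fret_model <- function(x, ...) {
  cat(sprintf("<fret_model> k_12 = %g /s, k_21 = %g /s; E = %g / %g; %g ph/ms; leakage %g\n",
              x$k_12, x$k_21, x$E_1, x$E_2, x$total_rate, x$leakage))
  invisible(x)
}

#' EMCCD camera model
#'
#' Parameters of the detection chain applied after Poisson photon statistics:
#' electron-multiplying gain (modelled as Gamma-distributed multiplication,
#' the standard EMCCD excess-noise model), additive Gaussian read noise, and
#' a constant digitizer baseline.
#'
#' @param em_gain Mean multiplication gain (counts/photon, > 0; default 30).
#' @param read_noise_sd Read noise standard deviation (counts, >= 0;
#'   default 10).
#' @param baseline Digitizer offset (counts, >= 0; default 100).
#' @param pixel_size_um Physical pixel pitch in the sample plane (micron;
#'   default 68/512 = 0.1328, a 68 um field imaged on 512 px).
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(em_gain = 30, read_noise_sd = 10, baseline = 100,
                         pixel_size_um = 68 / 512) {
  .check_scalar(em_gain, "em_gain", min = 0, strict = TRUE)
  .check_scalar(read_noise_sd, "read_noise_sd", min = 0)
  .check_scalar(baseline, "baseline", min = 0)
  .check_scalar(pixel_size_um, "pixel_size_um", min = 0, strict = TRUE)
  structure(list(em_gain = em_gain, read_noise_sd = read_noise_sd,
                 baseline = baseline, pixel_size_um = pixel_size_um),
            class = "camera_model")
}

#' Dual-channel chip layout
#'
#' Describes how the camera chip is split into side-by-side sub-regions of
#' equal width and what each carries. Two layouts are used in practice:
#' a 30:70 beamsplitter sending 30% of the light to a conventional
#' (unswept) channel and 70% to the swept channel, and a FRET layout where
#' the swept beam is split by a dichroic into donor and acceptor channels
#' (each receiving its own photons, fractions 1).
#'
#' @param width_px,height_px Size of each channel sub-region (px).
#' @param channels Character vector naming the channels left to right; each
#'   of `"conventional"`, `"swept"`, `"donor"`, `"acceptor"` at most once.
#' @param fractions Numeric photon fraction routed to each channel (same
#'   length as `channels`).
#' @return An object of class `channel_layout`.
#' @export
#' @examples
#' channel_layout(64, 64)  # conventional | swept at 30:70
#' channel_layout(64, 64, c("donor", "acceptor"), c(1, 1))
channel_layout <- function(width_px, height_px,
                           channels = c("conventional", "swept"),
                           fractions = c(0.3, 0.7)) {
  .check_scalar(width_px, "width_px", min = 1, integerish = TRUE)
  .check_scalar(height_px, "height_px", min = 1, integerish = TRUE)
  channels <- match.arg(channels,
                        c("conventional", "swept", "donor", "acceptor"),
                        several.ok = TRUE)
  if (anyDuplicated(channels)) invalid_arg("duplicate channel names")
  if (length(fractions) != length(channels) || any(fractions < 0))
    invalid_arg("`fractions` must be non-negative, one per channel")
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 channels = channels,
                 fractions = stats::setNames(as.numeric(fractions), channels)),
            class = "channel_layout")
}

#' Column offset of a named channel within the full frame
#'
#' @param layout A [channel_layout()].
#' @param channel Channel name.
#' @return Integer column offset (0 for the leftmost channel): channel-local
#'   column `j` sits at full-frame column `offset + j`.
#' @export
channel_offset <- function(layout, channel) {
  stopifnot(inherits(layout, "channel_layout"))
  i <- match(channel, layout$channels)
  if (is.na(i)) invalid_arg(sprintf("layout has no channel '%s'", channel))
  (i - 1L) * layout$width_px
}

#' Extract one channel sub-image from a full frame
#'
#' @param frame A matrix (rows = y, columns = x).
#' @param layout A [channel_layout()].
#' @param channel Channel name.
#' @return The `height_px` x `width_px` sub-matrix of that channel.
#' @export
channel_image <- function(frame, layout, channel) {
  off <- channel_offset(layout, channel)
  frame[seq_len(layout$height_px), off + seq_len(layout$width_px),
        drop = FALSE]
}
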