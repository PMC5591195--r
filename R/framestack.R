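#' Time-ordered stack of 2-D images
#'
#' The in-memory carrier for simulated or loaded movies: a list of numeric
#' matrices (rows = y, columns = x) sharing dimensions, plus acquisition
#' metadata.
#'
#' @param frames List of numeric matrices of identical dimensions (>= 1).
#' @param exposure_ms Frame exposure (ms).
#' @param pixel_size_um Pixel pitch (micron).
#' @param layout A [channel_layout()] (or NULL for a plain stack).
#' @param sweep A [sweep_config()] (or NULL for unswept data).
#' @param meta Free-form metadata list (seed, provenance, ...).
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, exposure_ms, pixel_size_um, layout = NULL,
                        sweep = NULL, meta = list()) {
  if (!is.list(frames) || length(frames) < 1L)
    invalid_arg("`frames` must be a non-empty list of matrices")
  d <- dim(frames[[1]])
  ok <- vapply(frames, function(f) is.matrix(f) && identical(dim(f), d),
               logical(1))
  if (!all(ok)) invalid_arg("all frames must be matrices of equal dimensions")
  structure(list(frames = frames, exposure_ms = exposure_ms,
                 pixel_size_um = pixel_size_um, layout = layout,
                 sweep = sweep, meta = meta),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_stack> %d frames of %d x %d px, exposure %g ms\n",
              length(x$frames), d[1], d[2], x$exposure_ms))
  if (!is.null(x$layout))
    cat(sprintf("  channels: %s\n", paste(x$layout$channels, collapse = " | ")))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack A [frame_stack()].
#' @return Integer frame count.
#' @export
n_frames <- function(stack) length(stack$frames)

#' Subset the frames of a stack
#'
#' @param stack A [frame_stack()].
#' @param idx Frame indices to keep (in order).
#' @return A new [frame_stack()] with the selected frames.
#' @export
stack_frames <- function(stack, idx) {
  stopifnot(inherits(stack, "frame_stack"))
  frame_stack(stack$frames[idx], stack$exposure_ms, stack$pixel_size_um,
              stack$layout, stack$sweep, stack$meta)
}

#' Pixel-wise mean image over frames
#'
#' @param stack A [frame_stack()].
#' @param idx Frames to average (default all).
#' @return A matrix.
#' @export
average_frames <- function(stack, idx = seq_along(stack$frames)) {
  Reduce(`+`, stack$frames[idx]) / length(idx)
}

#' Write a stack as multi-page TIFF with a JSON sidecar
#'
#' Pixel values are rounded and clamped to the 16-bit unsigned range (a
#' warning reports saturation). Metadata (dimensions, exposure, pixel size,
#' layout, sweep configuration, extra meta, package version) travels in a
#' sidecar JSON file next to the TIFF rather than in TIFF tags, so any
#' reader can consume it.
#'
#' @param stack A [frame_stack()].
#' @param path Output TIFF path; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  ints <- lapply(stack$frames, function(f) {
    f <- round(f)
    if (any(f > 65535))
      warning("pixel counts exceed 65535; values saturated in the written TIFF")
    pmin(pmax(f, 0), 65535)
  })
  tiff::writeTIFF(lapply(ints, function(f) f / 65535), path,
                  bits.per.sample = 16, compression = "none")
  d <- dim(stack$frames[[1]])
  side <- list(
    n_frames = length(stack$frames), height_px = d[1], width_px = d[2],
    exposure_ms = stack$exposure_ms, pixel_size_um = stack$pixel_size_um,
    layout = if (!is.null(stack$layout)) {
      list(width_px = stack$layout$width_px,
           height_px = stack$layout$height_px,
           channels = stack$layout$channels,
           fractions = as.numeric(stack$layout$fractions))
    },
    sweep = if (!is.null(stack$sweep)) sweep_config_to_list(stack$sweep),
    meta = stack$meta,
    smSweep_version = as.character(utils::packageVersion("smSweep")))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a stack written by [write_stack()]
#'
#' @param path TIFF path; the JSON sidecar `paste0(path, ".json")` must
#'   exist and agree with the pixel data.
#' @return A [frame_stack()] with integer-valued pixels.
#' @export
read_stack <- function(path) {
  if (!file.exists(path))
    validation_error(sprintf("TIFF file not found: %s", path))
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    validation_error(sprintf("missing sidecar metadata file: %s", sidecar))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    storage.mode(p) <- "double"
    p
  })
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  d <- dim(pages[[1]])
  if (length(pages) != side$n_frames || d[1] != side$height_px ||
        d[2] != side$width_px)
    validation_error(sprintf(
      "sidecar %s does not match pixel data (%d frames of %d x %d vs declared %s x %s x %s)",
      sidecar, length(pages), d[1], d[2], side$n_frames, side$height_px,
      side$width_px))
  layout <- if (!is.null(side$layout))
    channel_layout(side$layout$width_px, side$layout$height_px,
                   side$layout$channels, side$layout$fractions)
  sweep <- if (!is.null(side$sweep)) sweep_config_from_list(side$sweep)
  if (!is.null(sweep) && !is.null(layout)) {
    # basic consistency: the sweep must fit inside one channel
    if (sweep_length_px(sweep) >= layout$width_px)
      validation_error(sprintf(
        "sidecar %s inconsistent: sweep length %g px exceeds channel width %d px",
        sidecar, sweep_length_px(sweep), layout$width_px))
  }
  meta <- side$meta
  frame_stack(pages, side$exposure_ms, side$pixel_size_um, layout, sweep,
              if (is.null(meta)) list() else meta)
}
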