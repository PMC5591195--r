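# Run configuration files (YAML or JSON) for reproducible CLI runs.

.runconfig_keys <- c("scenario", "seed", "n_frames", "n_molecules", "sweep",
                     "camera", "kinetics", "paths", "slide_px", "box_px",
                     "threshold_sigma", "max_lag", "leakage")

#' Read and validate a run configuration
#'
#' Accepts a YAML (`.yml`/`.yaml`) or JSON file with any of the keys
#' `scenario`, `seed`, `n_frames`, `n_molecules`, `sweep` (a
#' [sweep_config()] block), `camera` (a [camera_model()] block),
#' `kinetics` (model parameters), `paths`, `slide_px`, `box_px`,
#' `threshold_sigma`, `max_lag`, `leakage`. Unknown keys are rejected
#' (schema validation); `seed` is mandatory when `require_seed = TRUE`
#' (simulation commands).
#'
#' @param path Config file path.
#' @param require_seed Demand an integer `seed` entry (default FALSE).
#' @return A validated named list of class `run_config`.
#' @export
read_run_config <- function(path, require_seed = FALSE) {
  if (!file.exists(path)) validation_error(sprintf("config not found: %s", path))
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.list(cfg)) validation_error("config must be a mapping/object")
  unknown <- setdiff(names(cfg), .runconfig_keys)
  if (length(unknown))
    validation_error(paste0("unknown config key(s): ",
                            paste(unknown, collapse = ", ")))
  if (require_seed) {
    if (is.null(cfg$seed) || !is.numeric(cfg$seed))
      validation_error("a numeric `seed` is mandatory for simulation runs")
  }
  if (!is.null(cfg$sweep)) cfg$sweep_config <- sweep_config_from_list(cfg$sweep)
  if (!is.null(cfg$camera)) {
    cm <- cfg$camera
    cfg$camera_model <- camera_model(
      em_gain = cm$em_gain %||% 30,
      read_noise_sd = cm$read_noise_sd %||% 10,
      baseline = cm$baseline %||% 100,
      pixel_size_um = cm$pixel_size_um %||% (68 / 512))
  }
  class(cfg) <- c("run_config", "list")
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a machine-readable provenance record
#'
#' Every CLI run emits a JSON record of the exact inputs: command,
#' arguments, seed, configuration and package version.
#'
#' @param path Output JSON path.
#' @param command CLI command name.
#' @param args Named list of resolved arguments.
#' @param seed Seed used (or NULL).
#' @return `path`, invisibly.
#' @export
write_provenance <- function(path, command, args, seed = NULL) {
  rec <- list(command = command, args = args, seed = seed,
              smSweep_version = as.character(utils::packageVersion("smSweep")),
              r_version = as.character(getRversion()))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
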