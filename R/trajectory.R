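#' Simulate a two-state continuous-time trajectory
#'
#' Exact event-driven (Gillespie) simulation of the two-state Markov process
#' defined by a [kinetic_model()] (state 1 = dark/unbound, state 2 =
#' bright/bound) or a [fret_model()] (state 1 = conformation with `E_1`,
#' state 2 = conformation with `E_2`). Dwell times are exponential at the
#' model's rates; a state whose exit rate is zero is absorbing. With all
#' rates zero the trajectory stays in its initial state for the whole
#' duration (documented behaviour, not an error).
#'
#' @param model A [kinetic_model()] or [fret_model()].
#' @param duration_ms Total simulated time (ms, > 0).
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (so that batch simulations seeded once remain reproducible).
#' @param initial_state Starting state (1 or 2). Default: drawn from the
#'   stationary distribution, or state 2 when both rates are zero.
#' @return A data frame with columns `state`, `t_start`, `t_end` (ms)
#'   partitioning `[0, duration_ms]`, with attributes `model`,
#'   `duration_ms` and `initial_state`.
#' @export
#' @examples
#' m <- kinetic_model(k_on = 50, k_off = 130, bright_rate = 30)
#' ev <- simulate_state_trajectory(m, duration_ms = 1000, seed = 1)
#' mean(ev$t_end - ev$t_start)
simulate_state_trajectory <- function(model, duration_ms, seed = NULL,
                                      initial_state = NULL) {
  .check_scalar(duration_ms, "duration_ms", min = 0, strict = TRUE)
  if (!is.null(seed)) set.seed(seed)
  rates <- if (inherits(model, "kinetic_model")) {
    c(model$k_on, model$k_off)
  } else if (inherits(model, "fret_model")) {
    c(model$k_12, model$k_21)
  } else {
    invalid_arg("`model` must be a kinetic_model or fret_model")
  }
  rates <- rates / 1000  # per ms; rates[s] is the exit rate of state s

  if (is.null(initial_state)) {
    initial_state <- if (sum(rates) == 0) {
      2L
    } else if (stats::runif(1) < rates[1] / sum(rates)) 2L else 1L
  }
  initial_state <- as.integer(initial_state)
  if (!initial_state %in% c(1L, 2L)) invalid_arg("`initial_state` must be 1 or 2")

  other <- function(s) 3L - s

  # absorbing / degenerate cases
  if (rates[initial_state] == 0) {
    ev <- data.frame(state = initial_state, t_start = 0, t_end = duration_ms)
    return(.traj(ev, model, duration_ms, initial_state))
  }
  if (rates[other(initial_state)] == 0) {
    d1 <- stats::rexp(1, rates[initial_state])
    ev <- if (d1 >= duration_ms) {
      data.frame(state = initial_state, t_start = 0, t_end = duration_ms)
    } else {
      data.frame(state = c(initial_state, other(initial_state)),
                 t_start = c(0, d1), t_end = c(d1, duration_ms))
    }
    return(.traj(ev, model, duration_ms, initial_state))
  }

  # both rates positive: draw alternating exponential dwells in blocks
  mean_dwell <- mean(1 / rates)
  guess <- max(16L, ceiling(duration_ms / mean_dwell * 1.25) + 16L)
  dwells <- numeric(0)
  states <- integer(0)
  total <- 0
  nxt <- initial_state
  while (total < duration_ms) {
    st_block <- if (nxt == 1L) {
      rep_len(c(1L, 2L), guess)
    } else {
      rep_len(c(2L, 1L), guess)
    }
    dw_block <- stats::rexp(guess, rates[st_block])
    states <- c(states, st_block)
    dwells <- c(dwells, dw_block)
    total <- total + sum(dw_block)
    nxt <- other(st_block[guess])
    guess <- max(16L, ceiling(guess / 2))
  }
  t_end <- cumsum(dwells)
  keep <- seq_len(which(t_end >= duration_ms)[1])
  states <- states[keep]
  t_end <- pmin(t_end[keep], duration_ms)
  t_start <- c(0, t_end[-length(t_end)])
  ev <- data.frame(state = states, t_start = t_start, t_end = t_end)
  .traj(ev, model, duration_ms, initial_state)
}

.traj <- function(ev, model, duration_ms, initial_state) {
  attr(ev, "model") <- model
  attr(ev, "duration_ms") <- duration_ms
  attr(ev, "initial_state") <- initial_state
  class(ev) <- c("state_trajectory", "data.frame")
  ev
}

#' Dwell times of a simulated trajectory
#'
#' @param events A trajectory from [simulate_state_trajectory()].
#' @param state Which state's dwells to return (1 or 2).
#' @param drop_censored Drop the first and last interval, which are truncated
#'   by the simulation window (default `TRUE`).
#' @return Numeric vector of dwell durations (ms).
#' @export
trajectory_dwells <- function(events, state, drop_censored = TRUE) {
  keep <- rep(TRUE, nrow(events))
  if (drop_censored && nrow(events) > 1) {
    keep[c(1, nrow(events))] <- FALSE
  }
  d <- events$t_end - events$t_start
  d[keep & events$state == state]
}

#' Occupancy of state 2 within each sub-exposure window
#'
#' Partitions the camera timeline into frames of
#' `exposure_ms + frame_lag_ms` and each exposure into `n_steps` substeps,
#' and computes the fraction of each substep window the trajectory spent in
#' state 2 (bright / conformation 2). Photons arriving during the inter-frame
#' lag are never collected, so lag windows are simply skipped.
#'
#' @param events A trajectory from [simulate_state_trajectory()]; must span
#'   at least `n_frames * (exposure_ms + frame_lag_ms)`.
#' @param config A [sweep_config()].
#' @param n_frames Number of frames.
#' @return An `n_frames` x `n_steps` matrix of occupancies in `[0, 1]`.
#' @export
state_occupancy <- function(events, config, n_frames) {
  stopifnot(inherits(config, "sweep_config"))
  .check_scalar(n_frames, "n_frames", min = 1, integerish = TRUE)
  period <- config$exposure_ms + config$frame_lag_ms
  need <- (n_frames - 1) * period + config$exposure_ms
  dur <- attr(events, "duration_ms")
  if (is.null(dur)) dur <- max(events$t_end)
  if (dur + 1e-9 < need)
    invalid_arg(sprintf(
      "trajectory spans %.6g ms but %.6g ms are required for %d frames",
      dur, need, n_frames))
  delta <- substep_ms(config)
  starts <- outer((seq_len(n_frames) - 1) * period,
                  (seq_len(config$n_steps) - 1) * delta, "+")
  B <- .state2_time_fn(events)
  occ <- (B(starts + delta) - B(starts)) / delta
  matrix(occ, nrow = n_frames, ncol = config$n_steps)
}

# cumulative time spent in state 2 on [0, t], piecewise linear
.state2_time_fn <- function(events) {
  ts <- events$t_start
  te <- events$t_end
  s2 <- events$state == 2L
  cum <- c(0, cumsum((te - ts) * s2))
  t_max <- te[length(te)]
  function(t) {
    t <- pmin(pmax(t, 0), t_max)
    i <- pmax(findInterval(t, ts), 1L)
    cum[i] + ifelse(s2[i], pmin(t, te[i]) - ts[i], 0)
  }
}

#' Expected photons per sub-exposure window
#'
#' Integrates the trajectory's photon emission rate over each substep
#' window: a [kinetic_model()] emits `bright_rate` photons/ms in state 2 and
#' `dark_rate` in state 1; a [fret_model()] emits `total_rate` regardless of
#' state (the state controls the donor/acceptor split, see
#' [fret_expected_photons()]). Photons during the inter-frame lag are
#' discarded.
#'
#' @inheritParams state_occupancy
#' @return An `n_frames` x `n_steps` matrix of expected photon counts, with
#'   the occupancy matrix attached as attribute `"occupancy"`.
#' @export
integrate_substeps <- function(events, config, n_frames) {
  occ <- state_occupancy(events, config, n_frames)
  model <- attr(events, "model")
  delta <- substep_ms(config)
  lam <- if (inherits(model, "fret_model")) {
    matrix(model$total_rate * delta, nrow(occ), ncol(occ))
  } else {
    delta * (occ * model$bright_rate + (1 - occ) * model$dark_rate)
  }
  attr(lam, "occupancy") <- occ
  lam
}

#' Expected donor and acceptor photons per substep for a FRET trajectory
#'
#' Photons in each substep are partitioned by the time-averaged efficiency of
#' the window: donor fraction `1 - E`, acceptor fraction `E`, where `E`
#' interpolates `E_1`/`E_2` by state occupancy. Spectral crosstalk then adds
#' `leakage` times the detected donor photons to the acceptor channel.
#'
#' @inheritParams state_occupancy
#' @return A list with `n_frames` x `n_steps` matrices `donor`, `acceptor`
#'   (leakage included), `efficiency` (window-averaged true E) and
#'   `occupancy`.
#' @export
fret_expected_photons <- function(events, config, n_frames) {
  model <- attr(events, "model")
  if (!inherits(model, "fret_model"))
    invalid_arg("trajectory was not simulated from a fret_model")
  occ <- state_occupancy(events, config, n_frames)
  eff <- (1 - occ) * model$E_1 + occ * model$E_2
  tot <- model$total_rate * substep_ms(config)
  donor <- tot * (1 - eff)
  acceptor <- tot * eff + model$leakage * donor
  list(donor = donor, acceptor = acceptor, efficiency = eff, occupancy = occ)
}
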