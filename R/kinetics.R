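# Kinetic analyses on decoded traces: SNR, blinking autocorrelation,
# threshold dwell detection, exponential dwell fitting, FRET efficiency.

#' Signal-to-noise ratios of a trace
#'
#' `SNR_B = (I_S - I_B) / sigma_B` and `SNR_S = (I_S - I_B) / sigma_S`,
#' where `I_S`/`sigma_S` are the mean/SD over ON samples and
#' `I_B`/`sigma_B` over OFF samples.
#'
#' @param trace A `spot_trace` or a numeric vector of intensities.
#' @param on_mask Logical vector marking ON samples (>= 2 ON and >= 2 OFF
#'   samples required).
#' @return A list of class `snr_result`: `snr_b`, `snr_s`, `i_s`, `i_b`,
#'   `sigma_s`, `sigma_b`.
#' @export
compute_snr <- function(trace, on_mask) {
  v <- if (inherits(trace, "spot_trace")) trace$values else as.numeric(trace)
  if (length(on_mask) != length(v))
    invalid_arg("`on_mask` must have one entry per sample")
  on_mask <- as.logical(on_mask)
  if (sum(on_mask) < 2 || sum(!on_mask) < 2)
    insufficient_data("need at least 2 ON and 2 OFF samples")
  i_s <- mean(v[on_mask]); sigma_s <- stats::sd(v[on_mask])
  i_b <- mean(v[!on_mask]); sigma_b <- stats::sd(v[!on_mask])
  num <- i_s - i_b  # zero contrast gives SNR 0 even on a noiseless trace
  structure(list(snr_b = if (num == 0) 0 else num / sigma_b,
                 snr_s = if (num == 0) 0 else num / sigma_s,
                 i_s = i_s, i_b = i_b, sigma_s = sigma_s, sigma_b = sigma_b),
            class = "snr_result")
}

#' Normalized autocorrelation of a trace
#'
#' Mean-subtracted sample autocorrelation at lags `0..max_lag`. Two
#' normalizations are offered: `"variance"` (lag 0 equals 1, the usual
#' statistical ACF) and `"mean2"` (autocovariance divided by the squared
#' mean), the convention under which a two-state telegraph intensity trace
#' follows `(k_off/k_on) exp(-(k_on + k_off) t)` and the amplitude carries
#' the rate ratio.
#'
#' @param x Numeric trace; `length(x) > 2 * max_lag` required.
#' @param max_lag Largest lag in samples.
#' @param normalize `"variance"` (default) or `"mean2"`.
#' @return Numeric vector of length `max_lag + 1` (lag 0 first) with
#'   attribute `lags`.
#' @export
autocorrelation <- function(x, max_lag, normalize = c("variance", "mean2")) {
  normalize <- match.arg(normalize)
  x <- as.numeric(x)
  .check_scalar(max_lag, "max_lag", min = 1, integerish = TRUE)
  if (length(x) <= 2 * max_lag)
    invalid_arg("trace must be longer than twice `max_lag`")
  if (stats::sd(x) == 0)
    insufficient_data("zero-variance trace has no autocorrelation")
  cv <- as.numeric(stats::acf(x, lag.max = max_lag, type = "covariance",
                              plot = FALSE, demean = TRUE)$acf)
  out <- switch(normalize,
                variance = cv / cv[1],
                mean2 = cv / mean(x)^2)
  attr(out, "lags") <- 0:max_lag
  attr(out, "normalize") <- normalize
  out
}

#' Averaged blinking autocorrelation over molecules
#'
#' Computes the mean-squared-normalized autocovariance of each trace and
#' averages the curves, the form fitted by [fit_blinking_acf()]. The lag
#' axis uses the effective sample interval
#' `substep_ms + frame_lag_ms / n_steps`: consecutive samples within a
#' frame are one substep apart, but each frame boundary inserts the
#' camera's dead time, so on average lag k spans
#' `k * (substep + lag/N)` ms. Ignoring this overestimates fitted rates by
#' the ratio `(exposure + lag) / exposure`.
#'
#' @param traces A list of `spot_trace` objects (or numeric vectors).
#' @param max_lag Largest lag in samples.
#' @param frame_lag_ms Inter-frame dead time (ms, default 0); pass the
#'   sweep config's value for calibrated lag times.
#' @return A list with `lags_ms`, `acf` (averaged, lag 0 first),
#'   `bin_ms` (the integration bin width, for [fit_blinking_acf()]'s
#'   finite-bin correction) and `n_traces`.
#' @export
blinking_acf <- function(traces, max_lag, frame_lag_ms = 0) {
  if (inherits(traces, "spot_trace") || is.numeric(traces))
    traces <- list(traces)
  substep <- if (inherits(traces[[1]], "spot_trace"))
    traces[[1]]$substep_ms else 1
  n_steps <- if (inherits(traces[[1]], "spot_trace"))
    traces[[1]]$n_steps else 1
  interval <- substep + frame_lag_ms / n_steps
  curves <- lapply(traces, function(tr) {
    v <- if (inherits(tr, "spot_trace")) tr$values else as.numeric(tr)
    autocorrelation(v, max_lag, normalize = "mean2")
  })
  list(lags_ms = (0:max_lag) * interval,
       acf = Reduce(`+`, curves) / length(curves),
       bin_ms = substep, n_traces = length(curves))
}

#' Fit the two-state blinking model to an autocorrelation curve
#'
#' Nonlinear least squares of `A * exp(-k * t)` to the positive lags of a
#' mean-squared-normalized autocorrelation, under the two-state
#' identification `A = k_off / k_on`, `k = k_on + k_off`. Lag 0 is always
#' excluded (it carries the shot-noise spike). When the ACF was computed
#' from time-binned samples of width `bin_ms`, setting
#' `binning_correction = TRUE` fits the finite-bin model
#' `A * w(k b) * exp(-k (t - b))` with `w(u) = (1 - e^-u)^2 / u^2`,
#' removing the amplitude bias that binning otherwise introduces.
#'
#' @param acf_values Autocorrelation values (lag 0 first, as returned by
#'   [autocorrelation()] / [blinking_acf()]).
#' @param lags_ms Lag times in ms, same length.
#' @param binning_correction Apply the finite-bin amplitude model
#'   (default `FALSE`, the plain continuous exponential).
#' @param bin_ms Bin width for the correction; default the first positive
#'   lag spacing.
#' @return An object of class `acf_fit`: `k_on`, `k_off` (s^-1),
#'   `amplitude` (= k_off/k_on), `decay_rate` (= k_on + k_off, s^-1),
#'   `off_time_ms` (= 1000/k_on), standard errors, and the fit object.
#' @export
fit_blinking_acf <- function(acf_values, lags_ms, binning_correction = FALSE,
                             bin_ms = NULL) {
  acf_values <- as.numeric(acf_values)
  if (length(acf_values) != length(lags_ms))
    invalid_arg("`acf_values` and `lags_ms` must have equal length")
  keep <- lags_ms > 0
  y <- acf_values[keep]
  t <- lags_ms[keep]
  if (length(y) < 5)
    insufficient_data("need at least 5 positive-lag points for the fit")
  if (is.null(bin_ms)) bin_ms <- min(t)

  # log-linear initialization on the positive values
  pos <- y > 0
  if (sum(pos) < 3) fit_failure("autocorrelation has too few positive values")
  ini <- stats::lm(log(y[pos]) ~ t[pos])
  k0 <- max(-stats::coef(ini)[2], 1e-4)     # per ms
  A0 <- max(exp(stats::coef(ini)[1]), 1e-6)

  df <- data.frame(y = y, t = t)
  fit <- tryCatch({
    if (binning_correction) {
      b <- bin_ms
      minpack.lm::nlsLM(
        y ~ A * (1 - exp(-k * b))^2 / (k * b)^2 * exp(-k * (t - b)),
        data = df, start = list(A = A0, k = k0),
        lower = c(1e-8, 1e-8),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(y ~ A * exp(-k * t), data = df,
                        start = list(A = A0, k = k0), lower = c(1e-8, 1e-8),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e)
    fit_failure(paste0("autocorrelation fit did not converge: ",
                       conditionMessage(e))))

  p <- stats::coef(fit)
  A <- p[["A"]]; k_ms <- p[["k"]]
  k_tot <- k_ms * 1000                       # s^-1
  k_on <- k_tot / (1 + A)
  k_off <- k_tot - k_on
  V <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA, 2, 2))
  # delta method for (k_on, k_off) from (A, k)
  J_on <- c(-k_tot / (1 + A)^2, 1000 / (1 + A))
  J_off <- c(k_tot / (1 + A)^2, 1000 * A / (1 + A))
  se_on <- sqrt(drop(t(J_on) %*% V %*% J_on))
  se_off <- sqrt(drop(t(J_off) %*% V %*% J_off))
  structure(list(k_on = k_on, k_off = k_off, amplitude = A,
                 decay_rate = k_tot, off_time_ms = 1000 / k_on,
                 on_time_ms = 1000 / k_off,
                 se_k_on = se_on, se_k_off = se_off,
                 lags_ms = t, acf_values = y,
                 fitted = stats::fitted(fit), fit = fit,
                 binning_correction = binning_correction),
            class = "acf_fit")
}

#' @export
print.acf_fit <- function(x, ...) {
  cat(sprintf("<acf_fit> k_on = %.4g /s (off-time %.3g ms), k_off = %.4g /s (on-time %.3g ms)\n",
              x$k_on, x$off_time_ms, x$k_off, x$on_time_ms))
  cat(sprintf("  amplitude k_off/k_on = %.4g, decay %.4g /s%s\n", x$amplitude,
              x$decay_rate,
              if (x$binning_correction) " (finite-bin model)" else ""))
  invisible(x)
}

#' Threshold dwell-time detection
#'
#' Samples are ON when the raw intensity exceeds
#' `I_B + threshold_sigma * sigma_B` (equivalently, when the
#' background-subtracted value exceeds `threshold_sigma * sigma_B`).
#' Runs of equal state become dwell records; dwells touching either end of
#' the trace are flagged censored.
#'
#' @param trace A `spot_trace` (needs `i_b`, `sigma_b` with
#'   `sigma_b > 0`), or a numeric vector if `i_b`/`sigma_b`/`substep_ms`
#'   are given.
#' @param threshold_sigma Threshold in background SDs (default 3).
#' @param molecule_id Identifier copied into the records (default 1).
#' @param i_b,sigma_b,substep_ms Overrides when `trace` is a bare vector.
#' @return A data frame with columns `molecule_id`, `state`
#'   (`"ON"`/`"OFF"`), `start_ms`, `duration_ms`, `censored`.
#' @export
detect_dwells_threshold <- function(trace, threshold_sigma = 3,
                                    molecule_id = 1L, i_b = NULL,
                                    sigma_b = NULL, substep_ms = NULL) {
  if (inherits(trace, "spot_trace")) {
    # values are already background-subtracted (and crosstalk-compensated),
    # so the I_B + k sigma_B rule reduces to values > k sigma_B
    v <- trace$values
    if (is.null(i_b)) i_b <- 0
    if (is.null(sigma_b)) sigma_b <- trace$sigma_b
    if (is.null(substep_ms)) substep_ms <- trace$substep_ms
  } else {
    v <- as.numeric(trace)
    if (is.null(i_b) || is.null(sigma_b) || is.null(substep_ms))
      invalid_arg("bare traces need `i_b`, `sigma_b` and `substep_ms`")
  }
  if (!is.finite(sigma_b) || sigma_b <= 0)
    invalid_arg("`sigma_b` must be positive")
  on <- v > i_b + threshold_sigma * sigma_b
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  n <- length(r$lengths)
  data.frame(molecule_id = molecule_id,
             state = ifelse(r$values, "ON", "OFF"),
             start_ms = starts * substep_ms,
             duration_ms = r$lengths * substep_ms,
             censored = seq_len(n) %in% c(1L, n))
}

#' Exponential dwell-time fit
#'
#' Maximum-likelihood mean dwell time over uncensored dwells of one state,
#' with a bootstrap standard error. For continuous durations the MLE is the
#' sample mean (minus `left_truncate_ms` when the record is known to be
#' left-truncated). Threshold-detected dwells are integer multiples of the
#' substep and their first bin is edge-dominated (a dwell's first and last
#' bins cross the threshold only if sufficiently covered); passing
#' `discrete_ms` therefore switches to a left-truncated geometric MLE: runs
#' longer than `left_truncate_ms` (default one substep) are kept, and by
#' memorylessness of the geometric tail
#' `tau = -d / log(1 - d / (mean - t0))` recovers the decay constant
#' unbiasedly while ignoring the edge-biased first bin.
#'
#' @param dwells A dwell data frame from [detect_dwells_threshold()] (rows
#'   from several molecules may be concatenated).
#' @param state `"ON"` or `"OFF"`.
#' @param min_n Minimum number of uncensored dwells (default 50).
#' @param discrete_ms Sampling interval of the discretized durations, or
#'   `NULL` (default) for continuous data.
#' @param left_truncate_ms Left-truncation point: dwells no longer than
#'   this are discarded and the tail refitted. Default `NULL`: one substep
#'   (`discrete_ms`) for discrete data, 0 for continuous.
#' @param n_boot Bootstrap replicates for the SE (default 200).
#' @return A list of class `dwell_fit`: `tau_ms`, `se_ms`, `n`, `state`.
#' @export
fit_dwell_histogram <- function(dwells, state = c("ON", "OFF"), min_n = 50,
                                discrete_ms = NULL, left_truncate_ms = NULL,
                                n_boot = 200) {
  state <- match.arg(state)
  if (is.null(left_truncate_ms))
    left_truncate_ms <- if (is.null(discrete_ms)) 0 else discrete_ms
  d <- dwells$duration_ms[dwells$state == state & !dwells$censored]
  d <- d[d > left_truncate_ms]
  if (length(d) < min_n)
    insufficient_data(sprintf(
      "only %d uncensored %s dwells after truncation (need >= %d)",
      length(d), state, min_n))
  est <- function(x) {
    m <- mean(x) - left_truncate_ms
    if (is.null(discrete_ms)) return(m)
    if (m <= discrete_ms) return(discrete_ms / 2)  # degenerate: all minimal
    -discrete_ms / log(1 - discrete_ms / m)
  }
  tau <- est(d)
  se <- if (length(unique(d)) == 1L) {
    0
  } else {
    reps <- vapply(seq_len(n_boot), function(i)
      est(sample(d, replace = TRUE)), numeric(1))
    stats::sd(reps)
  }
  structure(list(tau_ms = tau, se_ms = se, n = length(d), state = state,
                 discrete_ms = discrete_ms),
            class = "dwell_fit")
}

#' @export
print.dwell_fit <- function(x, ...) {
  cat(sprintf("<dwell_fit> tau_%s = %.4g +/- %.2g ms (n = %d%s)\n",
              tolower(x$state), x$tau_ms, x$se_ms, x$n,
              if (!is.null(x$discrete_ms)) ", discrete MLE" else ""))
  invisible(x)
}

#' FRET efficiency with background and leakage correction
#'
#' `E = I_A' / (I_D' + I_A')` with `I_D' = i_d - background_d` and
#' `I_A' = i_a - background_a - leakage * I_D'`. Results are clamped to
#' `[0, 1]`; samples with non-positive total intensity are returned as `NA`
#' (flagged invalid, to be excluded downstream).
#'
#' @param i_d,i_a Donor and acceptor intensities (equal length).
#' @param leakage Donor-to-acceptor crosstalk fraction (default 0).
#' @param background_d,background_a Channel backgrounds (default 0;
#'   unnecessary for already background-subtracted traces).
#' @return Numeric vector of efficiencies in `[0, 1]` (NA where invalid),
#'   with attribute `n_invalid`.
#' @export
fret_efficiency <- function(i_d, i_a, leakage = 0, background_d = 0,
                            background_a = 0) {
  if (length(i_d) != length(i_a))
    invalid_arg("`i_d` and `i_a` must have equal length")
  id <- i_d - background_d
  ia <- i_a - background_a - leakage * id
  tot <- id + ia
  e <- ifelse(tot > 0, ia / tot, NA_real_)
  e <- pmin(pmax(e, 0), 1)
  attr(e, "n_invalid") <- sum(tot <= 0)
  e
}

#' Pooled FRET efficiency histogram
#'
#' @param efficiencies Pooled per-substep efficiencies (>= 100 finite
#'   samples); NAs dropped.
#' @param n_bins Number of equal bins over `[0, 1]` (default 40).
#' @return A list with `mids`, `density` (integrating to 1) and `counts`.
#' @export
fret_histogram <- function(efficiencies, n_bins = 40) {
  e <- efficiencies[is.finite(efficiencies)]
  if (length(e) < 100)
    insufficient_data("need at least 100 efficiency samples")
  h <- graphics::hist(e, breaks = seq(0, 1, length.out = n_bins + 1),
                      plot = FALSE)
  list(mids = h$mids, density = h$density, counts = h$counts)
}

#' Block-average pooled samples
#'
#' Averages `n` consecutive samples, e.g. collapsing 5-ms efficiencies to
#' the 20-ms values a conventional camera would record. Trailing samples
#' that do not fill a block are dropped; blocks containing NAs average the
#' finite members.
#'
#' @param x Numeric vector.
#' @param n Block size.
#' @return Vector of length `floor(length(x)/n)`.
#' @export
block_average <- function(x, n) {
  .check_scalar(n, "n", min = 1, integerish = TRUE)
  nb <- floor(length(x) / n)
  if (nb == 0) return(numeric(0))
  colMeans(matrix(x[seq_len(nb * n)], nrow = n), na.rm = TRUE)
}

#' Two-mode test on a histogram
#'
#' Detects whether a histogram is bimodal: after light smoothing
#' (3-bin running mean) the two highest local maxima must be separated by a
#' valley lower than `valley_frac` times the smaller peak.
#'
#' @param h A histogram from [fret_histogram()] (or a list with `density`).
#' @param valley_frac Valley criterion (default 0.6).
#' @return `TRUE` if two resolved modes are found.
#' @export
is_bimodal <- function(h, valley_frac = 0.6) {
  d <- h$density
  n <- length(d)
  sm <- stats::filter(d, rep(1 / 3, 3), sides = 2)
  sm[1] <- mean(d[1:2]); sm[n] <- mean(d[(n - 1):n])
  sm <- as.numeric(sm)
  peaks <- which(diff(sign(diff(c(-Inf, sm, -Inf)))) == -2)
  if (length(peaks) < 2) return(FALSE)
  ord <- order(sm[peaks], decreasing = TRUE)
  p1 <- peaks[ord[1]]; p2 <- peaks[ord[2]]
  lo <- min(p1, p2); hi <- max(p1, p2)
  if (hi - lo < 2) return(FALSE)
  valley <- min(sm[(lo + 1):(hi - 1)])
  valley < valley_frac * min(sm[p1], sm[p2])
}
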