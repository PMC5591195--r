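# Gaussian-emission hidden Markov model for two-state FRET traces:
# maximum-likelihood Baum-Welch, BIC model selection (1 vs 2 states),
# Viterbi decoding, and rate conversion from the transition matrix.

.gauss_hmm_1state <- function(x) {
  mu <- mean(x)
  s <- max(stats::sd(x), 1e-9)
  list(K = 1L, mu = mu, sigma = s, trans = matrix(1, 1, 1), init = 1,
       loglik = sum(stats::dnorm(x, mu, s, log = TRUE)),
       path = rep(1L, length(x)), n_iter = 0L)
}

.gauss_hmm_2state <- function(x, max_iter = 300, tol = 1e-8) {
  n <- length(x)
  qs <- stats::quantile(x, c(0.2, 0.8), names = FALSE)
  mu <- qs
  if (diff(mu) < 1e-8) mu <- mu + c(-1e-3, 1e-3)
  s <- rep(max(stats::sd(x) / 2, 1e-6), 2)
  P <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE)
  pi0 <- c(0.5, 0.5)
  ll_old <- -Inf
  ll <- ll_old
  for (it in seq_len(max_iter)) {
    B <- cbind(stats::dnorm(x, mu[1], s[1]), stats::dnorm(x, mu[2], s[2]))
    B[B < 1e-300] <- 1e-300
    alpha <- matrix(0, n, 2)
    cvec <- numeric(n)
    a <- pi0 * B[1, ]
    cvec[1] <- sum(a); alpha[1, ] <- a / cvec[1]
    for (t in 2:n) {
      a <- (alpha[t - 1, ] %*% P) * B[t, ]
      cvec[t] <- sum(a)
      alpha[t, ] <- a / cvec[t]
    }
    ll <- sum(log(cvec))
    beta <- matrix(0, n, 2)
    beta[n, ] <- 1
    for (t in (n - 1):1)
      beta[t, ] <- (P %*% (B[t + 1, ] * beta[t + 1, ])) / cvec[t + 1]
    g <- alpha * beta
    g <- g / rowSums(g)
    xi <- matrix(0, 2, 2)
    for (i in 1:2) for (j in 1:2)
      xi[i, j] <- sum(alpha[-n, i] * P[i, j] * B[-1, j] * beta[-1, j] /
                        cvec[-1])
    P <- xi / rowSums(xi)
    pi0 <- g[1, ]
    cg <- colSums(g)
    mu <- colSums(g * x) / cg
    s <- sqrt(colSums(g * (x - rep(mu, each = n))^2) / cg)
    s <- pmax(s, 1e-6)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  # canonical labelling: state 1 = lower mean
  if (mu[1] > mu[2]) {
    mu <- rev(mu); s <- rev(s); pi0 <- rev(pi0)
    P <- P[2:1, 2:1]
  }
  path <- .viterbi_gauss(x, mu, s, P, pi0)
  list(K = 2L, mu = mu, sigma = s, trans = P, init = pi0, loglik = ll,
       path = path, n_iter = it)
}

.viterbi_gauss <- function(x, mu, s, P, pi0) {
  n <- length(x)
  K <- length(mu)
  lB <- vapply(seq_len(K), function(k) stats::dnorm(x, mu[k], s[k], log = TRUE),
               numeric(n))
  lP <- log(pmax(P, 1e-300))
  delta <- matrix(-Inf, n, K)
  psi <- matrix(0L, n, K)
  delta[1, ] <- log(pmax(pi0, 1e-300)) + lB[1, ]
  for (t in 2:n) {
    for (k in seq_len(K)) {
      cand <- delta[t - 1, ] + lP[, k]
      psi[t, k] <- which.max(cand)
      delta[t, k] <- cand[psi[t, k]] + lB[t, k]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  for (t in (n - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  path
}

#' Fit a two-state hidden Markov model to a FRET efficiency trace
#'
#' Gaussian-emission HMMs with 1 and 2 states are fitted by maximum
#' likelihood (Baum-Welch with deterministic quantile initialization, so
#' results are reproducible) and compared by BIC. For the selected model
#' the Viterbi state path is returned, and for two states the
#' interconversion rates are recovered from the fitted transition matrix by
#' exact inversion of the discretely observed two-state process:
#' `k_12 + k_21 = -log(1 - p_12 - p_21) / dt` and
#' `k_12 / (k_12 + k_21) = p_12 / (p_12 + p_21)`. Dwell-based rates from
#' the Viterbi path are also reported.
#'
#' @param efficiency Per-substep FRET efficiencies (NAs dropped; >= 50
#'   samples required).
#' @param substep_ms Sample interval (ms).
#' @param max_iter,tol Baum-Welch stopping controls.
#' @return A list of class `hmm_fit`: `n_states`, `state_path` (1 = low-E
#'   state), `k_12`, `k_21` (s^-1, NA for one state), `trans`, `means`,
#'   `sds`, `loglik`, `bic`, `dwell_rates`.
#' @export
fit_two_state_hmm <- function(efficiency, substep_ms, max_iter = 300,
                              tol = 1e-8) {
  x <- as.numeric(efficiency)
  x <- x[is.finite(x)]
  if (length(x) < 50)
    insufficient_data("need at least 50 finite efficiency samples")
  .check_scalar(substep_ms, "substep_ms", min = 0, strict = TRUE)
  n <- length(x)

  m1 <- .gauss_hmm_1state(x)
  if (stats::sd(x) < 1e-12) {
    return(structure(list(n_states = 1L, state_path = m1$path, k_12 = NA_real_,
                          k_21 = NA_real_, trans = m1$trans, means = m1$mu,
                          sds = m1$sigma, loglik = m1$loglik,
                          bic = -2 * m1$loglik + 2 * log(n),
                          dwell_rates = c(k_12 = NA_real_, k_21 = NA_real_),
                          substep_ms = substep_ms),
                     class = "hmm_fit"))
  }
  m2 <- .gauss_hmm_2state(x, max_iter, tol)
  bic1 <- -2 * m1$loglik + 2 * log(n)
  bic2 <- -2 * m2$loglik + 7 * log(n)
  if (bic1 <= bic2) {
    structure(list(n_states = 1L, state_path = m1$path, k_12 = NA_real_,
                   k_21 = NA_real_, trans = m1$trans, means = m1$mu,
                   sds = m1$sigma, loglik = m1$loglik, bic = bic1,
                   dwell_rates = c(k_12 = NA_real_, k_21 = NA_real_),
                   substep_ms = substep_ms),
              class = "hmm_fit")
  } else {
    rates <- .rates_from_trans(m2$trans, substep_ms)
    dr <- .rates_from_path(m2$path, substep_ms)
    structure(list(n_states = 2L, state_path = m2$path, k_12 = rates[1],
                   k_21 = rates[2], trans = m2$trans, means = m2$mu,
                   sds = m2$sigma, loglik = m2$loglik, bic = bic2,
                   dwell_rates = dr, substep_ms = substep_ms),
              class = "hmm_fit")
  }
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf("<hmm_fit> %d state(s) selected (BIC %.1f)\n", x$n_states, x$bic))
  if (x$n_states == 2)
    cat(sprintf("  means %.3f / %.3f; k_12 = %.4g /s, k_21 = %.4g /s (sum %.4g)\n",
                x$means[1], x$means[2], x$k_12, x$k_21, x$k_12 + x$k_21))
  invisible(x)
}

# exact CTMC rates from a discrete-time 2x2 transition matrix
.rates_from_trans <- function(P, substep_ms) {
  p12 <- P[1, 2]; p21 <- P[2, 1]
  lam <- 1 - p12 - p21           # second eigenvalue = exp(-k_sum * dt)
  dt_s <- substep_ms / 1000
  if (lam <= 0 || p12 + p21 <= 0) return(c(NA_real_, NA_real_))
  k_sum <- -log(lam) / dt_s
  k12 <- k_sum * p12 / (p12 + p21)
  c(k12, k_sum - k12)
}

# dwell-mean rates from a Viterbi path (interior runs only, geometric MLE)
.rates_from_path <- function(path, substep_ms) {
  r <- rle(path)
  n <- length(r$lengths)
  if (n < 3) return(c(k_12 = NA_real_, k_21 = NA_real_))
  interior <- 2:(n - 1)
  dt_s <- substep_ms / 1000
  k_for <- function(state) {
    len <- r$lengths[interior][r$values[interior] == state]
    if (length(len) == 0) return(NA_real_)
    m <- mean(len)
    if (m <= 1) return(-log(.Machine$double.eps) / dt_s)
    -log(1 - 1 / m) / dt_s
  }
  c(k_12 = k_for(1L), k_21 = k_for(2L))
}

#' Pool two-state HMM rates over molecules
#'
#' Concatenates the Viterbi dwell runs of all two-state fits (dropping each
#' trace's censored first and last runs) and converts the pooled mean dwell
#' in each state to a rate with the geometric-dwell correction. Pooling
#' dwells is more stable than averaging per-molecule rates when individual
#' traces hold few events; per-molecule rates are returned alongside.
#' Because the Viterbi path smooths dwells that span only a few samples,
#' the dwell-based rates underestimate fast kinetics; the
#' transition-matrix rates (`k_12_trans`, `k_21_trans`, averaged over
#' molecules) invert the sampling interval exactly and are preferred when
#' the mean dwell is below ~5 samples.
#'
#' @param fits A list of `hmm_fit` objects (one-state fits are skipped).
#' @return A list with `k_12`, `k_21`, `k_sum` (s^-1, pooled dwell-based),
#'   `k_12_trans`, `k_21_trans` (transition-matrix based), `n_dwells`,
#'   `n_traces_used`, and the `per_molecule` rate data frame.
#' @export
pool_hmm_rates <- function(fits) {
  fits2 <- Filter(function(f) inherits(f, "hmm_fit") && f$n_states == 2L, fits)
  if (length(fits2) == 0)
    insufficient_data("no two-state fits to pool")
  dt_s <- fits2[[1]]$substep_ms / 1000
  lens <- list(`1` = numeric(0), `2` = numeric(0))
  for (f in fits2) {
    r <- rle(f$state_path)
    n <- length(r$lengths)
    if (n < 3) next
    for (state in 1:2) {
      keep <- r$values[2:(n - 1)] == state
      lens[[state]] <- c(lens[[state]], r$lengths[2:(n - 1)][keep])
    }
  }
  if (length(lens[[1]]) == 0 || length(lens[[2]]) == 0)
    insufficient_data("no interior dwells in the pooled paths")
  k_of <- function(len) {
    m <- mean(len)
    if (m <= 1) return(NA_real_)
    -log(1 - 1 / m) / dt_s
  }
  k12 <- k_of(lens[[1]])
  k21 <- k_of(lens[[2]])
  per <- data.frame(
    k_12 = vapply(fits2, function(f) f$k_12, numeric(1)),
    k_21 = vapply(fits2, function(f) f$k_21, numeric(1)))
  list(k_12 = k12, k_21 = k21, k_sum = k12 + k21,
       k_12_trans = mean(per$k_12, na.rm = TRUE),
       k_21_trans = mean(per$k_21, na.rm = TRUE),
       n_dwells = length(lens[[1]]) + length(lens[[2]]),
       n_traces_used = length(fits2), per_molecule = per)
}
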