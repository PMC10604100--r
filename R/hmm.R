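# Two-state Gaussian hidden Markov analysis of single-molecule pore traces:
# EM parameter estimation, Viterbi decoding, and spike statistics (peak
# intensity, background sigma, SNR).

#' Fit a two-state Gaussian HMM to an intensity trace
#'
#' Expectation-maximization fit of a two-state hidden Markov model with
#' Gaussian emissions, initialized from the 10%/90% quantiles, decoded by
#' the most probable (Viterbi) path. States are reported sorted by mean, so
#' state 2 is the "on" (bright) state; the output is invariant to internal
#' label permutations. Degenerate traces (zero variance, or an
#' uninformative split) fall back to a flagged single-state result with
#' zero events. The fit is deterministic given the trace.
#'
#' @param intensity Numeric trace (>= 50 frames recommended).
#' @param max_iter,tol EM iteration controls.
#' @param min_sd Lower bound on emission SDs (guards collapse onto a
#'   single point).
#' @return An object of class `hmm_result`: `means`, `sds`, `transition`
#'   (2 x 2), `initial`, `path` (1 = off, 2 = on), `log_lik`,
#'   `degenerate`, `n_iter`.
#' @examples
#' x <- rep(c(0, 70), each = 50) + rnorm(100, 0, 10)
#' fit_two_state_hmm(x)$means
#' @export
fit_two_state_hmm <- function(intensity, max_iter = 200, tol = 1e-8,
                              min_sd = 1e-8) {
  x <- as.numeric(intensity)
  n <- length(x)
  if (n < 50) warning("trace shorter than 50 frames: HMM estimates unstable")
  degenerate_result <- function() {
    structure(list(means = c(mean(x), mean(x)),
                   sds = c(max(stats::sd(x), min_sd), max(stats::sd(x), min_sd)),
                   transition = matrix(0.5, 2, 2), initial = c(1, 0),
                   path = rep(1L, n), log_lik = NA_real_,
                   degenerate = TRUE, n_iter = 0L),
              class = "hmm_result")
  }
  if (stats::sd(x) == 0 || n < 4) return(degenerate_result())
  mu <- as.numeric(stats::quantile(x, c(0.1, 0.9)))
  if (diff(mu) < .Machine$double.eps^0.5 * max(abs(mu), 1))
    return(degenerate_result())
  sg <- rep(max(stats::sd(x) / 2, min_sd), 2)
  A <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2, byrow = TRUE)
  pi0 <- c(0.5, 0.5)
  ll_old <- -Inf
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    # emission densities (floored to avoid log(0))
    B <- cbind(stats::dnorm(x, mu[1], sg[1]), stats::dnorm(x, mu[2], sg[2]))
    B <- pmax(B, 1e-300)
    # scaled forward-backward
    alpha <- matrix(0, n, 2); beta <- matrix(0, n, 2); cvec <- numeric(n)
    a <- pi0 * B[1, ]
    cvec[1] <- sum(a); alpha[1, ] <- a / cvec[1]
    for (t in 2:n) {
      a <- (alpha[t - 1, ] %*% A) * B[t, ]
      cvec[t] <- sum(a); alpha[t, ] <- a / cvec[t]
    }
    beta[n, ] <- 1
    for (t in (n - 1):1) {
      b <- A %*% (B[t + 1, ] * beta[t + 1, ])
      beta[t, ] <- b / cvec[t + 1]
    }
    gam <- alpha * beta
    gam <- gam / rowSums(gam)
    # transition expectations
    xi <- matrix(0, 2, 2)
    for (i in 1:2) for (j in 1:2) {
      xi[i, j] <- sum(alpha[1:(n - 1), i] * A[i, j] * B[2:n, j] *
                        beta[2:n, j] / cvec[2:n])
    }
    ll <- sum(log(cvec))
    # M step
    pi0 <- gam[1, ]
    A <- xi / rowSums(xi)
    mu <- colSums(gam * x) / colSums(gam)
    sg <- sqrt(colSums(gam * (x - rep(mu, each = n))^2) / colSums(gam))
    sg <- pmax(sg, min_sd)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  # sort states by mean (off = 1, on = 2)
  ord <- order(mu)
  mu <- mu[ord]; sg <- sg[ord]
  A <- A[ord, ord]; pi0 <- pi0[ord]
  # Viterbi decoding in log space
  logB <- cbind(stats::dnorm(x, mu[1], sg[1], log = TRUE),
                stats::dnorm(x, mu[2], sg[2], log = TRUE))
  logA <- log(pmax(A, 1e-300))
  v <- matrix(-Inf, n, 2); ptr <- matrix(0L, n, 2)
  v[1, ] <- log(pmax(pi0, 1e-300)) + logB[1, ]
  for (t in 2:n) {
    for (j in 1:2) {
      cand <- v[t - 1, ] + logA[, j]
      ptr[t, j] <- which.max(cand)
      v[t, j] <- max(cand) + logB[t, j]
    }
  }
  path <- integer(n)
  path[n] <- which.max(v[n, ])
  for (t in (n - 1):1) path[t] <- ptr[t + 1, path[t + 1]]
  structure(list(means = mu, sds = sg, transition = A, initial = pi0,
                 path = path, log_lik = ll, degenerate = FALSE,
                 n_iter = iter),
            class = "hmm_result")
}

#' @export
print.hmm_result <- function(x, ...) {
  if (x$degenerate) {
    cat("two-state HMM: degenerate trace, single-state fallback\n")
  } else {
    cat(sprintf("two-state HMM: off %.3g (sd %.3g), on %.3g (sd %.3g), %d on-frames\n",
                x$means[1], x$sds[1], x$means[2], x$sds[2], sum(x$path == 2)))
  }
  invisible(x)
}

#' Peak intensity, background noise and SNR of a decoded trace
#'
#' From a fitted [fit_two_state_hmm()] result and its trace: the peak
#' intensity is the on-state mean minus the off-state mean; the background
#' noise sigma is the standard deviation of the off-state frames about the
#' off-state mean; SNR = peak / sigma. On-events (consecutive on-frames)
#' are listed with their durations. Traces with no on-frames return
#' `peak = NA` with `flag = "no_on_state"`.
#'
#' @param result An `hmm_result`.
#' @param intensity The trace that was fitted.
#' @param frame_interval_s Frame interval for dwell times (default 1:
#'   durations in frames).
#' @return List: `peak`, `sigma`, `snr`, `n_events`, `events` (data frame
#'   `start`, `end`, `duration_s`), `flag`.
#' @export
spike_stats <- function(result, intensity, frame_interval_s = 1) {
  stopifnot(inherits(result, "hmm_result"))
  x <- as.numeric(intensity)
  stopifnot(length(x) == length(result$path))
  on <- result$path == 2L
  off <- !on
  if (result$degenerate || !any(on)) {
    return(list(peak = NA_real_,
                sigma = stats::sd(x[off]),
                snr = NA_real_, n_events = 0L,
                events = data.frame(start = integer(), end = integer(),
                                    duration_s = numeric()),
                flag = if (result$degenerate) "degenerate" else "no_on_state"))
  }
  peak <- result$means[2] - result$means[1]
  sigma <- sqrt(mean((x[off] - result$means[1])^2))
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ev <- data.frame(start = starts[r$values], end = ends[r$values])
  ev$duration_s <- (ev$end - ev$start + 1) * frame_interval_s
  list(peak = peak, sigma = sigma, snr = peak / sigma,
       n_events = nrow(ev), events = ev, flag = "ok")
}
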