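# Fluorescence correlation spectroscopy: multi-tau autocorrelation, the
# 3D-diffusion model fit, molecular brightness and effective volume.

#' Binned photon trace
#'
#' @param counts Non-negative integer counts per bin.
#' @param bin_ms Bin width (ms).
#' @param channel Optional channel tag.
#' @return An object of class `photon_trace`.
#' @export
photon_trace <- function(counts, bin_ms, channel = "default") {
  counts <- as.numeric(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  stopifnot(bin_ms > 0)
  structure(list(counts = counts, bin_ms = bin_ms,
                 duration_s = length(counts) * bin_ms / 1000,
                 channel = channel),
            class = "photon_trace")
}

#' @export
print.photon_trace <- function(x, ...) {
  cat(sprintf("photon trace: %d bins x %g ms (%.3g s), <I> = %.3g counts/ms\n",
              length(x$counts), x$bin_ms, x$duration_s, mean(x$counts) / x$bin_ms))
  invisible(x)
}

#' Mean count rate of a trace (counts/ms)
#' @param trace A [photon_trace()].
#' @return Mean intensity (counts per ms).
#' @export
mean_intensity <- function(trace) {
  stopifnot(inherits(trace, "photon_trace"))
  mean(trace$counts) / trace$bin_ms
}

#' Multi-tau autocorrelation
#'
#' Normalized intensity autocorrelation `G(t_c)` on a quasi-logarithmic lag
#' grid, computed by a multi-tau scheme with `m` channels per octave and
#' symmetric normalization
#' `G = <I(t) I(t+tau)> / (mean_left * mean_right) - 1`,
#' binning the trace by two after each octave. At every level the estimate
#' equals the direct correlation of the binned trace at the same lag (see
#' [autocorrelate_direct()] for the O(T L) reference estimator).
#'
#' @param trace A [photon_trace()].
#' @param m Channels per octave (default 16).
#' @param max_lag_ms Longest lag to compute (default 1/8 of the trace).
#' @param segments Number of trace segments used to estimate per-lag
#'   standard errors (block method); 0 disables. Segments shorter than
#'   8 x `max_lag_ms` are not attempted.
#' @return An object of class `correlation_curve`: fields `lag_ms`, `g`
#'   and (when estimated) `se`.
#' @export
autocorrelate <- function(trace, m = 16L, max_lag_ms = NULL, segments = 8L) {
  stopifnot(inherits(trace, "photon_trace"))
  if (mean(trace$counts) == 0)
    stop("zero-mean trace: normalization undefined")
  if (is.null(max_lag_ms)) max_lag_ms <- trace$duration_s * 1000 / 8
  max_level <- max(0L, ceiling(log2(max_lag_ms / trace$bin_ms / (2 * m))) + 1L)
  out <- .cpp_multitau(trace$counts, trace$bin_ms, as.integer(m), as.integer(max_level))
  keep <- out$lag <= max_lag_ms
  lag <- out$lag[keep]
  g <- out$g[keep]
  se <- NULL
  seg_len <- length(trace$counts) %/% max(segments, 1L)
  if (segments > 1L && seg_len * trace$bin_ms >= 8 * max(lag)) {
    gs <- vapply(seq_len(segments), function(i) {
      sub <- trace$counts[((i - 1) * seg_len + 1):(i * seg_len)]
      if (mean(sub) == 0) return(rep(NA_real_, length(lag)))
      o <- .cpp_multitau(sub, trace$bin_ms, as.integer(m), as.integer(max_level))
      o$g[match(lag, o$lag)]
    }, numeric(length(lag)))
    se <- apply(gs, 1, stats::sd, na.rm = TRUE) / sqrt(segments)
  }
  structure(list(lag_ms = lag, g = g, se = se, m = m, bin_ms = trace$bin_ms),
            class = "correlation_curve")
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat(sprintf("correlation curve: %d lags in [%.3g, %.3g] ms, G(min lag) = %.4g\n",
              length(x$lag_ms), min(x$lag_ms), max(x$lag_ms), x$g[1]))
  invisible(x)
}

#' Direct (brute-force) autocorrelation
#'
#' Reference estimator: for each requested lag k (in bins), computes
#' `mean(I_t I_{t+k}) / (mean_left * mean_right) - 1` by direct summation.
#' Used as the independent check of [autocorrelate()].
#'
#' @param counts Numeric count vector.
#' @param lags_bins Integer lags in units of bins.
#' @return Numeric vector of G values.
#' @export
autocorrelate_direct <- function(counts, lags_bins) {
  n <- length(counts)
  vapply(lags_bins, function(k) {
    stopifnot(k >= 1, k < n)
    a <- counts[seq_len(n - k)]
    b <- counts[seq_len(n - k) + k]
    mean(a * b) / (mean(a) * mean(b)) - 1
  }, 0)
}

#' Fit the 3D-diffusion FCS model
#'
#' Weighted least-squares fit of
#' `G(t_c) = (1/N) (1 + t_c/t_D)^-1 (1 + t_c/(p^2 t_D))^-1/2`
#' with the axial-elongation factor fixed at `p = 3.4`. For the complex
#' nanowell geometries this is an effective-parameter description used to
#' extract the amplitude (`1/N`) and average decay time of the curve, not a
#' geometric claim. The amplitude is read from the fitted model, never from
#' the shot-noise-dominated zero-lag bin.
#'
#' @param curve A [correlation_curve()].
#' @param p Geometric factor (fixed, default 3.4).
#' @param weights `"block"` uses inverse-variance weights from the
#'   segment-based standard errors attached by [autocorrelate()] (falling
#'   back to plain least squares when absent); `"uniform"` forces plain
#'   least squares.
#' @return An object of class `fcs_fit`: `N`, `t_D_ms`, their standard
#'   errors, `p`, convergence flag and the fitted curve.
#' @export
fit_fcs <- function(curve, p = 3.4, weights = c("block", "uniform")) {
  stopifnot(inherits(curve, "correlation_curve"))
  weights <- match.arg(weights)
  if (length(curve$lag_ms) < 10)
    stop("need >= 10 lags spanning the decay")
  df <- data.frame(t = curve$lag_ms, g = curve$g)
  g0 <- stats::median(df$g[seq_len(min(4, nrow(df)))])
  if (!is.finite(g0) || g0 <= 0)
    stop("non-decaying or negative-amplitude curve: FCS fit not possible")
  # crude t_D start: lag nearest to half amplitude
  td0 <- df$t[which.min(abs(df$g - g0 / 2))]
  w <- rep(1, nrow(df))
  if (weights == "block" && !is.null(curve$se) && all(is.finite(curve$se))) {
    w <- 1 / pmax(curve$se, max(curve$se) / 100)^2
    w <- w / mean(w)
  }
  fit <- try(minpack.lm::nlsLM(
    g ~ (1 / N) / ((1 + t / tD) * sqrt(1 + t / (p^2 * tD))),
    data = df, start = list(N = 1 / g0, tD = max(td0, curve$bin_ms)),
    weights = w,
    lower = c(N = 1e-6, tD = 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error"))
    stop("FCS fit failed to converge: ", attr(fit, "condition")$message)
  est <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) c(NA, NA))
  structure(list(N = unname(est["N"]), t_D_ms = unname(est["tD"]),
                 N_se = unname(se[1]), t_D_se = unname(se[2]), p = p,
                 converged = TRUE,
                 residual_norm = sqrt(mean(stats::residuals(fit)^2)),
                 fitted = stats::fitted(fit), curve = curve),
            class = "fcs_fit")
}

#' @export
print.fcs_fit <- function(x, ...) {
  cat(sprintf("FCS fit (p = %g): N = %.3f +/- %.3f, t_D = %.3f +/- %.3f ms\n",
              x$p, x$N, x$N_se, x$t_D_ms, x$t_D_se))
  invisible(x)
}

#' Evaluate the 3D-diffusion FCS model
#'
#' @param lag_ms Lag times (ms).
#' @param N Mean particle number.
#' @param t_D_ms Diffusion time (ms).
#' @param p Axial-elongation factor (default 3.4).
#' @return Model G values.
#' @export
fcs_model <- function(lag_ms, N, t_D_ms, p = 3.4) {
  (1 / N) / ((1 + lag_ms / t_D_ms) * sqrt(1 + lag_ms / (p^2 * t_D_ms)))
}

#' Molecular brightness and effective FCS volume
#'
#' `epsilon = <I>/N` (counts/ms per molecule) and
#' `V_FCS = N / (N_A c)` (liters) at the known concentration `c`.
#'
#' @param fit An [fcs_fit()] result.
#' @param trace The [photon_trace()] the curve came from.
#' @param concentration Fluorophore concentration (mol/L), > 0.
#' @return List with `epsilon_cpms` and `v_fcs_l`.
#' @export
brightness_volume <- function(fit, trace, concentration) {
  stopifnot(inherits(fit, "fcs_fit"), inherits(trace, "photon_trace"))
  if (concentration <= 0) stop("concentration must be > 0")
  list(epsilon_cpms = mean_intensity(trace) / fit$N,
       v_fcs_l = fit$N / (.N_AVOGADRO * concentration))
}

#' Signal enhancement factor
#'
#' Ratio of the molecular brightness in the ZMW to the free-diffusion
#' brightness, `epsilon_ZMW / epsilon_0`.
#'
#' @param epsilon_zmw,epsilon_free Brightness values (same units).
#' @return Fold enhancement.
#' @export
enhancement_factor <- function(epsilon_zmw, epsilon_free) {
  if (any(epsilon_free <= 0)) stop("free-diffusion brightness must be > 0")
  epsilon_zmw / epsilon_free
}

#' Scaling of particle number with pore size
#'
#' For cylindrical wells the mean particle number should scale with the
#' geometric volume: quadratically with the diameter at fixed depth
#' (log-log slope 2) and linearly with the milling depth at fixed diameter
#' (positive slope; positive intercept from the aperture bore volume).
#'
#' @param results Data frame with columns `d_nm`, `h_nm`, `N`.
#' @return List with `d_exponent` (log-log slope of N vs d, with `se` and
#'   95% CI) per depth, and `h_slope`/`h_intercept` (linear N vs h) per
#'   diameter.
#' @export
scaling_analysis <- function(results) {
  stopifnot(all(c("d_nm", "h_nm", "N") %in% names(results)))
  d_fit <- lapply(split(results, results$h_nm), function(df) {
    if (length(unique(df$d_nm)) < 3) return(NULL)
    fm <- stats::lm(log(N) ~ log(d_nm), data = df[df$N > 0, ])
    ci <- suppressWarnings(stats::confint(fm))["log(d_nm)", ]
    sm <- suppressWarnings(summary(fm))  # exact geometric inputs fit perfectly
    data.frame(h_nm = df$h_nm[1], d_exponent = stats::coef(fm)[["log(d_nm)"]],
               se = sm$coefficients["log(d_nm)", "Std. Error"],
               ci_lo = ci[1], ci_hi = ci[2], row.names = NULL)
  })
  h_fit <- lapply(split(results, results$d_nm), function(df) {
    if (length(unique(df$h_nm)) < 3) return(NULL)
    fm <- stats::lm(N ~ h_nm, data = df)
    data.frame(d_nm = df$d_nm[1],
               h_slope = stats::coef(fm)[["h_nm"]],
               h_intercept = stats::coef(fm)[["(Intercept)"]],
               row.names = NULL)
  })
  d_fit <- do.call(rbind, d_fit[!vapply(d_fit, is.null, TRUE)])
  h_fit <- do.call(rbind, h_fit[!vapply(h_fit, is.null, TRUE)])
  if (is.null(d_fit) && is.null(h_fit))
    stop("degenerate grid: need >= 3 points along at least one axis")
  list(by_depth = d_fit, by_diameter = h_fit)
}
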