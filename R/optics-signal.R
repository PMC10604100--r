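# Metal-modified fluorescence calculus: quantum yield, lifetime, detection
# efficiency, detected signal and enhancement profiles along the pore axis.

#' Metal-modified quantum yield
#'
#' Quantum yield of a fluorophore whose radiative rate is modified to
#' `gamma_r_rel * gamma_r0` and which acquires a nonradiative loss channel
#' `gamma_loss_rel * gamma_r0` to the metal, while its internal nonradiative
#' relaxation is unchanged:
#' `Phi = gamma_r_rel / (gamma_r_rel + gamma_loss_rel + (1 - Phi0)/Phi0)`.
#'
#' @param gamma_r_rel Radiative rate ratio `gamma_r/gamma_r0` (>= 0);
#'   vectorized.
#' @param gamma_loss_rel Loss rate ratio `gamma_loss/gamma_r0` (>= 0).
#' @param fluor A [fluorophore()] supplying the intrinsic quantum yield.
#' @return Quantum yield in `[0, 1]`.
#' @examples
#' quantum_yield_zmw(1, 0, fluorophore_preset("Alexa488"))  # 0.8, free space
#' @export
quantum_yield_zmw <- function(gamma_r_rel, gamma_loss_rel, fluor) {
  stopifnot(inherits(fluor, "fluorophore"))
  if (any(gamma_r_rel < 0) || any(gamma_loss_rel < 0))
    stop("rate ratios must be >= 0")
  phi0 <- fluor$quantum_yield
  gamma_r_rel / (gamma_r_rel + gamma_loss_rel + (1 - phi0) / phi0)
}

#' Fluorescence lifetime from the modified rates
#'
#' Uses `tau = Phi / gamma_r` with `gamma_r = gamma_r_rel * Phi0/tau0`, so
#' that in free space (`Phi = Phi0`, `gamma_r_rel = 1`) the free-dye
#' lifetime is recovered exactly.
#'
#' @param phi Quantum yield in the structure (vectorized).
#' @param gamma_r_rel Radiative rate ratio (> 0).
#' @param fluor A [fluorophore()].
#' @return Lifetime (ns).
#' @export
lifetime_from_rates <- function(phi, gamma_r_rel, fluor) {
  stopifnot(inherits(fluor, "fluorophore"))
  if (any(gamma_r_rel <= 0)) stop("gamma_r_rel must be > 0 for a finite lifetime")
  phi / (gamma_r_rel * fluor$gamma_r0)
}

#' Detection efficiency
#'
#' Fraction of the far-field power radiated toward the lower (detection)
#' half-space, `eta = P_ff_down / P_ff_total`.
#'
#' @param p_ff_down Far-field power into the detection half-space.
#' @param p_ff_total Total far-field power (> 0).
#' @return Efficiency in `[0, 1]`.
#' @export
detection_efficiency <- function(p_ff_down, p_ff_total) {
  if (any(p_ff_total <= 0)) stop("total far-field power must be > 0")
  if (any(p_ff_down < 0) || any(p_ff_down > p_ff_total * (1 + 1e-9)))
    stop("need 0 <= P_ff_down <= P_ff_total")
  pmin(p_ff_down / p_ff_total, 1)
}

#' Detected signal profile
#'
#' Pointwise product `S(z) = I_ex(z) * eta(z) * Phi(z)` on a shared z grid.
#'
#' @param i_ex Relative excitation intensity.
#' @param eta Detection efficiency.
#' @param phi Quantum yield.
#' @return Detected signal (arbitrary units), same length.
#' @export
detected_signal <- function(i_ex, eta, phi) {
  if (length(i_ex) != length(eta) || length(i_ex) != length(phi))
    stop("grid mismatch: I_ex, eta and Phi must share one z grid")
  i_ex * eta * phi
}

#' Axial signal model for a nanowell
#'
#' Combines an excitation profile and a dipole emission profile for one
#' geometry and fluorophore into the full axial calculus: quantum yield
#' `Phi(z)`, lifetime `tau(z)`, detection efficiency `eta(z)`, detected
#' signal `S(z)` and enhancement `zeta(z) = S(z) / (I_ex0 * eta0 * Phi0)`,
#' where the free-diffusion reference assumes `eta0 = 0.5` (half the
#' emission detected) and unit relative excitation.
#'
#' The two profiles must be given on the same strictly increasing z grid
#' (package convention: z = 0 at the lower metal surface, positive into the
#' nanowell).
#'
#' @param geometry A [nanowell_geometry()].
#' @param fluor A [fluorophore()].
#' @param excitation An [excitation_profile()].
#' @param emission A [dipole_emission_profile()] on the same grid.
#' @param eta0 Free-diffusion detection efficiency (default 0.5).
#' @param i_ex0 Free-diffusion relative excitation intensity (default 1).
#' @return An object of class `signal_model`: a list with the geometry,
#'   fluorophore, reference constants and a data frame `profile` with
#'   columns `z`, `i_ex`, `phi`, `tau_ns`, `eta`, `s`, `zeta`.
#' @export
signal_model <- function(geometry, fluor, excitation, emission,
                         eta0 = 0.5, i_ex0 = 1) {
  stopifnot(inherits(geometry, "nanowell_geometry"), inherits(fluor, "fluorophore"),
            inherits(excitation, "excitation_profile"),
            inherits(emission, "dipole_emission_profile"))
  if (length(excitation$z) != length(emission$z) ||
      any(abs(excitation$z - emission$z) > 1e-9))
    stop("grid mismatch: excitation and emission profiles must share one z grid")
  rr <- relative_rates(emission)
  phi <- quantum_yield_zmw(rr$gamma_r_rel, rr$gamma_loss_rel, fluor)
  tau <- lifetime_from_rates(phi, rr$gamma_r_rel, fluor)
  eta <- detection_efficiency(emission$p_ff_down, emission$p_ff)
  s <- detected_signal(excitation$intensity, eta, phi)
  zeta <- s / (i_ex0 * eta0 * fluor$quantum_yield)
  structure(list(geometry = geometry, fluor = fluor,
                 eta0 = eta0, i_ex0 = i_ex0,
                 profile = data.frame(z = excitation$z, i_ex = excitation$intensity,
                                      phi = phi, tau_ns = tau, eta = eta,
                                      s = s, zeta = zeta)),
            class = "signal_model")
}

#' @export
print.signal_model <- function(x, ...) {
  cat(sprintf("signal model: %s in d = %g nm / h = %g nm nanowell; %d z-points\n",
              x$fluor$label, x$geometry$diameter, x$geometry$overmill_depth,
              nrow(x$profile)))
  cat(sprintf("  signal-weighted <zeta> = %.3f, <tau> = %.3f ns\n",
              average_enhancement(x), signal_averaged_lifetime(x)))
  invisible(x)
}

#' Enhancement profile
#'
#' `zeta(z) = S(z) / (I_ex0 * eta0 * Phi0)`: the detected signal relative to
#' the free-diffusion reference. Equals 1 everywhere for a free-space
#' configuration.
#'
#' @param s Detected signal S(z).
#' @param fluor A [fluorophore()].
#' @param eta0,i_ex0 Free-diffusion reference constants.
#' @return Enhancement factor zeta(z).
#' @export
enhancement_profile <- function(s, fluor, eta0 = 0.5, i_ex0 = 1) {
  stopifnot(inherits(fluor, "fluorophore"))
  s / (i_ex0 * eta0 * fluor$quantum_yield)
}

# trapezoidal quadrature on the native grid
.trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# restrict a signal-model profile to the axial averaging window: from the
# bottom of the well (z = h) through the aperture to 200 nm beyond the
# reference plane on the bulk side
.average_window <- function(model) {
  p <- model$profile
  h <- model$geometry$overmill_depth
  sel <- p$z >= -200 & p$z <= h
  if (sum(sel) < 2) stop("averaging window is empty on this grid")
  p[sel, , drop = FALSE]
}

#' Signal-weighted average enhancement
#'
#' `zeta_bar = integral(zeta(z) S(z) dz) / integral(S(z) dz)` over the axial
#' window from the bottom of the well to 200 nm beyond the metal reference
#' plane, by trapezoidal quadrature on the native grid.
#'
#' @param model A [signal_model()].
#' @return Scalar average enhancement.
#' @export
average_enhancement <- function(model) {
  stopifnot(inherits(model, "signal_model"))
  p <- .average_window(model)
  denom <- .trapz(p$z, p$s)
  if (denom <= 0) stop("total signal in the averaging window is zero")
  .trapz(p$z, p$zeta * p$s) / denom
}

#' Signal-weighted average lifetime
#'
#' `<tau> = integral(tau(z) S(z) dz) / integral(S(z) dz)` over the same
#' axial window as [average_enhancement()]; this is the model prediction to
#' compare against a measured (fitted) lifetime.
#'
#' @param model A [signal_model()].
#' @return Average lifetime (ns).
#' @export
signal_averaged_lifetime <- function(model) {
  stopifnot(inherits(model, "signal_model"))
  p <- .average_window(model)
  denom <- .trapz(p$z, p$s)
  if (denom <= 0) stop("total signal in the averaging window is zero")
  .trapz(p$z, p$tau_ns * p$s) / denom
}
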