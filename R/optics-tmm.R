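# 1-D thin-film optics: layer stacks, transfer-matrix field solution, and the
# standing-wave excitation profile below the metal film.

#' Palladium refractive index
#'
#' Complex refractive index n + ik of palladium, interpolated linearly in
#' log-wavelength from a bundled tabulation
#' (`system.file("extdata/pd_nk.csv", package = "nanowell")`). The bundled
#' table is generated from a five-oscillator Drude-Lorentz parametrization of
#' published Pd ellipsometry (plasma energy 9.72 eV; oscillator strengths
#' 0.330, 0.649, 0.121, 0.638, 0.453; widths 0.008, 2.950, 0.555, 4.621,
#' 3.236 eV; energies 0, 0.336, 0.501, 1.659, 5.715 eV) and covers
#' 300-900 nm. The table is a configuration item: supply your own via
#' `table` to use a different source of optical constants.
#'
#' @param wavelength Vacuum wavelength (nm); vectorized.
#' @param table Optional data frame with columns `wavelength_nm`, `n`, `k`.
#' @return Complex refractive index (same length as `wavelength`).
#' @export
pd_refractive_index <- function(wavelength, table = NULL) {
  if (is.null(table)) table <- .pd_table()
  stopifnot(all(c("wavelength_nm", "n", "k") %in% names(table)))
  rng <- range(table$wavelength_nm)
  if (any(wavelength < rng[1] | wavelength > rng[2]))
    stop(sprintf("wavelength outside tabulated range [%g, %g] nm", rng[1], rng[2]))
  lw <- log(table$wavelength_nm)
  n <- stats::approx(lw, table$n, xout = log(wavelength))$y
  k <- stats::approx(lw, table$k, xout = log(wavelength))$y
  complex(real = n, imaginary = k)
}

.pd_env <- new.env(parent = emptyenv())
.pd_table <- function() {
  if (is.null(.pd_env$tab)) {
    f <- system.file("extdata", "pd_nk.csv", package = "nanowell")
    .pd_env$tab <- utils::read.csv(f)
  }
  .pd_env$tab
}

#' Planar layer stack
#'
#' A stack of homogeneous layers for the 1-D transfer-matrix solver. The
#' first and last entries are semi-infinite half-spaces (`thickness = Inf`);
#' light is incident from the first layer.
#'
#' @param index Complex (or real) refractive index per layer.
#' @param thickness Layer thicknesses (nm); first and last must be `Inf`.
#' @param label Optional layer names.
#' @return An object of class `layer_stack`.
#' @examples
#' layer_stack(c(1.335, pd_refractive_index(488), 1.52),
#'             c(Inf, 100, Inf), c("water", "Pd", "glass"))
#' @export
layer_stack <- function(index, thickness, label = NULL) {
  index <- as.complex(index)
  if (length(index) != length(thickness) || length(index) < 2)
    stop("need matching index/thickness vectors with at least two layers")
  if (!is.infinite(thickness[1]) || !is.infinite(thickness[length(thickness)]))
    stop("first and last layers must be semi-infinite (thickness = Inf)")
  if (length(thickness) > 2 && any(thickness[-c(1, length(thickness))] <= 0))
    stop("interior layer thicknesses must be positive")
  if (any(Re(index) <= 0)) stop("nonphysical refractive index (Re <= 0)")
  if (any(Im(index) < 0)) stop("nonphysical refractive index (Im < 0, gain media unsupported)")
  if (Im(index[1]) != 0) stop("incidence medium must be lossless")
  if (is.null(label)) label <- paste0("layer", seq_along(index))
  structure(list(index = index, thickness = thickness, label = label),
            class = "layer_stack")
}

# Airy recursion for a multilayer: effective reflection seen from each layer
# and forward amplitudes at each left edge. Scalar amplitudes; pol = "s" or
# "p" selects the Fresnel coefficients.
.tmm_solve <- function(stack, wavelength, angle_deg = 0, pol = "s") {
  N <- stack$index
  d <- stack$thickness
  L <- length(N)
  k0 <- 2 * pi / wavelength
  sin1 <- sin(angle_deg * pi / 180)
  # kz with branch Im >= 0 so evanescent waves decay in +x
  kz <- k0 * sqrt(N^2 - (N[1] * sin1)^2 + 0i)
  kz <- ifelse(Im(kz) < 0, -kz, kz)
  rf <- tf <- vector("complex", L - 1)
  for (j in seq_len(L - 1)) {
    if (pol == "s") {
      rf[j] <- (kz[j] - kz[j + 1]) / (kz[j] + kz[j + 1])
      tf[j] <- 2 * kz[j] / (kz[j] + kz[j + 1])
    } else {
      num <- N[j + 1]^2 * kz[j] - N[j]^2 * kz[j + 1]
      den <- N[j + 1]^2 * kz[j] + N[j]^2 * kz[j + 1]
      rf[j] <- num / den
      tf[j] <- 2 * N[j] * N[j + 1] * kz[j] / den
    }
  }
  # back-to-front: rho[j] = reflection seen from layer j at its right
  # interface; rho_tilde[j] = same referenced to the layer's left edge
  rho <- rho_tilde <- vector("complex", L)
  rho_tilde[L] <- 0
  for (j in (L - 1):1) {
    rt_next <- if (j + 1 == L) 0 else rho[j + 1] * exp(2i * kz[j + 1] * d[j + 1])
    rho[j] <- (rf[j] + rt_next) / (1 + rf[j] * rt_next)
    rho_tilde[j] <- NA  # set below for interior layers
  }
  for (j in 2:(L - 1)) if (L > 2) rho_tilde[j] <- rho[j] * exp(2i * kz[j] * d[j])
  # forward amplitudes at left edges; incidence amplitude 1 at interface 1
  cc <- vector("complex", L)
  cc[1] <- 1
  for (j in 2:L) {
    phi_prev <- if (j == 2) 1 else exp(1i * kz[j - 1] * d[j - 1])
    rt <- if (j == L) 0 else rho_tilde[j]
    cc[j] <- tf[j - 1] * cc[j - 1] * phi_prev / (1 + rf[j - 1] * rt)
  }
  r <- rho[1]
  t <- cc[L]
  Rr <- Mod(r)^2
  Tt <- if (pol == "s") {
    Re(kz[L]) / Re(kz[1]) * Mod(t)^2
  } else {
    # p-pol power factor Re(N cos*) with cos_j = kz_j/(k0 N_j)
    Re(N[L] * Conj(kz[L] / (k0 * N[L]))) / Re(N[1] * kz[1] / (k0 * N[1])) * Mod(t)^2
  }
  list(kz = kz, r = r, t = t, R = Rr, T = Tt, A = 1 - Rr - Tt,
       cc = cc, rho = rho, rho_tilde = rho_tilde, d = d, L = L)
}

# complex field amplitude at positions x (nm); x = 0 at the first interface,
# x < 0 in the incidence medium, x increasing toward the exit half-space
.tmm_field <- function(sol, x) {
  # left edges of layers 2..L
  edges <- if (sol$L > 2) c(0, cumsum(sol$d[2:(sol$L - 1)])) else 0
  E <- complex(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    if (xi <= 0) {
      E[i] <- exp(1i * sol$kz[1] * xi) + sol$rho[1] * exp(-1i * sol$kz[1] * xi)
    } else {
      j <- findInterval(xi, edges, rightmost.closed = FALSE) + 1  # layer index
      if (j >= sol$L) {
        xi_loc <- xi - edges[length(edges)]
        E[i] <- sol$cc[sol$L] * exp(1i * sol$kz[sol$L] * xi_loc)
      } else {
        xi_loc <- xi - edges[j - 1]
        rt <- sol$rho_tilde[j]
        E[i] <- sol$cc[j] * (exp(1i * sol$kz[j] * xi_loc) + rt * exp(-1i * sol$kz[j] * xi_loc))
      }
    }
  }
  E
}

#' Reflectance, transmittance and absorbance of a layer stack
#'
#' Solves the stack with the transfer-matrix method and returns the energy
#' balance. `A_flux` is absorbance computed independently from the Poynting
#' flux drop across each absorbing layer (field-gradient quadrature), so
#' `R + T + A_flux = 1` is a genuine numerical check, not an identity. The
#' flux decomposition is implemented for s-polarization; for p-polarization
#' `A_flux` is returned as `NA`.
#'
#' @param stack A [layer_stack()].
#' @param wavelength Vacuum wavelength (nm).
#' @param angle_deg Angle of incidence in the first medium (degrees).
#' @param pol Polarization, `"s"` (default) or `"p"`.
#' @return List with `R`, `T`, `A` (`= 1 - R - T`) and `A_flux`.
#' @export
tmm_energy <- function(stack, wavelength, angle_deg = 0, pol = c("s", "p")) {
  pol <- match.arg(pol)
  sol <- .tmm_solve(stack, wavelength, angle_deg, pol)
  # normalized Poynting flux f(xi) = Im(conj(E) dE/dx)/Re(kz1) inside layer j,
  # with E = a e^{i kz xi} + b e^{-i kz xi} evaluated analytically
  flux_in_layer <- function(j, xi) {
    a <- sol$cc[j]
    b <- a * if (j == sol$L) 0 else sol$rho_tilde[j]
    Ef <- a * exp(1i * sol$kz[j] * xi)
    Eb <- b * exp(-1i * sol$kz[j] * xi)
    Im(Conj(Ef + Eb) * (1i * sol$kz[j]) * (Ef - Eb)) / Re(sol$kz[1])
  }
  a_flux <- if (pol == "p") NA_real_ else 0
  if (sol$L > 2 && pol == "s") {
    for (j in 2:(sol$L - 1)) {
      if (Im(stack$index[j]) > 0) {
        a_flux <- a_flux + (flux_in_layer(j, 0) - flux_in_layer(j, sol$d[j]))
      }
    }
  }
  list(R = sol$R, T = sol$T, A = sol$A, A_flux = a_flux)
}

#' Excitation profile object
#'
#' Relative excitation intensity `I_ex(z)/I0` on an axial grid, in the
#' package z-convention (`z = 0` at the lower metal surface, positive toward
#' the detection side / into the nanowell).
#'
#' @param z Strictly increasing axial grid (nm).
#' @param intensity Relative intensities (>= 0).
#' @param mode Illumination tag, e.g. `"widefield"` or `"tirf(70)"`.
#' @param wavelength Vacuum wavelength (nm).
#' @return An object of class `excitation_profile`.
#' @export
excitation_profile <- function(z, intensity, mode = "widefield", wavelength = NA_real_) {
  stopifnot(length(z) == length(intensity))
  if (is.unsorted(z, strictly = TRUE)) stop("z grid must be strictly increasing")
  if (any(intensity < 0)) stop("intensities must be >= 0")
  structure(list(z = z, intensity = intensity, mode = mode, wavelength = wavelength),
            class = "excitation_profile")
}

#' @export
print.excitation_profile <- function(x, ...) {
  cat(sprintf("excitation profile (%s, %g nm): %d points, z in [%g, %g] nm, peak %.3g\n",
              x$mode, x$wavelength, length(x$z), min(x$z), max(x$z), max(x$intensity)))
  invisible(x)
}

#' Standing-wave excitation profile below a metal film
#'
#' One-dimensional transfer-matrix intensity `|E(z)|^2/|E0|^2` in the
#' incidence medium below the film. Light reflected off the metal interferes
#' with the incident wave and forms a standing wave on the detection side;
#' at oblique incidence the axial period is set by the z-component of the
#' wave vector, which shifts the first intensity maximum away from the metal
#' surface (the TIRF regime behaviour).
#'
#' The returned profile uses the package z-convention: `z > 0` is distance
#' from the film into the incidence (detection-side) medium; `z <= 0` samples
#' the field inside the film and beyond (transmitted side), giving the
#' blocked/leak-through background level.
#'
#' @param wavelength Vacuum wavelength (nm).
#' @param angle_deg Angle of incidence (degrees, in the incidence medium).
#' @param stack A [layer_stack()]; incidence from the first layer, metal film
#'   as interior layer(s). Defaults to water / 100 nm Pd / water.
#' @param z Axial grid (nm); default `seq(-200, 400, by = 1)` beyond the
#'   metal into the well.
#' @param pol Polarization (`"s"` default).
#' @return An [excitation_profile()].
#' @examples
#' p <- standing_wave_profile(488)
#' max(p$intensity)  # ~3-fold peak above the incident intensity
#' @export
standing_wave_profile <- function(wavelength, angle_deg = 0, stack = NULL,
                                  z = seq(-200, 400, by = 1), pol = "s") {
  if (is.null(stack)) {
    stack <- layer_stack(c(1.335, pd_refractive_index(wavelength), 1.335),
                         c(Inf, 100, Inf), c("water", "Pd", "backing"))
  }
  sol <- .tmm_solve(stack, wavelength, angle_deg, pol)
  # package z (into the incidence medium) maps to solver x = -z
  E <- .tmm_field(sol, -z)
  excitation_profile(z, Mod(E)^2, mode = if (angle_deg == 0) "widefield"
                     else sprintf("tirf(%g)", angle_deg), wavelength = wavelength)
}
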