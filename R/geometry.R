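#' Nanowell geometry
#'
#' Describes a single overmilled zero-mode-waveguide (ZMW) pore: a cylindrical
#' aperture of diameter `diameter` through a metal film of thickness
#' `metal_thickness`, continued by a nanowell milled `overmill_depth` into the
#' glass beneath the film.
#'
#' The axial convention used throughout the package is: `z = 0` at the lower
#' (glass-side) metal surface, `z > 0` toward the detection side, i.e. into
#' the nanowell and the glass; the metal occupies `[-metal_thickness, 0]` and
#' the bulk solution lies at `z < -metal_thickness`.
#'
#' @param diameter Pore diameter d (nm).
#' @param metal_thickness Metal film thickness (nm).
#' @param overmill_depth Overmilling depth h into the glass (nm); 0 for a
#'   standard (non-overmilled) ZMW.
#' @param taper_angle Wall taper from vertical (degrees); the default 0 is a
#'   straight cylinder. Taper affects geometric volume only, not the 1-D
#'   optics.
#' @return An object of class `nanowell_geometry`.
#' @examples
#' g <- nanowell_geometry(200, 100, 150)
#' nanowell_volume(g)  # liters
#' @export
nanowell_geometry <- function(diameter, metal_thickness, overmill_depth = 0,
                              taper_angle = 0) {
  stopifnot(is.numeric(diameter), length(diameter) == 1L,
            is.numeric(metal_thickness), length(metal_thickness) == 1L,
            is.numeric(overmill_depth), length(overmill_depth) == 1L)
  if (diameter <= 0) stop("pore diameter must be positive")
  if (metal_thickness <= 0) stop("metal thickness must be positive")
  if (overmill_depth < 0) stop("overmill depth must be >= 0")
  if (taper_angle < 0) stop("taper angle must be >= 0")
  structure(list(diameter = diameter,
                 metal_thickness = metal_thickness,
                 overmill_depth = overmill_depth,
                 taper_angle = taper_angle),
            class = "nanowell_geometry")
}

#' @export
print.nanowell_geometry <- function(x, ...) {
  cat(sprintf("ZMW nanowell: d = %g nm, metal %g nm, overmill h = %g nm, taper %g deg\n",
              x$diameter, x$metal_thickness, x$overmill_depth, x$taper_angle))
  invisible(x)
}

#' Geometric volume of a nanowell (aperture + overmilled well)
#'
#' Volume of the cylinder of diameter `d` spanning the metal aperture and the
#' overmilled well, i.e. depth `metal_thickness + overmill_depth`. A non-zero
#' taper widens the well linearly with depth (conical frustum).
#'
#' @param geometry A [nanowell_geometry()].
#' @param include_aperture Include the aperture bore through the metal
#'   (default `TRUE`).
#' @return Volume in liters.
#' @export
nanowell_volume <- function(geometry, include_aperture = TRUE) {
  stopifnot(inherits(geometry, "nanowell_geometry"))
  depth <- geometry$overmill_depth + if (include_aperture) geometry$metal_thickness else 0
  r0 <- geometry$diameter / 2
  if (geometry$taper_angle == 0) {
    v_nm3 <- pi * r0^2 * depth
  } else {
    r1 <- r0 + depth * tan(geometry$taper_angle * pi / 180)
    v_nm3 <- pi * depth * (r0^2 + r0 * r1 + r1^2) / 3
  }
  v_nm3 * 1e-24  # 1 L = 1e24 nm^3
}

#' Fluorophore photophysics
#'
#' Intrinsic photophysical constants of a fluorophore in free solution. The
#' intrinsic radiative rate is gamma_r0 = Phi0/tau0 and the intrinsic
#' nonradiative rate gamma_nr0 = gamma_r0 (1 - Phi0)/Phi0; the nonradiative
#' internal relaxation is assumed unaffected by the nanostructure.
#'
#' @param label Name of the dye.
#' @param quantum_yield Intrinsic quantum yield Phi0 in (0, 1].
#' @param lifetime_ns Free-dye fluorescence lifetime tau0 (ns).
#' @param lambda_ex,lambda_em Excitation / emission wavelengths (nm).
#' @return An object of class `fluorophore`.
#' @examples
#' fluorophore_preset("Alexa488")
#' @export
fluorophore <- function(label, quantum_yield, lifetime_ns,
                        lambda_ex = NA_real_, lambda_em = NA_real_) {
  if (!is.numeric(quantum_yield) || quantum_yield <= 0 || quantum_yield > 1)
    stop("quantum yield must be in (0, 1]")
  if (!is.numeric(lifetime_ns) || lifetime_ns <= 0)
    stop("lifetime must be positive")
  gr0 <- quantum_yield / lifetime_ns
  structure(list(label = label,
                 quantum_yield = quantum_yield,
                 lifetime_ns = lifetime_ns,
                 lambda_ex = lambda_ex,
                 lambda_em = lambda_em,
                 gamma_r0 = gr0,                                  # 1/ns
                 gamma_nr0 = gr0 * (1 - quantum_yield) / quantum_yield),
            class = "fluorophore")
}

#' @export
print.fluorophore <- function(x, ...) {
  cat(sprintf("fluorophore %s: Phi0 = %g, tau0 = %g ns (ex %g / em %g nm)\n",
              x$label, x$quantum_yield, x$lifetime_ns, x$lambda_ex, x$lambda_em))
  invisible(x)
}

#' Preset fluorophores
#'
#' Literature constants for the two dyes used throughout: Alexa488
#' (Phi0 = 0.8, tau0 = 4.0 ns, 488/520 nm) and JFX650 (Phi0 = 0.53,
#' tau0 = 3.9 ns, 640/670 nm).
#'
#' @param name `"Alexa488"` or `"JFX650"`.
#' @return A [fluorophore()].
#' @export
fluorophore_preset <- function(name = c("Alexa488", "JFX650")) {
  name <- match.arg(name)
  switch(name,
         Alexa488 = fluorophore("Alexa488", 0.8, 4.0, 488, 520),
         JFX650   = fluorophore("JFX650", 0.53, 3.9, 640, 670))
}

#' Avogadro's number (1/mol)
#' @keywords internal
.N_AVOGADRO <- 6.02214076e23
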