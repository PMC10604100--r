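# Generator for the axial optics profiles a field solver would supply:
# standing-wave + evanescent excitation, and mirror-model dipole emission.

#' Generate excitation and emission profiles for a nanowell
#'
#' Builds the two axial inputs of [signal_model()] semi-analytically:
#'
#' * Excitation: the transfer-matrix standing wave in the well (`z > 0`,
#'   incidence from the detection side), stitched at the metal surface to
#'   the first-order evanescent decay inside the aperture
#'   (`-t_m < z <= 0`), continuing at the aperture-exit attenuation
#'   (`exp(-t_m/Lambda)`) into the bulk (`z < -t_m`).
#' * Emission: the planar-mirror dipole model for emitters in the well;
#'   inside the aperture and in the bulk the far-field reaching the
#'   detection side is attenuated by the same evanescent factor at the
#'   emission wavelength (emitters beyond the metal are seen only through
#'   the aperture), with unmodified total emission.
#'
#' For apertures above cutoff at the relevant wavelength there is no finite
#' evanescent decay length; `propagating = "transmit"` then applies no
#' aperture attenuation, while the default `"error"` refuses to stitch.
#' Deterministic given its inputs.
#'
#' @param geometry A [nanowell_geometry()].
#' @param fluor A [fluorophore()].
#' @param mode `"widefield"` or `"tirf"`.
#' @param z Axial grid (nm); default covers bulk to well bottom.
#' @param n_medium Refractive index of the aqueous medium.
#' @param tirf_angle Incidence angle (degrees) when `mode = "tirf"`.
#' @param propagating `"error"` (default) or `"transmit"`: behaviour when
#'   the aperture is above cutoff.
#' @return List with elements `excitation` ([excitation_profile()]) and
#'   `emission` ([dipole_emission_profile()]) on the shared grid.
#' @examples
#' g <- nanowell_geometry(100, 100, 100)
#' pr <- make_optics_profiles(g, fluorophore_preset("Alexa488"))
#' @export
make_optics_profiles <- function(geometry, fluor, mode = c("widefield", "tirf"),
                                 z = NULL, n_medium = 1.335, tirf_angle = 70,
                                 propagating = c("error", "transmit")) {
  stopifnot(inherits(geometry, "nanowell_geometry"), inherits(fluor, "fluorophore"))
  mode <- match.arg(mode)
  propagating <- match.arg(propagating)
  tm <- geometry$metal_thickness
  h <- geometry$overmill_depth
  if (is.null(z)) z <- seq(-(tm + 220), max(h, 1) + 20, by = 2)
  if (is.unsorted(z, strictly = TRUE)) stop("z grid must be strictly increasing")

  decay_len <- function(wavelength) {
    lc <- cutoff_wavelength(geometry$diameter)
    lm <- wavelength / n_medium
    if (lm < lc) {
      if (propagating == "error")
        stop("aperture is above cutoff at ", wavelength,
             " nm: no evanescent decay length (set propagating = \"transmit\" ",
             "to stitch without attenuation)")
      return(Inf)
    }
    evanescent_decay_length(geometry$diameter, wavelength, n_medium)
  }
  lam_ex <- decay_len(fluor$lambda_ex)
  lam_em <- decay_len(fluor$lambda_em)

  # excitation: standing wave on the well side of the film
  npd_ex <- pd_refractive_index(fluor$lambda_ex)
  stack <- layer_stack(c(n_medium, npd_ex, n_medium), c(Inf, tm, Inf),
                       c("medium", "Pd", "bulk"))
  angle <- if (mode == "tirf") tirf_angle else 0
  zwell <- z[z >= 0]
  i_ex <- numeric(length(z))
  sw <- standing_wave_profile(fluor$lambda_ex, angle, stack,
                              z = if (length(zwell)) zwell else 0)
  i_surface <- standing_wave_profile(fluor$lambda_ex, angle, stack, z = c(0, 1))$intensity[1]
  i_ex[z >= 0] <- sw$intensity
  inside <- z < 0 & z >= -tm
  i_ex[inside] <- i_surface * evan_factor(-z[inside], lam_ex)
  i_ex[z < -tm] <- i_surface * evan_factor(tm, lam_ex)
  excitation <- excitation_profile(z, i_ex, mode = sw$mode,
                                   wavelength = fluor$lambda_ex)

  # emission: mirror model in the well; aperture-attenuated free dipole beyond
  p_r <- rep(1, length(z))
  p_ff <- rep(1, length(z))
  p_ffd <- rep(0.5, length(z))
  well <- z > 0
  if (any(well)) {
    em <- mirror_dipole_profile(z[well], fluor$lambda_em, reflector = "pd",
                                orientation = "isotropic", n_medium = n_medium)
    p_r[well] <- em$p_r
    p_ff[well] <- em$p_ff
    p_ffd[well] <- em$p_ff_down
  }
  depth_to_exit <- pmin(-z[!well], tm)   # path length through the aperture
  p_ffd[!well] <- 0.5 * evan_factor(depth_to_exit, lam_em)
  emission <- dipole_emission_profile(z, p_r, p_ff, p_ffd, "isotropic")

  list(excitation = excitation, emission = emission)
}

# exp(-depth/Lambda), with Lambda = Inf meaning no attenuation
evan_factor <- function(depth, decay_length) {
  if (is.infinite(decay_length)) rep(1, length(depth)) else exp(-depth / decay_length)
}
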