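#' ZMW cutoff wavelength
#'
#' Longest wavelength that propagates through a circular aperture of diameter
#' `d`; light with wavelength (in the medium) above the cutoff is evanescent
#' inside the waveguide. For these ZMWs the first-order relation
#' `lambda_c = 1.7 d` is used.
#'
#' @param d Aperture diameter (nm); vectorized.
#' @return Cutoff wavelength (nm).
#' @examples
#' cutoff_wavelength(100)  # 170 nm
#' @export
cutoff_wavelength <- function(d) {
  if (!is.numeric(d) || any(d < 0)) stop("aperture diameter must be >= 0")
  1.7 * d
}

#' Evanescent intensity decay length inside a below-cutoff ZMW
#'
#' First-order 1/e decay length of the excitation *intensity* inside a
#' below-cutoff circular waveguide,
#' `Lambda = 1 / (4 pi sqrt(1/lambda_c^2 - 1/lambda_m^2))`,
#' where `lambda_c = 1.7 d` and `lambda_m = lambda / n_medium` is the
#' wavelength in the medium. Valid only in the evanescent regime
#' `lambda_m > lambda_c`; in the propagating regime there is no finite decay
#' length and the function errors (or returns `Inf` exactly at cutoff).
#'
#' @param d Aperture diameter (nm).
#' @param wavelength Vacuum wavelength (nm).
#' @param n_medium Refractive index of the medium filling the aperture.
#' @return Decay length Lambda (nm).
#' @examples
#' evanescent_decay_length(100, 488, 1.33)  # ~15.3 nm
#' @export
evanescent_decay_length <- function(d, wavelength, n_medium = 1.33) {
  if (any(d < 0)) stop("aperture diameter must be >= 0")
  if (any(wavelength <= 0) || any(n_medium <= 0)) stop("wavelength and index must be positive")
  lc <- cutoff_wavelength(d)
  lm <- wavelength / n_medium
  if (any(lm < lc)) {
    stop("propagating regime (lambda/n >= cutoff is required): no finite decay length; ",
         "aperture supports a guided mode")
  }
  1 / (4 * pi * sqrt(1 / lc^2 - 1 / lm^2))
}

#' Evanescent intensity profile inside the aperture
#'
#' Relative excitation intensity `exp(-z'/Lambda)` at depth `z'` into the
#' aperture from its illuminated entry.
#'
#' @param depth Distance into the aperture from the illuminated side (nm);
#'   vectorized, values < 0 are clamped to 0 (no decay before entry).
#' @param decay_length Decay length Lambda (nm), from
#'   [evanescent_decay_length()].
#' @return Relative intensity (unitless).
#' @export
evanescent_intensity <- function(depth, decay_length) {
  stopifnot(decay_length > 0)
  exp(-pmax(depth, 0) / decay_length)
}
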