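# shared fixtures: small geometries, dyes and reference constants

alexa <- fluorophore_preset("Alexa488")
jfx <- fluorophore_preset("JFX650")

geom_std <- nanowell_geometry(200, 100, 200)
geom_small <- nanowell_geometry(100, 100, 100)

N_AV <- 6.02214076e23

well_volume_l <- function(g) pi * (g$diameter / 2)^2 * g$overmill_depth * 1e-24

# trapezoid quadrature used as an independent check of weighted averages
trapz_ref <- function(x, y) sum((y[-1] + y[-length(y)]) * diff(x)) / 2

# memoized 20-seed open-cylinder FCS fits shared by two acceptance checks
.fits_cache <- new.env(parent = emptyenv())
open_cylinder_fits <- function() {
  if (is.null(.fits_cache$fits)) {
    g <- nanowell_geometry(300, 100, 300)
    .fits_cache$fits <- vapply(1:20, function(s) {
      cfg <- sim_config(seed = 4000 + s, concentration = 2e-6, duration_s = 0.4,
                        dt_us = 1, bin_ms = 0.005, brightness_cpms = 120,
                        reservoir_depth_nm = 250, reservoir_side_nm = 500)
      tr <- suppressWarnings(simulate_photon_trace(g, cfg))
      fit_fcs(autocorrelate(tr, max_lag_ms = 2))$N
    }, 0)
  }
  .fits_cache$fits
}

# deterministic telegraph trace with Gaussian noise, for HMM tests
make_telegraph <- function(n_frames, peak, sigma, p_switch = 0.02, seed = 1) {
  withr::with_seed(seed, {
    state <- integer(n_frames)
    s <- 0L
    for (t in seq_len(n_frames)) {
      if (runif(1) < p_switch) s <- 1L - s
      state[t] <- s
    }
    list(state = state, x = state * peak + rnorm(n_frames, 0, sigma))
  })
}
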