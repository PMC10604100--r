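# synthetic-data generators: determinism, concentration conservation,
# photon statistics, ground-truth bookkeeping

test_that("optics profile generator is deterministic and stitches the decay", {
  g <- geom_small  # d = 100: well below cutoff at 488
  p1 <- make_optics_profiles(g, alexa)
  p2 <- make_optics_profiles(g, alexa)
  expect_identical(p1$excitation$intensity, p2$excitation$intensity)
  expect_identical(p1$emission$p_r, p2$emission$p_r)
  # inside the aperture the intensity decays with the closed-form Lambda
  lam <- evanescent_decay_length(100, 488, 1.335)
  z <- p1$excitation$z
  inside <- z < 0 & z >= -100
  i0 <- p1$excitation$intensity[z == 0]
  expect_equal(p1$excitation$intensity[inside],
               i0 * exp(z[inside] / lam), tolerance = 1e-9)
  # beyond the metal, detection is the aperture-attenuated half-space:
  # p_ff_down = 0.5 exp(-t_m / Lambda_em) in the bulk, excitation constant
  lam_em <- evanescent_decay_length(100, 520, 1.335)
  bulk <- z < -100
  expect_equal(unique(p1$emission$p_ff_down[bulk]), 0.5 * exp(-100 / lam_em),
               tolerance = 1e-9)
  expect_equal(length(unique(p1$excitation$intensity[bulk])), 1L)
  # propagating aperture refuses silent stitching
  expect_error(make_optics_profiles(nanowell_geometry(280, 100, 100), alexa),
               "cutoff")
  expect_s3_class(make_optics_profiles(nanowell_geometry(280, 100, 100), alexa,
                                       propagating = "transmit")$excitation,
                  "excitation_profile")
})

test_that("diffusion keeps the configured concentration in the well", {
  cfg <- sim_config(seed = 21, duration_s = 0.6, dt_us = 1)
  tr <- suppressWarnings(simulate_photon_trace(geom_std, cfg))
  mw <- attr(tr, "mean_well")
  expected <- cfg$concentration * N_AV * well_volume_l(geom_std)
  # block means give an honest SE for the autocorrelated count series
  blocks <- colMeans(matrix(mw[seq_len(50 * (length(mw) %/% 50))], nrow = 50))
  se <- sd(blocks) / sqrt(length(blocks))
  expect_lt(abs(mean(mw) - expected), 3 * se + 0.02 * expected)
})

test_that("occupancy scales linearly with concentration and empties at zero", {
  base <- sim_config(seed = 5, duration_s = 0.25, dt_us = 1, concentration = 400e-9)
  dbl <- sim_config(seed = 5, duration_s = 0.25, dt_us = 1, concentration = 800e-9)
  t1 <- suppressWarnings(simulate_photon_trace(geom_std, base))
  t2 <- suppressWarnings(simulate_photon_trace(geom_std, dbl))
  expect_equal(mean(attr(t2, "mean_well")) / mean(attr(t1, "mean_well")), 2,
               tolerance = 0.25)
  t0 <- simulate_photon_trace(geom_std, sim_config(seed = 5, concentration = 0,
                                                   duration_s = 0.05))
  expect_equal(sum(t0$counts), 0)
  expect_equal(attr(t0, "n_particles"), 0L)
})

test_that("photon traces are seed-deterministic and Poisson per bin", {
  cfg <- sim_config(seed = 33, duration_s = 0.2, dt_us = 1)
  a <- suppressWarnings(simulate_photon_trace(geom_std, cfg))
  b <- suppressWarnings(simulate_photon_trace(geom_std, cfg))
  expect_identical(a$counts, b$counts)
  # Fano factor ~ 1 for a constant-rate segment: emulate an immobile
  # emitter by a huge reservoir particle count and uniform signal --
  # simpler: the generator's Poisson step itself, via a zero-variance rate
  # trace from trajectories of zero particles is degenerate; instead use
  # emit_photon_trace on a single frozen particle
  g <- geom_std
  cfg2 <- sim_config(seed = 9, duration_s = 0.4, dt_us = 50, bin_ms = 1,
                     brightness_cpms = 40)
  traj <- suppressWarnings(simulate_nanowell_diffusion(g, cfg2, record_every = 1L))
  # freeze the particles: constant rate -> per-bin counts Poisson
  traj$z[] <- 100
  z <- seq(-300, 220, 5)
  ex <- excitation_profile(z, rep(1, length(z)))
  em <- dipole_emission_profile(z, rep(1, length(z)), rep(1, length(z)),
                                rep(0.5, length(z)))
  m <- signal_model(g, alexa, ex, em)
  ptr <- emit_photon_trace(traj, m, cfg2)
  fano <- var(ptr$counts) / mean(ptr$counts)
  expect_gt(mean(ptr$counts), 5)
  expect_equal(fano, 1, tolerance = 0.35)
  # S = 0 everywhere -> all-zero trace
  m0 <- m; m0$profile$s <- rep(0, nrow(m0$profile))
  expect_equal(sum(emit_photon_trace(traj, m0, cfg2)$counts), 0)
})

test_that("TCSPC generator reproduces exponential statistics", {
  # tiny IRF: histogram mean approaches t0 + tau (+ half-bin discretization)
  d <- make_tcspc(2.0, irf_fwhm_ps = 1, n_photons = 2e5, bin_ps = 10,
                  window_ns = 40, t0_ns = 1, seed = 4)
  mu <- sum(d$time_ps * d$counts) / sum(d$counts) / 1000
  expect_equal(mu - 1, 2.0, tolerance = 0.02)
  # two equal photon-fraction components: mixture mean 3 ns
  d2 <- make_tcspc(c(1, 5), c(0.5, 0.5), irf_fwhm_ps = 1, n_photons = 2e5,
                   bin_ps = 10, window_ns = 60, t0_ns = 1, seed = 4)
  mu2 <- sum(d2$time_ps * d2$counts) / sum(d2$counts) / 1000
  expect_equal(mu2 - 1, 3.0, tolerance = 0.06)
  # seed determinism
  expect_identical(make_tcspc(4, n_photons = 1e4, seed = 11)$counts,
                   make_tcspc(4, n_photons = 1e4, seed = 11)$counts)
  expect_warning(make_tcspc(0.04, bin_ps = 25, n_photons = 10), "bin width")
})

test_that("cell-movie ground truth honours its own contracts", {
  lay <- pore_array_layout(6, 6)
  cfg <- sim_config(seed = 2)
  mv <- make_cell_movie(lay, cfg, n_frames = 40, covered_fraction = 1)
  # configured high fraction is an exact bookkeeping statement of the truth
  expect_equal(mv$truth$population %in% c("high", "low"), rep(TRUE, 36))
  # spikes occur on high-population pores only
  expect_true(all(mv$spikes$id %in% mv$truth$id[mv$truth$population == "high"]))
  # no cells -> nothing but background anywhere
  mv0 <- make_cell_movie(lay, cfg, n_frames = 10, covered_fraction = 0)
  expect_true(all(!mv0$truth$covered))
  expect_equal(nrow(mv0$spikes), 0)
  # determinism
  mv2 <- make_cell_movie(lay, cfg, n_frames = 40, covered_fraction = 1)
  expect_identical(mv$bfp[[7]], mv2$bfp[[7]])
  expect_identical(mv$truth, mv2$truth)
  # overlapping pores are a layout error
  expect_error(pore_array_layout(4, 4, pitch_px = 3), "pitch")
})
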