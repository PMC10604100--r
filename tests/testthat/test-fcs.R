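# autocorrelation and FCS model fitting

test_that("multi-tau equals the direct estimator at every level", {
  withr::with_seed(8, {
    x <- rpois(30000, 4 + 2 * sin(seq_len(30000) / 150))
  })
  tr <- photon_trace(x, 1)
  ac <- autocorrelate(tr, m = 16)
  # level 0: native binning, lags 1..31
  expect_equal(ac$g[1:31], autocorrelate_direct(x, 1:31), tolerance = 1e-12)
  # level 1 and 2: compare against direct correlation of the binned trace
  bin2 <- function(v) (v[seq(1, length(v) - 1, 2)] + v[seq(2, length(v), 2)]) / 2
  x1 <- bin2(x)
  i1 <- match(seq(32, 62, 2), ac$lag_ms)
  expect_equal(ac$g[i1], autocorrelate_direct(x1, 16:31), tolerance = 1e-12)
  x2 <- bin2(x1)
  i2 <- match(seq(64, 124, 4), ac$lag_ms)
  expect_equal(ac$g[i2], autocorrelate_direct(x2, 16:31), tolerance = 1e-12)
})

test_that("correlation normalization handles edge cases", {
  expect_error(autocorrelate(photon_trace(rep(0, 100), 1)), "zero-mean")
  # constant noiseless trace correlates to exactly zero
  g <- autocorrelate(photon_trace(rep(7, 4000), 1))
  expect_equal(max(abs(g$g)), 0)
})

test_that("the 3D-diffusion fit is exact on noiseless model curves", {
  lags <- exp(seq(log(0.01), log(50), length.out = 60))
  curve <- structure(list(lag_ms = lags, g = fcs_model(lags, N = 5, t_D_ms = 1),
                          m = 16, bin_ms = 0.01),
                     class = "correlation_curve")
  fit <- fit_fcs(curve, weights = "uniform")
  expect_equal(fit$N, 5, tolerance = 1e-6)
  expect_equal(fit$t_D_ms, 1, tolerance = 1e-6)
  # amplitude identity G(0) = 1/N
  expect_equal(fcs_model(0, 5, 1), 1 / 5)
  expect_error(fit_fcs(structure(list(lag_ms = 1:20, g = rep(-0.1, 20),
                                      m = 16, bin_ms = 1),
                                 class = "correlation_curve")),
               "non-decaying|negative")
})

test_that("brightness and effective volume follow their definitions", {
  tr <- photon_trace(rep(50, 1000), 1)  # <I> = 50 counts/ms
  fit <- structure(list(N = 5, t_D_ms = 1, p = 3.4), class = "fcs_fit")
  bv <- brightness_volume(fit, tr, 500e-9)
  expect_equal(bv$epsilon_cpms, 10)
  fit2 <- structure(list(N = 3.011, t_D_ms = 1, p = 3.4), class = "fcs_fit")
  bv2 <- brightness_volume(fit2, tr, 500e-9)
  expect_equal(bv2$v_fcs_l, 3.011 / (N_AV * 500e-9))
  expect_equal(bv2$v_fcs_l, 1.0e-17, tolerance = 1e-4)
  # V_FCS linear in N
  expect_equal(brightness_volume(fit, tr, 500e-9)$v_fcs_l /
                 brightness_volume(fit2, tr, 500e-9)$v_fcs_l, 5 / 3.011)
  expect_error(brightness_volume(fit, tr, 0), "concentration")
  expect_equal(enhancement_factor(5, 1), 5)
  expect_equal(enhancement_factor(2, 2), 1)
  expect_error(enhancement_factor(1, 0), "> 0")
})

test_that("scaling analysis recovers cylinder geometry exactly", {
  grid <- expand.grid(d_nm = c(100, 150, 200, 280), h_nm = c(50, 100, 200))
  grid$N <- 3.011e17 * pi * (grid$d_nm / 2)^2 * (grid$h_nm + 100) * 1e-24
  res <- scaling_analysis(grid)
  expect_equal(res$by_depth$d_exponent, rep(2, 3), tolerance = 1e-10)
  # N affine in h with intercept proportional to the aperture volume
  expect_equal(res$by_diameter$h_intercept,
               3.011e17 * pi * (res$by_diameter$d_nm / 2)^2 * 100 * 1e-24,
               tolerance = 1e-10)
  expect_true(all(res$by_diameter$h_slope > 0))
  expect_error(scaling_analysis(data.frame(d_nm = 1:2, h_nm = 1:2, N = 1:2)),
               "degenerate")
})

test_that("fitting a simulated open cylinder recovers particle number and volume", {
  g <- nanowell_geometry(300, 100, 300)
  cfg <- sim_config(seed = 41, concentration = 2e-6, duration_s = 0.8,
                    dt_us = 1, bin_ms = 0.005, brightness_cpms = 120,
                    reservoir_depth_nm = 300, reservoir_side_nm = 600)
  tr <- suppressWarnings(simulate_photon_trace(g, cfg))   # uniform unit S in cylinder
  fit <- fit_fcs(autocorrelate(tr, max_lag_ms = 2))
  # particle number within ~10% of the cylinder-average occupancy
  cyl_n <- cfg$concentration * N_AV * pi * 150^2 * 400 * 1e-24
  expect_equal(fit$N, cyl_n, tolerance = 0.12)
  bv <- brightness_volume(fit, tr, cfg$concentration)
  v_cyl <- pi * 150^2 * 400 * 1e-24
  expect_equal(bv$v_fcs_l, v_cyl, tolerance = 0.15)
})
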