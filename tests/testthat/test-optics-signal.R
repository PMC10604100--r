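# quantum yield / lifetime / detection efficiency / signal / enhancement

test_that("quantum yield obeys the free-space identity for any Phi0", {
  for (phi0 in c(0.1, 0.25, 0.53, 0.8, 1)) {
    fl <- fluorophore("x", phi0, 4)
    expect_equal(quantum_yield_zmw(1, 0, fl), phi0)
  }
})

test_that("quantum yield follows the modified-rate formula and its limits", {
  expect_equal(quantum_yield_zmw(1, 3, alexa), 1 / 4.25)
  expect_lt(quantum_yield_zmw(1, 1e9, alexa), 1e-8)  # total quenching
  # strictly decreasing in the loss rate at fixed radiative rate
  loss <- seq(0, 5, by = 0.5)
  phi <- quantum_yield_zmw(1, loss, alexa)
  expect_true(all(diff(phi) < 0))
  expect_true(all(phi >= 0 & phi <= 1))
  expect_error(quantum_yield_zmw(-1, 0, alexa), ">= 0")
})

test_that("lifetime relation recovers the free-dye value and scales with Phi", {
  expect_equal(lifetime_from_rates(0.8, 1, alexa), 4.0)
  expect_equal(lifetime_from_rates(0.4, 1, alexa), 2.0)  # Phi halved
  expect_equal(lifetime_from_rates(quantum_yield_zmw(1, 3, alexa), 1, alexa),
               (1 / 4.25) * 4.0 / 0.8)
  expect_equal(lifetime_from_rates(0.53, 1, jfx), 3.9)
  expect_error(lifetime_from_rates(0.5, 0, alexa), "> 0")
})

test_that("detection efficiency is the downward far-field fraction", {
  expect_equal(detection_efficiency(0.5, 1), 0.5)   # free space
  expect_equal(detection_efficiency(1, 1), 1)       # opaque mirror above
  # decreasing as upward leakage increases
  up <- seq(0, 0.8, 0.2)
  expect_true(all(diff(detection_efficiency(1 - up, 1)) < 0))
  expect_error(detection_efficiency(0.5, 0), "> 0")
  expect_error(detection_efficiency(1.5, 1), "<=")
})

test_that("detected signal is the pointwise triple product", {
  expect_equal(detected_signal(c(1, 2), c(0.5, 0.5), c(0.8, 0.4)),
               c(0.4, 0.4))
  expect_equal(detected_signal(0, 1, 1), 0)
  expect_equal(detected_signal(1, 0.5, 0.8), 0.5 * 0.8)
  expect_error(detected_signal(1:3, 1:2, 1:3), "mismatch")
})

test_that("enhancement is 1 for the free-space reference everywhere", {
  z <- seq(-150, 200, by = 5)
  ex <- excitation_profile(z, rep(1, length(z)))
  em <- dipole_emission_profile(z, rep(1, length(z)), rep(1, length(z)),
                                rep(0.5, length(z)))
  m <- signal_model(nanowell_geometry(200, 100, 150), alexa, ex, em)
  expect_equal(m$profile$zeta, rep(1, length(z)), tolerance = 1e-12)
  expect_equal(average_enhancement(m), 1, tolerance = 1e-12)
  expect_equal(signal_averaged_lifetime(m), 4.0, tolerance = 1e-12)
})

test_that("signal-weighted averages agree with hand-computed quadrature", {
  # constant zeta = c gives zeta_bar = c for any positive signal
  expect_equal({
    s <- c(1, 5, 2); z <- c(0, 10, 20)
    trapz_ref(z, 3 * s) / trapz_ref(z, s)
  }, 3)
  # two-point profile zeta = (1, 3), S = (1, 1) -> weighted mean 2
  z2 <- c(0, 10)
  ex2 <- excitation_profile(z2, c(1, 3))      # zeta tracks I_ex here
  em2 <- dipole_emission_profile(z2, c(1, 1), c(1, 1), c(0.5, 0.5))
  m2 <- signal_model(nanowell_geometry(200, 100, 10), alexa, ex2, em2)
  expect_equal(m2$profile$zeta, c(1, 3))
  # zeta-weighting by S = (1,3): integral(zeta*S)/integral(S) = (1*1+3*3)/(1+3) wrong
  # on the trapezoid: ((1*1+3*3)/2) / ((1+3)/2) = 2.5; with S = zeta here.
  expect_equal(average_enhancement(m2),
               trapz_ref(z2, c(1, 3) * c(1, 3) * 0.5 * 0.8) /
                 trapz_ref(z2, c(1, 3) * 0.5 * 0.8))
  # lifetime average with equal weights: tau = (2, 4) -> 3
  expect_equal(trapz_ref(z2, c(2, 4) * c(1, 1)) / trapz_ref(z2, c(1, 1)), 3)
  m3 <- signal_model(nanowell_geometry(200, 100, 10), alexa,
                     excitation_profile(z2, c(1, 1)), em2)
  expect_equal(signal_averaged_lifetime(m3), 4.0)
  # weighted mean is bounded by the extremes
  p <- m2$profile
  expect_gte(signal_averaged_lifetime(m2), min(p$tau_ns))
  expect_lte(signal_averaged_lifetime(m2), max(p$tau_ns))
})

test_that("averaging window spans well bottom to 200 nm beyond the film", {
  z <- seq(-400, 300, by = 10)
  n <- length(z)
  ex <- excitation_profile(z, rep(1, n))
  em <- dipole_emission_profile(z, rep(1, n), rep(1, n), rep(0.5, n))
  g <- nanowell_geometry(200, 100, 150)
  m <- signal_model(g, alexa, ex, em)
  # zeta = 1 everywhere, but make S nonuniform outside the window: the
  # average must ignore z < -200 and z > h
  m$profile$zeta[m$profile$z < -200 | m$profile$z > 150] <- 99
  expect_equal(average_enhancement(m), 1, tolerance = 1e-12)
})
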