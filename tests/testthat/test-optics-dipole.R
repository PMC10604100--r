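# dipole-above-mirror emission model

pec_perp <- function(x) 1 - 3 * (cos(x) / x^2 - sin(x) / x^3)
pec_par <- function(x) 1 - 1.5 * (sin(x) / x + cos(x) / x^2 - sin(x) / x^3)

test_that("perfect-mirror quadrature reproduces the closed forms at all z", {
  zs <- c(2, 10, 50, 150, 400, 1500)
  k <- 2 * pi * 1.335 / 520
  pp <- mirror_dipole_profile(zs, 520, "perfect", "perpendicular")
  pl <- mirror_dipole_profile(zs, 520, "perfect", "parallel")
  expect_equal(pp$p_r, pec_perp(2 * k * zs), tolerance = 1e-9)
  expect_equal(pl$p_r, pec_par(2 * k * zs), tolerance = 1e-9)
  # lossless mirror: all power reaches the far field
  expect_equal(pp$p_ff, pp$p_r, tolerance = 1e-9)
  expect_equal(pl$p_ff, pl$p_r, tolerance = 1e-9)
})

test_that("contact and free-space limits hold", {
  # perpendicular -> 2, parallel -> 0 at contact (within 1% by small z)
  expect_equal(mirror_dipole_profile(0.05, 520, "perfect", "perpendicular")$p_r,
               2, tolerance = 0.01)
  expect_lt(mirror_dipole_profile(0.05, 520, "perfect", "parallel")$p_r, 0.01)
  # free space recovered within 1% beyond 5 wavelengths
  iso <- mirror_dipole_profile(c(2600, 5200), 520, "perfect", "isotropic")
  expect_equal(iso$p_r, c(1, 1), tolerance = 0.01)
  expect_error(mirror_dipole_profile(-5, 520), "z > 0")
})

test_that("isotropic averaging weights parallel and perpendicular 2:1", {
  zs <- c(30, 120)
  pa <- mirror_dipole_profile(zs, 520, "pd", "parallel")
  pe <- mirror_dipole_profile(zs, 520, "pd", "perpendicular")
  iso <- mirror_dipole_profile(zs, 520, "pd", "isotropic")
  expect_equal(iso$p_r, (2 * pa$p_r + pe$p_r) / 3, tolerance = 1e-12)
  expect_equal(iso$p_ff, (2 * pa$p_ff + pe$p_ff) / 3, tolerance = 1e-6)
})

test_that("a lossy metal absorbs: quenching grows toward contact", {
  pd <- mirror_dipole_profile(c(2, 10, 50, 200), 520, "pd", "isotropic")
  loss <- pd$p_r - pd$p_ff
  expect_true(all(loss >= 0))
  expect_true(all(diff(loss) < 0))  # strongest loss nearest the metal
  expect_gt(pd$p_r[1], 100)        # near-field quenching dominates at 2 nm
})

test_that("relative rates decompose into far-field and absorbed channels", {
  prof <- dipole_emission_profile(c(10, 20), p_r = c(1, 2), p_ff = c(1, 1),
                                  p_ff_down = c(0.5, 1))
  rr <- relative_rates(prof)
  expect_equal(rr$gamma_r_rel, c(1, 1))
  expect_equal(rr$gamma_loss_rel, c(0, 1))
  # free space: (1, 0)
  fs <- relative_rates(dipole_emission_profile(1, 1, 1, 0.5))
  expect_equal(c(fs$gamma_r_rel, fs$gamma_loss_rel), c(1, 0))
  # invariants rejected at construction
  expect_error(dipole_emission_profile(1, p_r = 1, p_ff = 2), "P_ff <= P_r")
  expect_error(dipole_emission_profile(1, p_r = 1, p_ff = 0.5, p_ff_down = 0.8),
               "P_ff_down")
})
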