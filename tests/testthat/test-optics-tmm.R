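# transfer-matrix standing-wave model

test_that("a perfect reflector gives a node at the surface and a 4-fold peak", {
  mirror <- layer_stack(c(1.335, complex(real = 0.01, imaginary = 1e4), 1.335),
                        c(Inf, 100, Inf))
  p <- standing_wave_profile(488, stack = mirror, z = seq(0, 200, by = 0.25))
  expect_lt(p$intensity[1], 1e-4)
  expect_equal(max(p$intensity), 4, tolerance = 1e-4)
  # first maximum at lambda / (4 n)
  expect_equal(p$z[which.max(p$intensity)], 488 / 4 / 1.335, tolerance = 0.01)
})

test_that("an empty stack leaves the field uniform", {
  p <- standing_wave_profile(488, stack = layer_stack(c(1, 1), c(Inf, Inf)),
                             z = seq(-50, 150, 10))
  expect_equal(p$intensity, rep(1, length(p$intensity)))
})

test_that("energy is conserved (R + T + A_flux = 1) across stacks and angles", {
  npd <- pd_refractive_index(488)
  stacks <- list(
    layer_stack(c(1.335, npd, 1.52), c(Inf, 15, Inf)),
    layer_stack(c(1.52, npd, 1.335), c(Inf, 40, Inf)),
    layer_stack(c(1.335, npd, 1.8 + 0.3i, 1.52), c(Inf, 10, 30, Inf)),
    layer_stack(c(1.0, 1.5, 1.0), c(Inf, 120, Inf)))
  for (st in stacks) {
    for (ang in c(0, 25, 55, 70)) {
      e <- tmm_energy(st, 488, ang, "s")
      expect_lt(abs(1 - e$R - e$T - e$A_flux), 1e-10)
    }
  }
})

test_that("oblique incidence stretches the standing-wave period (TIRF shift)", {
  npd <- pd_refractive_index(488)
  st <- layer_stack(c(1.335, npd, 1.335), c(Inf, 100, Inf))
  z <- seq(0, 250, by = 0.5)
  p0 <- standing_wave_profile(488, 0, st, z)
  p40 <- standing_wave_profile(488, 40, st, z)
  first_max <- function(p) p$z[which.max(p$intensity[p$z < 200])]
  expect_gt(first_max(p40), first_max(p0))
})

test_that("the Pd film peak is a few-fold and stored constants interpolate", {
  p <- standing_wave_profile(488)
  expect_gt(max(p$intensity), 2.5)
  expect_lt(max(p$intensity), 4)
  n1 <- pd_refractive_index(488)
  expect_gt(Im(n1), 2)  # strongly absorbing metal
  expect_error(pd_refractive_index(10), "range")
  # user-supplied table overrides the bundled one
  tab <- data.frame(wavelength_nm = c(400, 600), n = c(2, 2), k = c(3, 3))
  expect_equal(pd_refractive_index(488, tab), complex(real = 2, imaginary = 3))
})

test_that("nonphysical stacks are rejected", {
  expect_error(layer_stack(c(-1, 1), c(Inf, Inf)), "nonphysical")
  expect_error(layer_stack(c(1, 1), c(1, Inf)), "semi-infinite")
  expect_error(layer_stack(c(1.335 + 0.1i, 1), c(Inf, Inf)), "lossless")
  expect_error(excitation_profile(c(1, 1, 2), c(1, 1, 1)), "increasing")
  expect_error(excitation_profile(c(1, 2), c(-1, 1)), ">= 0")
})
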