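# nanowell

Optical modeling and single-molecule analysis for overmilled palladium
zero-mode-waveguide (ZMW) nanowells.

ZMWs are subwavelength apertures in a metal film: light with wavelength
above the cutoff `lambda_c = 1.7 d` cannot propagate through an aperture
of diameter `d`, so only an evanescent tail (decay length
`Lambda = [4 pi sqrt(1/lambda_c^2 - 1/lambda_m^2)]^-1`) excites
fluorophores inside. Overmilling the glass beneath the aperture creates an
attoliter nanowell that cell membrane protrusions can enter, enabling
single-molecule imaging of membrane proteins even with a high
concentration of the same fluorophore in the cytoplasm: the film blocks
the cell-body background while a standing wave below the metal focuses the
excitation into the well.

The package is written for experimentalists and modelers working with such
structures. It provides, as one tested chain:

* **Optics** — the ZMW cutoff/evanescent calculus; a transfer-matrix
  standing-wave model of excitation below the film (with tabulated Pd
  optical constants); a semi-analytic dipole-above-mirror emission model
  giving the modified quantum yield
  `Phi = g_r / (g_r + g_loss + (1-Phi0)/Phi0)` (rates normalized to the
  free-space radiative rate), lifetime `tau = Phi/gamma_r`, detection
  efficiency `eta`, detected signal `S(z) = I_ex eta Phi` and the
  signal-weighted enhancement `zeta_bar`.
* **FCS** — a multi-tau correlator (compiled, verified against a direct
  estimator to 1e-10) and the standard 3D-diffusion fit
  `G(t) = (1/N)(1 + t/tD)^-1 (1 + t/(p^2 tD))^-1/2` with `p = 3.4` fixed,
  yielding particle number `N`, diffusion time `tD`, molecular brightness
  `epsilon = <I>/N` and effective volume `V_FCS = N/(N_A c)`.
* **TCSPC** — Poisson-likelihood reconvolution fitting of mono- and
  bi-exponential decays with the IRF shift as a nuisance parameter.
* **Cell imaging** — pore localization on bright-field images, 7x7-window
  traces with edge-ring background subtraction, bimodal high/low
  classification against a no-cell control, occupancy-by-size statistics,
  wide-field vs TIRF comparison.
* **Trace HMM** — two-state Gaussian EM/Viterbi decoding with peak
  intensity, background sigma and SNR.
* **Synthetic data** — generators for every input: axial optics profiles,
  grand-canonical Brownian-dynamics photon traces in the well + reservoir
  geometry, TCSPC histograms, and EMCCD pore-array movies with ground
  truth.

## Worked example

Predict the optical response of a 200 nm pore overmilled 100 nm into the
glass, for Alexa488:

```r
library(nanowell)
g  <- nanowell_geometry(diameter = 200, metal_thickness = 100,
                        overmill_depth = 100)
fl <- fluorophore_preset("Alexa488")       # Phi0 = 0.8, tau0 = 4.0 ns
prof  <- make_optics_profiles(g, fl)       # standing wave + mirror dipole
model <- signal_model(g, fl, prof$excitation, prof$emission)
model
#> signal model: Alexa488 in d = 200 nm / h = 100 nm nanowell; 221 z-points
#>   signal-weighted <zeta> = 2.661, <tau> = 3.026 ns
```

The predicted per-molecule signal enhancement is 2.7-fold relative to free
diffusion (driven by the ~3-fold standing-wave excitation peak and the
2-fold detection-efficiency gain, partly offset by metal losses), and the
signal-averaged lifetime drops from 4.0 to 3.0 ns — both in the ranges
observed experimentally for wells of this size.

Simulate dye diffusion in the well and recover the particle number by FCS:

```r
cfg <- sim_config(seed = 42, concentration = 2e-6, duration_s = 0.8,
                  dt_us = 1, bin_ms = 0.005, brightness_cpms = 120)
tr  <- simulate_photon_trace(nanowell_geometry(300, 100, 300), cfg)
fit <- fit_fcs(autocorrelate(tr, max_lag_ms = 2))
fit
#> FCS fit (p = 3.4): N = 35.48 +/- ..., t_D = 0.17 +/- ... ms
brightness_volume(fit, tr, 2e-6)$v_fcs_l   # ~2.9e-17 L vs 2.83e-17 geometric
```

`N` matches the `c * N_A * V` expectation for the 300 nm x 400 nm cylinder
(34.1) within a few percent.

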