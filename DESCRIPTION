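Package: nanowell
Title: Optical Modeling and Single-Molecule Analysis for Overmilled
    Zero-Mode Waveguide Nanowells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models metal-modified fluorescence in overmilled palladium
    zero-mode-waveguide (ZMW) nanowells and analyses the single-molecule
    data acquired in them. Provides the ZMW cutoff/evanescent-decay
    calculus, a one-dimensional transfer-matrix model of standing-wave
    excitation below a metal film, a semi-analytic dipole-above-mirror
    emission model yielding quantum yield, lifetime, detection efficiency
    and signal-enhancement profiles, multi-tau fluorescence correlation
    spectroscopy with 3D-diffusion model fitting (particle number,
    diffusion time, molecular brightness, effective volume), TCSPC
    reconvolution lifetime fitting with Poisson likelihood, pore-array
    image analysis (pore localization, background-subtracted trace
    extraction, bimodal high/low classification, occupancy statistics),
    and two-state hidden Markov analysis of single-molecule traces
    (peak intensity, background noise, signal-to-noise ratio).
    Synthetic-data generators (Brownian-dynamics photon traces, decay
    histograms, EMCCD pore-array movies) emulate the corresponding
    experiments for validation and pipeline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    graphics,
    minpack.lm,
    mclust,
    jsonlite,
    yaml,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
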