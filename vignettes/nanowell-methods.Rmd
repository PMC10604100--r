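---
title: "Models and methods behind nanowell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nanowell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanowell)
```

# The system

A zero-mode waveguide (ZMW) is a subwavelength hole in a metal film on a
glass coverslip. Visible light cannot propagate through an aperture whose
cutoff wavelength $\lambda_c = 1.7\,d$ lies below the illumination
wavelength in the medium; inside the hole only an evanescent tail of the
excitation survives, decaying with
$\Lambda = \left[4\pi\sqrt{1/\lambda_c^2 - 1/\lambda_m^2}\right]^{-1}$.
*Overmilled* ZMWs extend the aperture by a nanowell milled into the glass
beneath the film (depths up to a few hundred nanometers), creating an
attoliter observation volume that live-cell membrane protrusions can
enter, while the metal blocks fluorescence from the cell body above.

This package implements the computational chain for such experiments:
the metal-modified photophysics along the pore axis, FCS analysis of
diffusing dyes in the wells, TCSPC lifetime fitting, pore-array image
analysis, and a two-state HMM for single-molecule traces — together with
synthetic-data generators that replace the microscope and the full-wave
field solver with semi-analytic physics at desk scale.

**Axial convention.** Everywhere in the package, $z = 0$ is the lower
(glass-side) metal surface, $z > 0$ points into the nanowell toward the
objective, the metal occupies $[-t_m, 0]$, and the bulk medium (cell body
or solution reservoir) lies at $z < -t_m$.

# Metal-modified fluorescence

An emitter near metal has its radiative rate modified and acquires a
nonradiative loss channel. With rates normalized to the free-space
radiative rate $\gamma_r^0 = \Phi_0/\tau_0$:

$$\Phi = \frac{\gamma_r/\gamma_r^0}
{\gamma_r/\gamma_r^0 + \gamma_\mathrm{loss}/\gamma_r^0 + (1-\Phi_0)/\Phi_0},
\qquad \tau = \frac{\Phi}{\gamma_r}.$$

The rate ratios come from classical electrodynamics of a dipole below a
planar reflector: the total dissipated power $P_r/P_r^0$ from the
angular-spectrum (Sommerfeld) integral over propagating and evanescent
waves, and the far-field power $P_\mathrm{ff}/P_r^0$ from quadrature of the
direct-plus-image interference pattern over the detection hemisphere. We
identify $\gamma_r/\gamma_r^0 = P_\mathrm{ff}/P_r^0$ (photons that escape)
and $\gamma_\mathrm{loss}/\gamma_r^0 = (P_r - P_\mathrm{ff})/P_r^0$
(power absorbed by the metal). This decomposition satisfies the free-space
identity $(1, 0) \Rightarrow \Phi = \Phi_0$ exactly and keeps
$\Phi \le 1$; note that identifying $\gamma_r$ with the *total* dissipated
power instead would count absorbed power twice. Because the reflector is
opaque, all far-field power exits through the detection half-space, so the
detection efficiency $\eta = P_\mathrm{ff}^{z-}/P_\mathrm{ff}$ is 1 under
the mirror and $\eta_0 = 1/2$ in free space — the origin of the 2-fold
detection-efficiency gain.

The model is one-dimensional on the pore axis: lateral variation of the
emission rates inside the pore is neglected (in full-wave simulations it
is weak), and the finite aperture is represented only through the
evanescent attenuation below cutoff. Perfect-mirror closed forms
($P_\perp/P^0 = 1 - 3(\cos x/x^2 - \sin x/x^3)$ with $x = 2kz$, and the
parallel analogue) serve as internal oracles: the numerical quadratures
reproduce them to $10^{-9}$, the contact limits (2 and 0) and the
free-space limit to 1%.

Excitation uses a standard transfer-matrix (Airy recursion) solution for
the layer stack, with the standing wave formed between the incident and
metal-reflected waves on the detection side. For the bundled palladium
optical constants the peak is $\approx 3.1 I_0$ at 488 nm in water — an
ideal laterally infinite mirror slightly exceeds the $\approx 3$-fold
maximum a full-wave solver finds inside the finite aperture geometry.
Energy conservation ($R + T + A = 1$, absorption computed independently
from Poynting-flux differences) holds to $10^{-10}$.

**Palladium optical constants.** The bundled table
(`inst/extdata/pd_nk.csv`) is generated from a five-oscillator
Drude–Lorentz parametrization of published Pd ellipsometry and
interpolated log-linearly in wavelength; it is a configuration item
(`pd_refractive_index(..., table = )`) because tabulations in the
literature differ by a few percent, which propagates to a few percent in
reflectivity-derived quantities.

**Detected signal and enhancement.** $S(z) = I_\mathrm{ex}(z)\,\eta(z)\,
\Phi(z)$; the enhancement $\zeta(z) = S(z)/(I_{\mathrm{ex},0}\,\eta_0\,
\Phi_0)$ references free diffusion with $\eta_0 = 0.5$. Signal-weighted
averages (of $\zeta$ and of $\tau$) integrate from the bottom of the well
($z = h$) through the aperture to 200 nm beyond the reference plane by
trapezoidal quadrature on the native grid; $S(z)$ is negligible beyond
the metal, so the far endpoint is uncritical. The signal-averaged
lifetime uses the same $S$-weighting as the enhancement average, which is
what "signal-averaged" means operationally: each axial position
contributes in proportion to the photons detected from it.

```{r optics-example}
g <- nanowell_geometry(diameter = 200, metal_thickness = 100,
                       overmill_depth = 100)
fl <- fluorophore_preset("Alexa488")
prof <- make_optics_profiles(g, fl)
model <- signal_model(g, fl, prof$excitation, prof$emission)
c(zeta_bar = average_enhancement(model),
  tau_avg_ns = signal_averaged_lifetime(model))
```

These land in the experimentally reported ranges (enhancement 2–5,
lifetimes reduced from the 4.0 ns free-dye value).

# Brownian photon simulation

`simulate_photon_trace()` performs Brownian dynamics in the aperture +
well cylinder coupled to a bulk reservoir slab; the aperture is the only
exchange path. Proposals are Gaussian; flat boundaries fold the proposal
(exact reflection), and moves ending inside metal or glass are rejected
in place. Because the proposal is symmetric, this is Metropolis sampling
of a uniform density — the equilibrium concentration is exact at any step
size, at the cost of slightly sticky dynamics within one step length of
the curved wall. The far reservoir boundary is grand-canonical: particles
crossing it leave to an implicit infinite bath, and new particles enter
as a Poisson flux $\rho L^2 \sigma/\sqrt{2\pi}$ per step with the exact
diffusive overshoot distribution. The particle number in any subvolume is
then Poisson with mean $c N_A V$, which is what the FCS amplitude
measures. (The trajectory-recording variant
`simulate_nanowell_diffusion()` uses a closed reflecting box: its mean
occupancy is identical but number fluctuations are mildly sub-Poisson,
fine for occupancy statistics.)

Default conditions mirror the free-dye experiments: 500 nM dye,
$D = 400\ \mu\mathrm{m}^2/\mathrm{s}$ (a small organic dye in water),
1 ms binning for trace display and 5–10 µs binning for correlation
work; photon emission is Poisson with rate proportional to
$\sum_i S(z_i)$, with the lateral profile taken uniform, consistent with
the 1-D optics. The generator does not model triplet blinking,
photobleaching (not significant in the underlying experiments), dye-metal
sticking, or anisotropic diffusion near walls — so passing parameter
recovery here validates the estimator chain, not those real-data effects.

# FCS analysis

The multi-tau correlator (16 channels per octave, symmetric
normalization, binning by two per octave) is implemented in compiled code
and is exactly equal — to $10^{-10}$ — to a direct $O(TL)$ correlation of
the equally binned trace, which the test suite verifies against an
independent R implementation. Curves are fitted to the standard
3D-diffusion model

$$G(t_c) = \frac{1}{N}\left(1 + \frac{t_c}{t_D}\right)^{-1}
\left(1 + \frac{t_c}{p^2 t_D}\right)^{-1/2}, \qquad p = 3.4
\text{ (fixed)},$$

by Levenberg–Marquardt least squares, weighted by per-lag standard errors
from eight trace segments when the trace is long enough. For confined
geometries this is an effective-parameter description — the amplitude
$1/N$ and decay time are meaningful, the geometric shape is not — and the
amplitude is always read from the fitted model, never from the
shot-noise-dominated zero-lag bin. On simulated open cylinders, fitted
$N$ carries a few-percent systematic from the sharp-edged volume (the
correlation decays like $1 - c\sqrt{t}$ at short lags, which the model
cannot follow); at 5 µs binning the net bias is below 5%, within the
10% recovery target. Brightness and effective volume follow
$\varepsilon = \langle I\rangle/N$ and $V_\mathrm{FCS} = N/(N_A c)$.

# TCSPC lifetime fitting

`make_tcspc()` draws photon delays as exponential waiting times plus
Gaussian IRF jitter and histograms them (25 ps bins by default);
component weights are photon-count fractions. `fit_reconvolution()`
maximizes the Poisson likelihood of $A\,(\mathrm{IRF} \ast \sum_i a_i
e^{-t/\tau_i}) + bg$ with the IRF shift as a nuisance parameter, on the
histogram grid by discrete convolution. Poisson MLE (not least squares)
keeps low-count bins honest; the reported reduced $\chi^2$ uses bins with
expectation at least 5. For two-component fits both the
amplitude-weighted mean $\sum a_i\tau_i$ and the intensity-weighted mean
$\sum a_i\tau_i^2/\sum a_i\tau_i$ are reported, because the literature
uses either as "the average": note that a generator using equal *photon*
fractions for (1, 5) ns yields decay amplitudes (0.83, 0.17), so the
photon-weighted mixture moment 3.0 ns is recovered by the
intensity-weighted mean. Recovery bias is below 2% across 0.5–5 ns at
$10^5$–$10^6$ photons with a 200 ps FWHM IRF.

# Pore-array image analysis

The synthetic movie generator emulates the live-cell data: a bright-field
frame with pores as dark spots, a cytoplasm-marker channel in which
covered pores are bimodal — a high population (membrane protruding into
the well) and a low population at 8% of the high mean (cell merely
covering the pore) — with a configurable fraction switching between the
levels as a two-state telegraph, and a single-molecule channel with
exponential-dwell spikes on high pores only. EMCCD readout is gain-scaled
Poisson plus Gaussian read noise; the full electron-multiplication gamma
cascade is deliberately omitted (it changes the excess noise factor, not
the structure the pipeline tests).

Analysis follows the standard recipe: pores are localized on the
inverted, smoothed bright-field image by local-maximum detection, a
global translation is estimated by robust matching against the declared
layout (marker holes included), and centers are refined by local
centroiding (&lt; 0.2 px on synthetic frames). Per-pore traces are the
mean of a 7×7 pixel window minus the mean of its outer one-pixel ring (24
pixels) — "outer edge pixels" interpreted as that ring — which makes
traces exactly invariant to additive offsets. Positive pores are called
against a no-cell control at mean + 3 SD (the stringency `k_sigma` is a
parameter because only the existence of a threshold, not its value, is
standard); high/low separation uses a two-component Gaussian mixture on
per-pore means rather than a fixed percentage cut, so the 8% low/high
ratio is a generator validation input, not an analysis assumption. A pore
is "switching" when a two-state hidden Markov fit beats a single Gaussian
by more than 10 BIC units — a likelihood criterion that rewards temporal
persistence, so plain noise does not trigger it.

# Two-state HMM and SNR

`fit_two_state_hmm()` is maximum-likelihood EM with Gaussian emissions,
quantile-based deterministic initialization, and Viterbi decoding; states
are reported sorted by mean, making results invariant to label
permutation, and degenerate traces fall back to a flagged single state.
The variational-Bayes algorithm used interactively in this field differs
in its priors, but on well-separated traces (SNR ≥ 5) the state
assignments agree; only state assignments, peak = on − off mean,
background σ (SD of off-state frames), and SNR = peak/σ are consumed
downstream. SNR is invariant under camera gain and offset by
construction.

# Pipeline and reproducibility

`run_pipeline()` executes the stages (`simulate-optics`, `simulate-fcs`,
`fit-fcs`, `simulate-lifetime`, `fit-lifetime`, `simulate-cells`,
`analyze-cells`, `hmm`, `report`) against a validated YAML configuration
(unknown keys are errors) and writes a manifest with the config snapshot,
seed, package version, applied thresholds and MD5 hashes of every output.
All randomness flows from the configured seed; identical configuration
reproduces identical files. A thin command-line wrapper ships in
`inst/exec/nanowell-pipeline.R`; the R functions are the primary
interface.

# Problem sizes and limitations

The validation suite runs at desk scale by design: Brownian FCS checks
use a 300 nm × 400 nm cylinder at 2 µM for 0.4–0.8 s of simulated time
(about $10^8$ particle-steps per run, 20 seeds for the statistical
properties), movies use 6×6 pore arrays at 40–150 frames, and TCSPC
checks use $10^5$–$10^6$ photons. These sizes give estimator standard
errors comfortably below the tolerances being asserted. What the suite
demonstrates is internal consistency — generators with known truth,
estimators recovering it, and closed-form oracles for the optics. It does
not demonstrate performance on real microscope data, where PSF overlap
between neighbouring pores, drift, uneven illumination, EM-register
noise statistics and dye photophysics all enter; the module boundaries
(profiles, traces, movies in standard formats) are where real data would
be substituted.
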