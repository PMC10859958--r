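---
title: "Models and methods: kinetic and spectral analysis of far-red chlorophyll antenna complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lhcakin)
```

This vignette documents the models behind `lhcakin`, the choices made
where several defensible options existed, and what the synthetic-data
tests do and do not demonstrate about measured data.

## The measurement model

Both time-resolved modalities are described by the same bilinear model:
the surface ψ(t, λ) is a sum over components of a wavelength-dependent
amplitude times a time-dependent population,

ψ(t, λ) = Σᵢ Aᵢ(λ) · cᵢ(t),

where the populations are exponential decays (global analysis, giving
decay-associated spectra DAS/DADS) or compartment populations of a
first-order kinetic scheme (target analysis, giving species-associated
spectra SADS), in either case convolved with the instrument response.

**IRF convolution.** For a Gaussian IRF of width σ (fwhm = 2√(2 ln 2) σ)
centered at t₀, the convolution with a causal exponential of rate k has
the closed form

c(t) = ½ exp(k(t₀ − t) + k²σ²/2) · erfc((t₀ − t + kσ²)/(σ√2)).

Evaluated literally, either factor overflows for t far on one side of
t₀. `conv_exp_gauss()` therefore computes ½·exp(A + log erfc(x)) with
log erfc obtained from the Gaussian tail in log space, which is finite
and accurate on the whole real line, for any rate from fs⁻¹ to ns⁻¹
scales — including k = 0, where the expression degrades gracefully to
the IRF-blurred step. Measured IRFs (the TCSPC case) are convolved
numerically on the surface's uniform channel grid. Times are picoseconds
everywhere internally; that keeps femtosecond TA steps and nanosecond
TCSPC windows within comfortable double range.

**Compartmental schemes.** `concentrations()` solves dc/dt = K c +
IRF(t)·x by eigendecomposition: each eigenmode is an exponential, so its
IRF convolution is analytic. This is exact for diagonalizable K with
real spectrum — which covers the sequential schemes used throughout —
and the function falls back to stiff ODE integration (flagged) for
defective or complex spectra, so arbitrary first-order schemes still
work, just more slowly.

## Global analysis by variable projection

`fit_global()` optimizes only the nonlinear parameters — log lifetimes,
plus the Gaussian IRF position and width when requested — and eliminates
the spectra at every iteration by conditional weighted linear least
squares, one wavelength at a time. Log-lifetimes enforce positivity and
make a fs-to-ns search space roughly isotropic. Weights are 1/√max(N, 1)
for photon-counting data (the Poisson standard deviation) and uniform
for ΔOD; the TA IRF width is bounded to 87–125 fs by default, the
plausible range for this kind of pump-probe setup, and the bound is
configurable. Levenberg–Marquardt runs with an iteration cap of 500 and
relative tolerances of 1e-10; lifetimes are reported ascending, and no
sign convention is imposed on the spectra (TA bleaches are negative).

Two lifetimes approaching within 1% of each other make the exponential
basis numerically rank deficient. A converged fit in that state is
flagged degenerate; during iterations the linear stage simply assigns
redundant columns zero amplitude so the optimizer can move through the
crossing rather than crash on it.

**DAS ↔ EADS.** A parallel fit with lifetimes τᵢ is algebraically
equivalent to a unidirectional sequential scheme with rates 1/τᵢ. With
A the Bateman amplitude matrix of the sequential populations
(cⱼ(t) = Σᵢ Aⱼᵢ e^(−kᵢt)), the two descriptions satisfy DAS = Aᵀ·EADS,
which `das_to_eads()` solves exactly; the inverse is a multiplication.
Equivalence is verified by resimulation in the tests to 1e-9.

**Choosing the component count.** `select_n_components()` refits at each
candidate n and recommends the smallest n beyond which the cost improves
by less than 2% (configurable). Spectra whose lag-1 autocorrelation
falls below 0.3 are flagged "shapeless" — a noise-like spectrum is the
usual symptom of one component too many.

## Two-branch target analysis

Ensembles reconstituted with Chl f contain complexes with and without
the pigment. The model is

ψ = (1 − f) · C_fixed S_fixed + f · C_free S_free,

with the fixed branch's rates and SADS pinned to a prior fit of the
Chl-f-free complex and a free sequential branch of four compartments
whose last compartment is a plain decay — on the ≤ 100 ps window fitted
here the slow decay manifold cannot be resolved further, so one decay
component suffices. Both branches share one IRF.

The fraction f is identifiable only because of a constraint: the
wavelength-integrated area of each branch's first SADS (its time-zero
spectrum) is forced equal. Time-zero TA spectra scale with the number of
excited complexes per population, so equal per-complex areas turn the
amplitude split (1 − f, f) into a population split. The constrained
linear solve is exact: with G = CᵀC, the unconstrained per-wavelength
solution is corrected along G⁻¹e₁ by a Lagrange multiplier chosen in
closed form so the constraint holds to machine precision.

Design choices here:

* **Signed vs absolute area.** Published descriptions of such constraints
  rarely say whether the area is signed. Time-zero TA spectra are
  single-signed (bleach), so the two coincide up to sign; the default
  `area_mode = "absolute"` matches the magnitude of the fixed branch's
  area and takes the sign from the unconstrained free solution, and a
  signed mode is available.
* f is parameterized through a logit, keeping it strictly inside (0, 1);
  convergence beyond |logit f| > 6 raises a boundary warning.
* Free rates are multi-started (3 jittered starts, fixed seed).
* The fixed branch's SADS are the EADS of the prior global fit, using the
  exact DAS→EADS conversion above.

## Spectral unmixing and stoichiometry

Pigment concentrations cannot be negative, so `unmix()` uses
non-negative least squares (active-set NNLS) rather than imposing
positivity after the fact. The default fit window for chlorophyll-only
work is 600–750 nm, where the Qy structure discriminates the pigments;
windows including the Soret/carotenoid region (e.g. 380–750 nm) are
needed when a carotenoid coefficient is wanted — on a red-only window
the carotenoid basis spectrum vanishes and the fit refuses it as rank
deficient rather than silently returning noise. No baseline-offset term
is included by default; extracts are assumed scatter-corrected.

Chlorophyll coefficients are normalized to 12 chlorophylls per complex,
the chlorophyll complement of monomeric Lhca4, with the carotenoid
scaled by the same factor. Ratios are plain quotients, reported at the
conventional precision (one decimal for a/b-type ratios, two for a/d).

The synthetic basis spectra are sums of two or three Gaussians per
pigment with in-acetone Qy maxima (a 663, b 646, d 688, f 707 nm) and
Qy-window areas calibrated so the relative oscillator strengths come out
1.0 : 0.67 : 1.20 : 1.34 for a : b : d : f. The band shapes are fixture
choices, not measured line shapes; only positions, relative areas and
rough widths are physical.

## Gaussian band deconvolution

`fit_gaussians()` fits in the wavenumber domain, where Gaussian line
shapes are conventional for electronic bands; centers and widths convert
back to nm via the first-order dispersion relation Δλ = λ²Δν/10⁷ at the
band center. Widths and areas are optimized in log space with fwhm
bounded to [20, 800] cm⁻¹. Initialization is a greedy peak pick: each
band starts at the running residual maximum with a local half-maximum
width estimate, which reliably seeds small bands far from the main mass;
five jittered restarts (fixed seed) guard against remaining local
minima. Non-convergence is flagged on the result, not thrown, since a
flagged fit is still inspectable.

## The synthetic-data generator

`make_fixture()` encodes the study conditions this package is built
around:

* TCSPC surfaces: five DAS components with lifetimes 12 ps, 0.19, 0.87,
  2.1 and 3.8 ns; the three main decay components carry DAS areas in the
  48:34:18 proportion; Gaussian IRF of 92 ps fwhm; Poisson noise at
  2×10⁴ peak counts. The wavelength grid (670–780 nm in 5 nm steps) and
  the 25 ns / 4096-channel time grid are generator choices sized so that
  a ~6 ps channel width supports the 12 ps component.
* TA surfaces: six DADS (0.525, 2.19, 6.67, 43.4, 671, 2530 ps), the
  first three with the −/+ donor/acceptor structure of energy-transfer
  components; 0.1 ps Gaussian IRF; time grid linear to 1 ps and
  log-spaced to 3.5 ns, mimicking delay-stage practice; Gaussian noise
  at 0.3% of the signal maximum.
* The mixture fixture combines the Chl-f-free sequential scheme (from
  the exact EADS conversion of the TA fixture) with a four-compartment
  Chl-f branch (0.605, 4.17, 18.7, 700 ps; terminal acceptor at 724 nm),
  at a Chl-f fraction defaulting to 0.67, with the two time-zero SADS
  areas equalized so the fraction is well defined.

What these fixtures do **not** emulate: wavelength-dependent time zero
(chirp) in TA, singlet-singlet annihilation, scattering or coherent
artifacts around t = 0, detector afterpulsing in TCSPC, and non-Gaussian
measured line shapes. Passing recovery tests on these fixtures therefore
demonstrates the correctness and conditioning of the estimators under
the stated noise models — not robustness to every artifact of real
surfaces, which need the usual pre-corrections first.

## Steady-state utilities

The 0–0 transition of a species is estimated as the crossing of its
absorption and emission spectra, both normalized to unit maximum, with
linear interpolation between the bracketing grid points; multiple
crossings return the bluest with a warning. Max-normalization is a
choice — the crossing of area-normalized spectra lands elsewhere — made
so the estimate is independent of acquisition units; it is the reason a
symmetric band pair crosses exactly midway. Energies are vacuum
wavenumbers, ν = 10⁷/λ with λ in nm, and no air/vacuum correction is
applied. kB is fixed at 0.6950 cm⁻¹ K⁻¹ and "room temperature" defaults
to 298 K. Band areas are trapezoidal throughout, and all interpolation
is linear — splines near steep band edges can ring, and a deterministic
quadrature makes normalizations exactly scale-invariant and idempotent.

## Problem sizes and determinism

The ensemble analyses use 25 seeds for the TCSPC lifetime-recovery and
Chl-f-fraction studies, 200 draws for noisy unmixing and 100 synthetic
spectra for deconvolution recovery — sizes at which the medians reported
are stable to well under their tolerance. Every stochastic step takes an
explicit seed and is reproducible; fits given the same data, bounds and
starts are deterministic.

## Known limitations

* Target models are limited to independent sequential branches; schemes
  with back-transfer or equilibria are out of scope.
* Lifetime uncertainties are not propagated from the full covariance;
  ensemble spread over seeds is the intended error measure.
* The measured-IRF path requires a uniform time grid (TCSPC channels);
  nonuniform TA grids use the analytic Gaussian IRF.
* No chirp simulation or correction.
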