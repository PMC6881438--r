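---
title: "Methods: compound GRIN objectives, synthetic multi-FOV movies, and calcium statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compound GRIN objectives, synthetic multi-FOV movies, and calcium statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matriex)
```

This vignette explains what `matriex` computes, the assumptions behind each
stage, and the numerical and design choices that were genuinely open. It
states no empirical result that the test suite and `scripts/acceptance.R`
do not themselves compute.

## 1. Paraxial optics of the compound objective

A GRIN rod lens guides paraxial rays sinusoidally; its index profile
`n(r) = N0 (1 − A r²/2)` sets the ray oscillation frequency `√A` (mm⁻¹).
The pitch `P = Z√A/2π` expresses the lens length in oscillation periods.
`back_working_distance()` evaluates the closed-form conjugate distance for
an object `L1` in front of the lens in water, imaging into air. The same
quantity follows from propagating the ABCD ray matrix of a gradient-index
duct and solving for the axis crossing; the two derivations agree
algebraically, and the test suite checks them against each other to
1e−6 mm over randomized specifications, which guards the implementation
against transcription errors in either form.

Assumptions: strictly paraxial rays, a parabolic index profile, thin
interfaces (no Fresnel or aberration terms). These suffice for working
distances and magnifications; they do not predict point-spread functions.
For PSFs the package deliberately ships measured bead FWHMs per supported
dry objective (`psf_fwhm_lookup()`) rather than a diffraction formula,
because GRIN aberrations make analytic PSF predictions unreliable for this
assembly; the values act as simulator calibration constants.

NA coupling uses the small-angle form exactly as conventionally printed:
`NA_comp = (1.33/M_a)·NA_DO` with water's `n1 = 1.33`, capped by the MO's
nominal NA. Note two constants coexist deliberately: `1.33` in the NA
formula and `1.328` as the front-medium index in the lens tables; both are
kept where they are conventionally used rather than unified. The lateral
magnification uses the Lagrange invariant `M_L·M_a = n1/n2`. Because the
manufacturer's `M_a = 0.1675` is itself a rounded catalogue value, the ray
traced `M_L` differs from `n1/(M_a n2)` by about 1%; tests compare them at
the 2% level.

### Depth conjugation

Multiple MOs image onto one plane when every optical column has the same
height: `Z(P) + L2(P) = H + (depth − L1)`, with `H` the common height of
the DO object plane above the brain surface (all lengths in mm, positive
downward). This planarity condition is the unique formalization that makes
all MO object planes conjugate to a single image plane.

`solve_pitch_for_depth()` solves it for `P` by bracketed 1-D root finding.
One numerical subtlety: the conjugation function has a pole where the `L2`
denominator vanishes (an afocal configuration; at the standard parameters
near `P ≈ 0.241`, inside the practical bracket `(0.15, 0.45)`). Naive
bisection over the whole bracket would converge to the pole's sign change.
The solver therefore scans a 1201-point grid, discards points with
`|residual| > 50 mm` (which removes the two grid cells flanking the pole —
residuals there are in the thousands), picks the first genuine sign change
on the continuous branch, and polishes with `uniroot` at `tol = 1e−12`.
The round-trip residual is required to be below 1 µm; in practice it is at
machine precision (the acceptance tests assert < 1e−6 mm). On the
practical branch the required `Z + L2` increases strictly with target
depth while the pitch decreases, matching the intuition that deeper
targets need longer-coupling lenses.

Two feasibility constraints are enforced with named errors: the target
depth may not be shallower than the front working distance, and the lens
must protrude above the brain surface (`protrusion = Z − (depth − L1) > 0`)
so it can be held and positioned.

### Scan geometry

`scan_geometry()` holds the scanner-side arithmetic: the effective field is
`base_field/zoom`, the DO-plane pixel is `field/npix`, and the specimen
pixel divides by `M_L`. With the default 6 mm field, zoom 1.4, 1200 px and
`M_L ≈ 7.93`, the DO-plane pixel is ~3.6 µm (coarse) while the in-FOV pixel
is ~0.45 µm. The published account quotes ~0.6 µm per in-FOV pixel together
with ~320 px across a 0.2 mm FOV; those two printed numbers imply
`M_L ≈ 6` rather than ~8, an internal inconsistency of the source material.
The package keeps the `M_L`-based computation and notes, rather than
adopts, the implied value. Likewise the target-zone diameter uses an
image-side field constant of 24 mm, the unique constant consistent with all
four published zone diameters; it is overridable.

## 2. The synthetic movie generator

The generator's purpose is to give every pipeline stage a ground truth, at
the study's conditions: 10 Hz frame rate, 300 s recordings (scaled down in
tests), circular FOVs of ~200 µm in one raster frame, GCaMP6f-like
transients, log-normal event amplitudes with the published per-region,
per-state exponents (`amplitude_law()`), ~0.1% inter-FOV crosstalk, rigid
jitter and Poisson–Gaussian noise.

* **Events.** Per cell, a Poisson process (default 0.2 Hz; spontaneous
  cortical rates at these indicators are of this order) with amplitudes
  `10^N(μ, σ)` in Δf/f units. The transient kernel is a double exponential
  with 50 ms rise and 400 ms decay — the indicator is named in the source
  but its kinetics are not; these are standard GCaMP6f values and are
  configurable. The kernel is sampled on the frame grid and normalized so
  its *sampled* maximum is 1, making a noise-free peak read-out exactly
  equal to the generating amplitude (no discretization bias in recovery
  tests).
* **Correlations.** Each cell adds a latent fluctuation
  `driver_amp·(W[r,]·D(t) + √(1−ΣW[r,]²)·e_i(t))` with unit-variance AR(1)
  drivers `D` (OU-style, default τ = 2 s) and private residuals. Expected
  Pearson correlation between cells of regions r and s is then exactly
  `Σ_k W[r,k]W[s,k]`, which makes correlation targets analytic. The default
  weight matrix gives each region a private driver (0.55) plus a driver
  shared by the two cortical regions (0.3, vs 0.15 for CA1), so
  intra-regional > cortico-cortical > cortico-hippocampal — the ordering
  the method is meant to resolve. `driver_amp` defaults to 0.1 Δf/f;
  baseline fluctuations much larger than that would swallow small events
  under a 3σ detection threshold.
* **Rendering.** Somata are uniform disks (radius 5 µm) blurred by the
  measured lateral PSF (Gaussian edge); the neuropil fills the complement
  of the soma coverage inside each FOV at a dimmer baseline, with a signal
  equal to `neuropil_amp` (default 0.15) times the mean somatic Δf/f of
  that FOV — the published neuropil medians (~0.15–0.18 Δf/f) motivate the
  default, which is calibration, not specification, since no generative
  neuropil model is published. Rendering somata as *uniform* disks with
  complementary neuropil makes the mean over a soma ROI an (almost)
  unbiased reader of the generated Δf/f; with Gaussian-profile somata over
  a full neuropil floor, ROI readouts were attenuated by tens of percent,
  which would conflate renderer geometry with pipeline accuracy.
* **Crosstalk.** Each FOV receives `crosstalk_frac` (default 0.001) times
  the mean brightness of every other FOV, uniformly — the plate-measurement
  model. Leakage is linear in the fraction by construction and the tests
  verify the 0.1% dark/bright ratio within shot noise.
* **Motion and noise.** Rigid integer jitter, zero-mean by recentring the
  rounded draws (an exactly zero integer mean is not generally attainable;
  tests assert |mean| ≤ 0.5 px). Sub-pixel motion is out of scope, matching
  the integer SSD corrector. Noise is Poisson on the photon counts (gain
  1.0) plus Gaussian read noise (`noise_sd` × somatic baseline); 16-bit
  output with an overflow guard at 95% of range.
* **Determinism.** One seed fans out to fixed per-stage streams
  (`derive_seed()`); identical configuration yields bit-identical arrays
  and byte-identical TIFF/JSON fixtures.

What the generator does *not* emulate: axial structure, scanning
distortion, photobleaching, non-rigid motion, correlated (non-white) noise,
or the true biological event statistics beyond the fitted log-normal laws.
Passing recovery tests therefore demonstrates self-consistency of the
pipeline under the stated model, not performance on arbitrary real data.

## 3. The analysis pipeline

* **Motion correction** is exhaustive integer-shift SSD minimization
  against a template averaged from selected frames (default: the first
  100), search radius ±10 px by default, ties broken by smallest shift
  magnitude then row-major order, alignment by edge replication. Sub-pixel
  refinement is deliberately omitted to match the stated SSD criterion
  exactly; the compiled search is verified against a plain-R exhaustive
  oracle.
* **Δf/f** uses the 25th percentile of the entire recording as `f0`, with
  linear interpolation between order statistics (the common percentile
  convention; the source does not specify one). `f0 ≤ 0` is an error with
  advice, since Δf/f is then undefined.
* **Event detection** is parameterized (threshold `k_sigma` = 3 times the
  MAD-based noise SD, minimum separation 1 s, onsets must stay above
  threshold ≥ 2 frames, amplitude = peak Δf/f before the next onset)
  because the source never defines its extraction rule. Consequences
  follow: a fluctuating baseline censors events below ~`3σ` and closely
  spaced events merge, so amplitude-law recovery tests use sparse events
  and a quiet driver. All event-level validation is against simulator
  ground truth, never published event counts.
* **Statistics.** Pearson correlations are computed on full Δf/f traces
  (not binarized events), as the published formula is applied to the
  traces; zero-variance traces are excluded with a count. The
  neuron-vs-neuropil comparison pairs each soma's median event amplitude
  with the median peak Δf/f of its annulus (2 px wide, 1 px gap, clipped to
  the FOV and to non-soma pixels) over the same windows, tested with the
  Wilcoxon signed-rank test. The source's phrase "paired Wilcoxon rank sum
  test" conflates two tests; for paired data the signed-rank test is the
  defensible reading, and the two-sample rank-sum test is used between
  states. All-zero differences return p = 1 (no ranks) rather than an
  error.

## 4. Problem sizes and test design

Unit and acceptance tests run at desk scale: frames of 96–160 px, 60–1200
frames, 6–18 cells per movie; the registration oracle uses 32 px crops.
These sizes make every distributional check well-powered for the effect it
asserts while the whole suite stays fast. Two statistical checks deserve
notes. First, the anesthetized→awake upshift for CA1 (0.09 log10 units at
σ ≈ 0.4) sits near the detection limit at the published sample sizes —
single draws reach p < 0.01 only ~70–80% of the time — so the test
summarizes the median p over 25 replicate draws instead of asserting a
single unlucky draw. Second, the crosstalk-robustness comparison renders
with Gaussian read noise only (no Poisson term): additive noise drawn from
the same seeded stream is identical across the two renders and cancels in
the difference, so the <1% RMS bound isolates the crosstalk term itself
rather than independent shot-noise redraws.

## 5. Known limitations

Paraxial design only (no aberrations or tolerancing); measured PSFs limited
to the four calibrated DO models; circular-FOV detection assumes dark
inter-FOV background; no automated cell segmentation (ROIs are drawn from
ground truth or by the user, matching manual ROI practice); integer-pixel
motion only; the long-coupling back working distance computed from the
printed 3-digit parameters is ~17.06 mm while the printed table rounds to
17.3 mm — the catalogue parameters were evidently rounded, and the package
reproduces the formula, not the typo-level discrepancy.
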