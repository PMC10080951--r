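---
title: "Modeling spatiotemporal summation of perimetric stimuli"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling spatiotemporal summation of perimetric stimuli}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perisum)
```

## The problem

White-on-white perimetry estimates the 50% detection threshold for round
achromatic flashes on a 10 cd/m² background, expressed in dB of attenuation
of the maximum luminance (3,185 cd/m²; DLS = dB/10). Sensitivity depends on
stimulus area and duration through two classic biphasic laws — complete
summation (log–log slope 1, Riccò/Bloch) for small/short stimuli, partial
summation beyond the critical size or duration — and, critically, the two
interact: Riccò's area shrinks as duration grows and the critical duration
shortens as area grows. `perisum` implements a model in which a single
quantity, the *total retinal input* (stimulus area × duration × RGC
receptive-field density × cone/RGC convergence), governs sensitivity, so
this interaction falls out of the architecture rather than being fitted.

## Retinal front end

**Mosaics.** Detectors sit on regular hexagonal lattices (`build_hex_mosaic()`),
the densest packing for circular elements and a good idealization of real
cone and parasol RGC mosaics. Positions are linear in integer (row, col)
indices with basis vectors (s, 0) and (s/2, s√3/2), so the lattice has an
exact rectangular "regularized" view (`regularize_lattice()`; row pitch
s√3/2, column pitch s) on which receptive-field pooling becomes a discrete
convolution — computed here by zero-padded FFT and verified in the tests
against per-cell brute-force sums to 10⁻⁹. Only one mosaic class is
simulated per run (parasol-OFF by convention; ON and OFF channels are
assumed redundant for detecting these stimuli), with density supplied as
data. Coordinates are visual degrees from fixation throughout; no retinal
mm conversion is performed.

**Receptive fields.** Each RGC pools cone values through a
difference-of-Gaussians: surround peak 1% of the center peak, surround SD
6.7× the center SD, and the center SD set to spacing/1.414 so the 1/e
center radius equals the intercell spacing — the classic primate
center/surround ratios, with absolute size slaved to mosaic density. The
kernel is truncated at 4 surround SDs (neglected tail mass < 10⁻³ of the
surround) and normalized to unit sum on a matched 1:1 cone lattice. The
normalization is a units convention: a fully covered RGC responds 1, so the
total input S counts "stimulated RGCs" and the critical input is directly
an RGC count; any other scale would be absorbed by the integration constant.

**Convergence.** Cone-to-RGC convergence (the cone/RGC density ratio,
interpolated log-linearly against eccentricity from a user-supplied table)
multiplies every response. A discretely re-meshed mosaic with an integer
cone:RGC ratio gives the same answer — the tests build a 4:1 stack and
confirm agreement within 2% — but the multiplicative route varies smoothly
across the field and avoids the integer-ratio constraint.

**Optics.** The mean-observer modulation transfer function is the square
root of the diffraction-limited MTF for the pupil (555 nm default)
multiplied by a pupil-dependent Lorentzian, following the published
mean-MTF formulation; blur is applied by multiplying the stimulus spectrum
by the MTF with ≥2× zero padding. An optional frequency-flat scatter
attenuation parameterizes age and iris pigmentation (baseline fractions
0.13/0.10/0.08 for light/medium/dark irides, scaled by 1 + (age/70)⁴, a
straylight-style form); it defaults off, and off is also the convention for
unit tests. Aliasing is guarded: blurring errors out unless the MTF at the
grid Nyquist frequency is below 0.01 or less than 1% of stimulus spectral
energy lies near Nyquist.

**Summation mode.** The total input S is the *signed* sum of RGC responses
by default; cells whose surround dominates contribute negatively,
interpreted as suppressed background activity. Signed summation makes S
exactly linear in contrast and density and nearly blur-invariant (optical
blur only redistributes flux, and the tests confirm invariance within 2% in
the well-sampled regime). Summing |Rᵢ| instead (`mode = "absolute"`) makes
the front end strongly blur-sensitive; simulation shows the absolute-mode
input *decreases* under blur — halo light landing on the centers of
suppressed cells (center gain 100× the surround) flips them positive and
shrinks the negative mass — and the blur shift is more than an order of
magnitude larger than in signed mode. Absolute mode is retained for that
sensitivity contrast, not for routine use.

## The pooler

The total input charges a leaky integrator whose impulse response is
h(t) = (S/τ)·e^(−t·S/τ): unit area, time constant τ/S. Writing f(t) for the
unit step of duration T and r = f ∗ h, the pooled response is

R = [∫₀^∞ r(t)ᵏ dt]^(1/k) · S^(1/k) = (τ·g(x))^(1/k), x = S·T/τ,
g(x) = ∫₀ˣ (1−e⁻ᵘ)ᵏ du + (1−e⁻ˣ)ᵏ/k,

and sensitivity reads out as DLS = log₁₀ R + Offset. Several properties
motivate this exact parameterization, which we fix deliberately among the
superficially similar alternatives (e.g. exponent placements that scale R
by S rather than S^(1/k), or a time constant τ rather than τ/S):

* the time constant τ/S shortens for larger stimuli, so bigger stimuli
  integrate faster and the critical duration drops, while longer durations
  shift the spatial summation curve left — the observed interaction;
* R depends on (S, T) only through x = S·T/τ, so area and duration trade
  off exactly (the tests assert the −log₁₀ 2 curve shift under doubled
  duration to 10⁻⁶);
* the log–log slope of R against S (or T) runs from 1 at small x (full
  Riccò/Bloch summation) to 1/k at large x, matching the classic limits.

The readout stage is where contrast enters: S is computed at unit Weber
contrast and thresholds come from the fitted Offset. Putting contrast
inside S — hence inside the time constant — would make thresholds
ill-defined in the partial-summation regime, so that placement is rejected.

The integral extends to infinity. A decision-bounded window (the 1,500 ms
response limit) would differ negligibly for ≤200 ms stimuli, since the
integrator tail decays with time constant τ/S ≪ the window in all fitted
regimes.

**Critical size.** The summation-curve transition is smooth, so the
critical point is a convention: the input where the slope is 0.5 (Piper
criterion). Analytically the slope is x·(1−e⁻ˣ)^(k−1)/(k·g(x)); the root
x_c (2.8822 for k = 4; bisection on [0.05, 100], tolerance 10⁻¹⁰; no root
exists for k ≤ 2) gives S_c = x_c·τ/T and T_c = x_c·τ/S, with S_c·T
constant. Riccò's area is recovered by inverting the area↔input map,
conventionally computed without optical blur to report the neural
contribution. Because a fit re-optimizes (τ, Offset) for whatever input
scaling is used, rescaling convergence by λ multiplies the fitted τ by λ
and shifts the Offset by −log₁₀(λ)/k while leaving predictions and Riccò's
area untouched; the tests assert this reparameterization identity.

**Area↔input map.** S(area) is evaluated on a geometric ladder of areas and
queried by linear interpolation in log₁₀–log₁₀ (warning beyond 0.3
log-units of the table, error beyond 1). Two routes exist: the `"product"`
map (S = area × density × convergence, the exact signed-mode continuum
limit) and the `"mosaic"` map (full rendering, blur, sampling, pooling).
On a discrete mosaic S(area) is a step function at small areas — the disc
grows between lattice shells — so the map keeps the strictly increasing
envelope for inversion, and an exactly centered lattice phase can bias
point-sampled counts by up to ~20% for sub-spacing discs. That is
discretization, not pooling error: phase-averaged counts match area ×
density (tested), and the well-sampled regime (many cells per disc) matches
the continuum within a few percent.

## Fitting

`fit_spatiotemporal()` minimizes the RMSE (in dB, i.e. 10·DLS — the argmin
is scale-invariant; only the reported magnitude depends on the unit) over
(log₁₀ τ, Offset) with Nelder–Mead from three deterministic starts
(log₁₀ τ ∈ {2, 3, 4}, Offset profiled at the start), keeping k = 4 fixed.
A design in which every observation shares one S·T product cannot separate
τ from Offset and errors out. Noise-free synthetic data are recovered
exactly; under 1-dB Gaussian threshold noise on the full 5 sizes × 5
durations design, fitted log₁₀ τ has bias < 0.05 and SD < 0.12 across 100
replicates (tested).

## Psychophysical procedure simulators

* **ZEST** (`zest_run()`): uniform prior on 0–50 dB at 0.1 dB resolution,
  Gaussian-CDF likelihood (SD 1 dB, 3% guess/lapse) oriented so brighter
  (lower-dB) stimuli are more visible, stimulus = posterior mean rounded to
  integer dB, stop at posterior SD < 1.5 dB. The 0.1 dB grid makes the
  integer rounding exact. Mean-of-posterior estimates are approximately
  unbiased (|bias| < 0.5 dB over 1,000 runs, tested).
* **QUEST+** (`questplus_run()`): joint grid over threshold (seed ± 5 dB,
  0.1 dB steps, Gaussian prior SD 4 dB) and spread (1–10 dB, 0.5 dB steps,
  uniform prior), fixed 3% rates; the next stimulus minimizes expected
  posterior entropy over integer-dB candidates; stop at joint entropy
  ≤ 4.5. Entropy is measured in nats: the grid's maximum entropy is
  ln(101 × 19) ≈ 7.6, which makes 4.5 a meaningful mid-range criterion,
  and no downstream quantity depends on QUEST+ trial counts.
* **MOCS** (`mocs_design()`): seven levels at the {10⁻⁴, 0.1, 0.3, 0.5,
  0.7, 0.9, 0.9999} quantiles of the estimated frequency-of-seeing curve,
  extremes forced to ≥ 10 dB either side of threshold, ≥ 1 dB spacing
  enforced by spreading inner levels outward, rounding to the 1 dB
  instrument grid applied last. The standard protocol (7 levels × 25
  repeats × 4 conditions × 4 locations) totals 2,800 presentations.
* **FOS fitting** (`fit_fos()`): Bayesian hierarchical model in JAGS —
  per-location thresholds μ_l ~ N(μ_pop, s_μ), log-spreads similarly
  pooled, global lapse/guess ~ Beta(1, 19), weakly informative hyperpriors
  (these hyperprior choices are this package's own). Partial pooling never
  widens per-location posteriors relative to independent fits (tested).
  Recovery tests use 100 repeats per level so the 0.5 dB accuracy bound is
  several posterior SDs wide; at 25 repeats the binomial noise floor is of
  the same order as that bound.
* **Validity filter** (`filter_responses()`): button presses < 180 ms after
  onset or inside inter-stimulus pauses are false responses.
* **Synthetic observers** (`synthetic_observer()`): threshold = model
  prediction (optionally jittered), spread from a log-linear
  slope–threshold relation log₁₀ σ = 1.42 − 0.035·μ by default — constants
  in the range reported for perimetric observers, encoding multiplicative
  response noise (shallower curves at lower sensitivity).

## The synthetic data generator

`generate_fixture()` emulates the experimental design: 12 locations on the
diagonals ({±7,±7}, {±4,±4}, {±1,±1} deg), Goldmann sizes I–V (0.10–1.72
deg) everywhere at 200 ms, four extra durations (15–105 ms) on the outer
ring — 140 independent threshold threads — plus 2,800 MOCS trials for the
four extreme size/duration conditions at the outer ring. Truth uses the
convergence-weighted product mapping with τ = 3465, Offset = 2.36 (the
all-durations operating point) and Gaussian test–retest noise of SD 1 dB,
about the replicate-level variability of such measurements. The shipped
density table is synthetic: parasol-OFF RGC densities (450, 121, 64 /deg²)
and cone densities (3207, 920, 586 /deg²) at the three tested
eccentricities, chosen to be consistent with published central-field
estimates; real analyses should substitute subject-specific tables.

What the generator does *not* emulate: fatigue and learning effects,
fixation instability, response-time structure beyond the validity rule,
spatial correlation of thresholds between neighboring locations, and any
departure of real frequency-of-seeing curves from the Gaussian-with-rates
form. Passing recovery tests therefore demonstrates internal consistency of
the estimation chain, not validity of those assumptions for real observers.

## Numerical choices

* g(x) uses the closed binomial form for integer k when x ≥ 0.1 and
  adaptive quadrature below (the binomial sum cancels catastrophically for
  small x); an independent double-quadrature route through the convolution
  integral (`pooled_response_numeric()`) agrees within 0.5% over
  x ∈ [10⁻³, 10³] (tested).
* Mosaic extent for area↔input maps is stimulus radius + 3 surround SDs +
  0.5 deg per side, so surrounds never truncate; the default lattice phase
  puts a cell at the stimulus center, with seeded jitter available (edge
  effects only).
* Degraded mosaics delete cells i.i.d.; since deletion only removes
  summands from the signed input, the loss study computes per-RGC responses
  once and resamples survivor masks, making 100-replicate runs cheap. With
  73% loss the expected input scales by 0.27 and Riccò's area by 1/0.27 =
  3.70 (recovered within the binomial noise of the replicate mean, tested
  with ~150 surviving cells inside the degraded critical area).
* Problem sizes in the test-suite simulations — e.g. 100 fit replicates,
  1,000 ZEST runs, 100 end-to-end ZEST→fit replicates, 20-point area
  ladders, mosaics of ~2,000–25,000 cells — were chosen as the smallest
  that leave the Monte-Carlo error well inside each asserted tolerance.

## Known limitations

* Linear, static front end: no contrast gain control, spiking dynamics,
  RGC class mixtures, or eccentricity-dependent receptive-field
  ellipticity.
* The capacitor kernel is monophasic with no response delay; it cannot
  produce the sensitivity decline reported for very long durations, and
  stimuli ≳ 1 s are outside its intended regime.
* Cone sampling uses bilinear interpolation of the rendered image; the
  interpolation scheme is not empirically constrained, and its residual is
  absorbed by the tolerances above.
* The slope-0.5 critical point is a reporting convention on a smooth
  curve; comparisons with criteria defined by two-branch fits are only
  approximate.
* Densities are inputs: the package deliberately does not model
  displacement-corrected RGC density maps or subject OCT customization.
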