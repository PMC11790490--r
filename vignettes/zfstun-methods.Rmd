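---
title: "Methods: dosimetry, kinematics and calcium analyses for electrical stunning of larval zebrafish"
author: "zfstun authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dosimetry, kinematics and calcium analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`zfstun` implements the complete analysis stack of an electrical-stunning
study in larval zebrafish: field dosimetry, behavioral mortality
classification, silhouette-based tail kinematics and calcium-imaging
analyses, plus a synthetic-data generator that replaces the raw recordings.
This vignette documents the models, the tunable parameters, the numerical
choices and the limits of what the synthetic validation can show.

## Electrical dosimetry

The exposure is described by a `FieldExposureConfig`: waveform (DC,
sinusoidal AC, or pulsed DC), peak voltage gradient `E` (V/cm), frequency,
duty cycle, duration, medium conductivity `sigma` (S/cm) and the chamber
geometry (electrode gap `d`, wetted electrode area `A`, medium volume `V`).
Defaults describe a free-swimming exposure chamber: `d` = 5 cm, `A` = 5.4
cm^2, `V` = 24 mL, `sigma` = 680 uS/cm (standard E3 embryo medium).

The dissipated power density is `p = E_eff^2 * sigma`, with the
*effective* field defined per waveform: the field itself for DC, the RMS
value `E / sqrt(2)` for sinusoidal AC, and the peak field for pulsed DC
with no duty-cycle factor. These conventions are the only set under which
the two published reference dissipation levels for larval euthanasia —
0.85 W/cm^3 for 50 V/cm AC in 680 uS/cm medium and roughly 0.7 W/cm^3 for
25 V/cm, 50 Hz PDC in ~1125 uS/cm medium — are reproduced simultaneously,
which is why the package treats them as fixed rather than configurable.

`densityFromCurrent()` converts a measured current trace to power and
current densities via `p(t) = U I(t) / V` and `J(t) = I(t) / A`. For AC
the measured current and voltage are interpreted as RMS readings, so
`U = E_eff * d`; with consistent geometry (`V = A d`) and the ohmic
current `I = sigma E_eff A`, this reproduces the closed-form power density
for every waveform — the identity the unit tests check to machine
precision.

`simulateJouleHeating()` integrates the feedback loop behind the observed
current rise during exposure: dissipation heats the medium
(`dT/dt = p / C`, volumetric heat capacity `C` = 4.18 J/(cm^3 K), water),
temperature raises conductivity linearly
(`sigma(T) = sigma0 (1 + alpha (T - T0))`, with `alpha` around 0.02/K for
dilute electrolytes), and conductivity raises dissipation. The integration
is forward Euler; halving the step changes the final temperature by well
under 1% at the default `dt` = 0.01 s. The model is deliberately
adiabatic: it captures the *mechanism* (monotone rise of current, power
and temperature) but is not expected to reproduce measured chamber
temperatures, which depend on electrode-local current crowding and heat
loss that the study did not quantify. With `alpha = 0` the electrical
traces are constant while the temperature still integrates linearly —
heating does not stop, only the feedback does.

## Mortality classification and proportion statistics

A larva counts as dead only if **all four** behavioral criteria — no
activity of any kind, loss of equilibrium, no operculum movement, no
startle response — hold at **both** observation points (directly after
exposure and after 30 min of recovery). Cardiac arrest is deliberately not
a criterion: larvae survive on cutaneous oxygen diffusion long after the
heart stops, so heartbeat is uninformative at this age. `classifyDead()`
is monotone by construction: clearing any flag can only move a larva from
dead to alive.

Rates come with 95% Wilson score intervals (`wilsonInterval()`), which
behave sensibly at observed rates of 0% and 100% where Wald intervals
collapse. Pairwise condition comparisons use the pooled-variance
two-proportion z-test without continuity correction — the classical
"z-test for proportions", chosen so that `z^2` equals Pearson's chi-square
on the 2x2 table — followed by Bonferroni correction
`p_adj = min(1, m p)`. The family size `m` is caller-supplied (defaulting
to the number of pairs tested) because the appropriate family depends on
which panel of comparisons a user reports.

## Tail kinematics from silhouette video

The pipeline mirrors a fixed preprocessing recipe: median filter (20 px
window), intensity inversion, Otsu binarization, removal of connected
components below 600 px, retention of the largest remaining component.
The silhouette is thinned to a one-pixel midline with a compiled
Zhang-Suen pass; the skeleton path is the longest geodesic through the
8-neighbor pixel graph (Euclidean edge weights), oriented head-first by
comparing distance-transform maxima along the two halves of the path (the
head half contains the widest body region).

**Total tail angle.** The angle is the sum of signed turning angles along
the skeleton, which telescopes to the heading difference between the two
path ends — so endpoint heading estimation is the whole game. Raw pixel
chains quantize headings to 45 degree steps; the implementation therefore
smooths the path with a local-quadratic filter (window 7 px; unlike a
moving average this does not bend curved ends inward), resamples it at
uniform 2 px arc steps including the exact endpoint, and extrapolates the
end headings by short linear fits of the unwrapped heading profile over 24
px — exact for constant curvature and robust to the staircase at the tail
tip. On analytic quarter-circle midlines of radii 25-60 px the estimator
is within 0.2 degrees of 90. Sign convention: bending toward increasing
image row (leftward for a head pointing along +column) is positive; the
absolute sign is a convention, as only magnitudes and frequencies are
interpreted downstream.

**Standard length** is the arc length of the lightly smoothed skeleton
(raw 8-connected chains overestimate oblique lengths by their staircase)
times the spatial scale. **Kymographs** resample each frame's signed
perpendicular displacement from the rostrocaudal reference axis (total
least squares fit to the first analyzable frame's skeleton) to the minimum
skeleton point count across frames, normalized by the stack-wide mean
absolute displacement; the stack-wide mean is used because a lone
field-exposure recording need not contain a swim bout to normalize
against. **Tail-beat frequency** is the maximum non-DC bin of a Welch
spectrum of the mean-detrended angle trace (Hann window, 1 s segments,
50% overlap), so at 500 Hz sampling the 60 Hz drive and 20 Hz swim
frequencies fall on exact bins.

## Calcium-imaging analyses

All recordings are sampled at 2 Hz; the design uses a 6 min baseline (3
min with a full-field flash of 6 s period — main frequency 1/6 Hz =
0.1667 Hz), a 6 min shock recording and a 12 min recovery recording.

* `dff()` computes `(F - F_b)/F_b` with `F_b` the mean over a baseline
  window (default: the first 60 s).
* `pixelwiseMeanPsd()` runs a Welch PSD per raw pixel (mean-detrended, no
  registration or segmentation — deliberately, because post-shock drift
  defeats registration) and averages across pixels. The Welch segment
  length defaults to 360 samples (180 s) so the stimulus main frequency
  lies exactly on a bin; Hann window, 50% overlap, one-sided density
  scaling satisfying Parseval.
* `buildRegressor()` resamples the logged 100 Hz on/off stimulus to the
  imaging rate by interval means thresholded at 0.5 (sample-and-hold for
  square waves) and convolves causally with a unit-sum exponential kernel
  of decay constant 1.61 s (GCaMP6f), truncated at five time constants.
* `stimCorrelation()` and `tunedFraction()` score stimulus tuning by
  Pearson correlation with the regressor; the tuning threshold is
  `|r| > 0.3`.
* `correlationVarianceTest()` is the classical Levene test (absolute
  deviations from the group *means*, not medians), delegated to
  `car::leveneTest`.
* `crossCorrMatrix()` keeps the `ceiling(0.2 N)` ROIs of largest `|r|` —
  absolute value, because both stimulus-correlated and anti-correlated
  populations are "best correlated" — sorts them by signed `r` from
  positive to negative, and computes all pairwise Pearson correlations; a
  healthy baseline shows two anti-correlated on/off blocks.
  `averageMatrices()` brings matrices of several fish to the rounded mean
  side length by separable linear interpolation and averages with weights
  proportional to each fish's total ROI count.
* `roiAcf()` computes per-ROI autocorrelation functions (mean-removed,
  lag-0 normalized) with the regressor's ACF attached; stimulus-locked
  activity shows peaks at multiples of the 6 s flash period, post-stun
  activity decays monotonically. The ACF operates on raw traces; since
  the estimator removes each trace's mean and normalizes at lag zero it
  is insensitive to the dF/F scaling.
* `comparePsdAcrossRecordings()` compares recordings per frequency bin
  with a repeated-measures ANOVA (fish as blocking factor) and
  Tukey-adjusted pairwise contrasts via `emmeans`; each bin is tested
  separately and the full per-bin, per-contrast table is returned so the
  user decides the omnibus structure. Bins with degenerate (zero residual)
  variance return NA p-values rather than errors. The model is fit with
  sum-to-zero contrasts so that no re-fit is needed downstream.

## The synthetic-data generator

No raw recordings are deposited with the study, so the generator is a
first-class module that emulates each data type with known ground truth.

**Calcium movies.** Square ROI footprints (3x3 px by default) are placed
disjointly on a jittered grid; on-tuned ROIs follow the CIRF-convolved
stimulus, off-tuned ROIs the convolved inverted stimulus, untuned ROIs are
noise-only. Noise is additive Gaussian per pixel and frame with unit s.d.,
and `snr` is the planted signal s.d. in noise-s.d. units. Three modeling
choices matter and are worth stating plainly:

* resting brightness is spatially homogeneous (ROI pixels and background
  share one baseline, default 100), as in densely expressed nuclear
  H2B-GCaMP6f where somata and neuropil are comparably bright;
* the planted modulation is zero-mean around rest — expression level, not
  momentary activity, sets resting brightness;
* response gain varies across neurons (lognormal jitter, s.d. 0.5 on the
  log scale), as real tectal populations do.

The first two properties are what make the pixel-PSD robust to the
simulated 100 px drift: a translation moves almost no resting contrast, so
the spectrum reflects temporal structure. That robustness is itself a
published property of the real data, which pins these generator choices —
a generator with strong static contrast would contradict the study design
it emulates. Post-stun movies are a global exponential decay toward an
intensity floor plus additive traveling Gaussian wavefronts (configurable
onset, speed, direction), optional linear drift, and noise — and no
stimulus-locked component whatsoever.

**Silhouette videos.** The larva is a filled 2-D shape: disks of a
tapering half-width profile stamped along a parametric midline of 240 px
(3.9 mm at 0.01625 mm/px — a realistic image scale, chosen so the fixed
20 px median window and 600 px area threshold operate as they would on
real video). The head/yolk region rises linearly from a pointed snout (so
the medial axis spans the full anatomical midline) to a half-width of 9%
of body length over the first sixth; the tail tapers linearly to a point.
The head segment is rigid and widths are pinned to the resting body
length: simulated contraction (via `lengthProfile`) shortens the tail
musculature without thinning the body, which is what lets a planted 20%
standard-length contraction be measured as 20%. In driven mode the
curvature is spatially uniform and sinusoidal in time (total angle
`A sin(2 pi f t)` exactly); in swim mode half a curvature wavelength
travels snout-to-tail each cycle, so the total angle is again sinusoidal
at the drive frequency while the bending phase lags rostrocaudally.

**Mortality records and current traces.** Records are Bernoulli draws: a
dead larva has all eight criterion flags set; an alive larva has at least
one unmet criterion. Current traces follow the joule-heating model, with
optional seed-reproducible measurement noise.

All generators are bit-reproducible for a fixed seed, and each restores
the caller's RNG state.

## Problem sizes and validation scope

The test suite and the acceptance script run everything at reduced but
non-trivial sizes chosen as the package's own validation design: calcium
movies of 64x128 px and 360 s (720 frames), silhouette videos of 280x360
px at 500 Hz for 0.1-2 s, 20-seed Monte-Carlo checks for tuning and
planted-fraction recovery, and 2000 replicates for Wilson coverage.

What passing tests show — and what they do not: the synthetic movies
satisfy the analyses' own assumptions (additive Gaussian noise, exact
square-wave stimulus, rigid footprints), so the tests validate the
*computations*, the planted-parameter recovery and the qualitative
phenotype contrasts (loss of the stimulus peak, of tuning, of population
structure after stunning). They do not validate robustness to real-world
nuisances the generator does not model: photobleaching, scan artifacts,
neuropil contamination, non-Gaussian photon noise, imperfect segmentation,
or larvae touching the frame edge. The length-contraction validation runs
without the median step: those frames are nearly noise-free, and the fixed
20 px window truncates bodies of different lengths at fixed *absolute*
widths, which would confound a measurement whose purpose is relative
length. On real video the window size should be chosen against the imaging
scale, which is exactly why `analyzeStack()` exposes it.

## Known limitations

* The adiabatic heating model understates measured chamber temperature
  rises (no electrode-local current crowding; no heat loss pathway).
* Wave detection in post-stun movies is out of scope: waves are generated
  with ground truth but the package does not fit wave speeds or origins.
* The Bonferroni family size and the recovery analysis window (before the
  first slow wave) are caller-supplied; neither has a principled default.
* The angle sign convention is arbitrary up to mirror symmetry; analyses
  should interpret magnitudes and frequencies only.
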