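---
title: "Measuring PET scanner performance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring PET scanner performance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petperf)
```

petperf implements the analysis side of the NEMA NU2-07 performance tests
for PET scanners — spatial resolution, sensitivity, scatter fraction and
count-rate performance (NECR), count-loss/randoms-correction accuracy, and
IEC body-phantom image quality — together with synthetic generators that
emulate each test's phantom and acquisition with known ground truth. The
generators exist so that every stage of the analysis can be validated by
parameter recovery: a physicist can check that the code recovers what it was
fed before trusting it on scanner data. This vignette explains the models,
the tunable parameters, and the numerical choices, and is explicit about
what the synthetic fixtures do and do not emulate.

## Spatial resolution

A reconstructed point source in air is summarised by the full width of its
point-spread function at half (FWHM) and one-tenth (FWTM) maximum, in the
radial, tangential and axial directions, at the standard positions (1 cm
and 10 cm from the transaxial centre). The pipeline is:

1. `locate_peak()` finds the maximum voxel and refines each coordinate with
   a parabola through the maximum and its two neighbours. The parabola is
   fitted to log intensities when all three samples are positive — exact
   for a Gaussian peak — and to raw intensities otherwise. Ties are broken
   towards the lowest index; a maximum on the volume border is an error.
2. Profiles are 1-D nearest-neighbour lines through the peak voxel along
   the grid axes (not integrated slabs; for a separable PSF an in-plane
   offset of the line scales the amplitude but not the width).
3. `profile_width()` takes the peak amplitude from the same log-parabola
   and finds the two crossings of `level × peak`.

For the crossings, two interpolators are available. `interp = "linear"` is
the classic prescription — linear interpolation between the two samples
straddling the level. It is simple but biased wide: near the half-maximum a
Gaussian is convex, so the chord lies below the curve and the crossing
moves outward. The bias is about +2% at FWHM = 3 voxels and +4% at
FWHM = 2.4 voxels, which matters at typical sampling (4.8 mm FWHM on a
2 mm grid). The default `interp = "spline"` therefore upsamples the profile
100× with a natural cubic spline before the linear crossing search; its
error stays below ~1.5% for FWHM ≥ 2.4 voxels. Below FWHM ≈ 2 voxels no
local interpolator is reliable — the generator warns when asked to produce
such a volume, and width estimates there should not be trusted. No
background is subtracted by default (point sources in air).

`make_point_source_volume()` paints an anisotropic Gaussian with the
requested per-axis widths, normalised so the voxel sum equals the requested
total counts exactly; recovery of the generating widths to within 1–2% and
of sub-voxel positions to within 0.05 voxel is part of the test suite.

## Sensitivity

The five-sleeve phantom measures the system sensitivity free of the
source's own attenuation. Each configuration `j` adds one aluminium sleeve
(wall 1.25 mm), giving accumulated thickness `X_j = 1.25 j` mm. The model
pair used by generator and analysis is

    rate_j = S0 · A(t_j) · exp(−2 μ X_j),

with `A(t)` the activity decayed to the frame **mid-time** (the protocol
does not fix the reference point; mid-time is used consistently throughout
the package) and the factor 2 standing for the annihilation photon pair
traversing both sleeve walls. This is a modelling convention, not physical
truth — the analysis inverts exactly the model the generator uses, and on
real data the fitted slope is simply an effective attenuation.
`fit_attenuation_free()` fits an unweighted least-squares line to
`(X_j, log rate_j)` and reports `S0 = exp(intercept)`; on exact exponential
input the recovery is exact to floating-point precision. The axial profile
scales the per-slice counts of the first configuration so they sum to `S0`;
the generator uses a triangular slice-sensitivity profile, the shape a 3-D
acquisition produces for a line source spanning the axial field of view.

Manufacturer acceptance limits (e.g. a minimum `S0`) are never built in;
they are supplied through the `limits` block of `run_suite()`'s config.

## Scatter fraction and count-rate performance

### The rate model

The line-in-cylinder acquisition is modelled by `countrate_model()`:

* trues `T(a) = c_T · a · exp(−λ a)` — paralyzable dead time; a
  non-paralyzable form with quadratic randoms need not produce a finite
  NECR peak, the paralyzable one always does;
* scatter `S(a) = T(a) · sf/(1 − sf)` — constant scatter fraction;
* randoms `R(a) = k_R · a²` — spatially flat, quadratic in activity;
* `NECR(a) = T²/(T + S + R)`.

`calibrate_countrate_model()` inverts this family to hit a requested
operating point (peak NECR and its activity concentration, at a given
scatter fraction). Writing `A` for the total activity at the peak and
`w = T(A)/(1−sf)`, the stationarity condition has the closed form
`w = 2 k_R A² λ / (1/A − λ)` and the peak value is
`(1−sf)² w²/(w + k_R A²)`; both are strictly increasing in `λ` on
`(0, 1/A)`, so a single monotone root solve determines `λ` and then `c_T`.
The test suite verifies the analytic peak against a brute-force grid search
at 0.01 kBq/cc resolution. The randoms coefficient defaults to
`k_R = 1 cps/MBq²`, which puts randoms at roughly a third of trues at a
high-count-rate scanner's peak — a realistic regime; it is a free
parameter. The activity-concentration denominator is the full cylinder
volume (`π · 101.5² mm² · 700 mm ≈ 22,656 mL`); pass `volume_mL` to use the
rounded 22,000 mL convention.

### The estimator

`compute_curves()` implements the single-slice profile analysis per frame
and slice:

1. `align_and_collapse()`: each angular projection is circularly shifted so
   its maximum sits at the central bin, then projections are summed.
   Counts are conserved exactly; all-zero projections are skipped.
2. `mask_beyond_12cm()`: bins with |r| > 120 mm are zeroed. Bin centres sit
   at `(i − floor(n/2)) · bin_size` (0-based `i`), i.e. there is a bin at
   exactly r = 0; on the default 256 × 2 mm grid the mask keeps exactly 121
   bins.
3. `split_trues_background()`: the scatter+randoms pedestal is read at
   ±20 mm, a straight line is drawn between the two values, and counts
   above the line inside the window are trues; everything else inside the
   mask — including the under-peak trapezoid — is background. Trues plus
   background equal the masked total exactly; negative trues are clamped to
   zero and flagged.

Randoms come from the delayed channel when present, otherwise from
residual subtraction using the scatter-to-trues ratio of the three
lowest-activity frames (documented as approximate). A frame qualifies as
"low activity" when `R < 1% of T`; the reported scatter fraction is the
mean of `S/(S+T)` over qualifying frames, and the per-frame NECR uses the
non-TOF single-randoms form `T²/(T+S+R)` (a `2R` variant is selectable).
Whether a published scatter fraction refers to the low-activity average or
to the value at the NECR peak is often ambiguous; the summary carries both
(`SF_reported_pct`, `SF_at_peak_pct`), and for the constant-SF generator
they coincide.

`find_necr_peak()` refines the peak with a parabola through the maximum
frame and its two neighbours in (activity concentration, NECR) space,
falling back to the maximum frame when the parabola is degenerate or its
vertex leaves the neighbour interval. The refined value is never below the
best sampled frame.

### Calibration of the emitted sinograms

The generator (`make_countrate_series()`) composes each projection from a
6 mm FWHM trues kernel at the projected line position (`45 cos θ` for the
45 mm offset), a 60 mm FWHM Gaussian scatter background centred under the
peak, and a flat randoms floor. Two consequences of the NU2 estimator
deserve emphasis:

* **Scatter fraction is operationally defined.** The ±2 cm trapezoid
  underestimates a Gaussian scatter hump by ~11% of the scatter counts, so
  raw-count SF and estimator SF differ by several points. Since the test
  *is* the estimator, ground truth must live on the estimator's scale: the
  generator solves a 2×2 linear system (the estimator's response to the
  unit trues and unit scatter shapes, computed once per geometry) so that
  the estimator-referenced trues and scatter equal the model's exactly.
  Because the split conserves counts inside the mask, total counts are
  conserved automatically.
* **Alignment moves bins.** A randoms floor restricted to the mask would
  be smeared across the mask edge by the per-angle circular shifts. The
  floor therefore spans the whole radial extent (a constant is
  shift-invariant), with its level set so the randoms *inside the mask*
  equal the model rate; the same number is recorded as the per-frame
  delayed channel. Model rates thus refer to the 12 cm analysis region.

The default frame schedule spans 1295 MBq (35 mCi) to 1.8 MBq in 30 frames
of 120 s, log-spaced in two phases: two-thirds of the frames down to
80 MBq, the rest below. The dense first phase brackets both scanners'
NECR peaks with ~16% activity steps; with a single log-spaced phase the
step near the peak is ~22% and the three-point parabola misplaces the peak
by ~1.3%, while the two-phase schedule keeps both the peak value and its
location within 1% — mirroring the practice of sampling more finely around
the expected peak. Frame mid-times follow from the decay law; within-frame
decay (~1% of a half-life) is absorbed by referencing all rates to the
frame mid-time, on both the generating and analysing side.

### Count-loss and randoms-correction accuracy

The acquisition records the dead-time constant it was generated with,
standing in for the scanner's built-in count-loss correction.
`randoms_accuracy()` multiplies the measured trues by `exp(λa)`, averages
the corrected specific rate (cps/MBq) over the qualifying low-activity
frames, extrapolates linearly in activity, and reports per-frame percent
deviations; the summary is the maximum absolute deviation below the NECR
peak. With a perfect correction the deviation is identically zero;
`make_bias_profile()` injects an imperfect correction whose below-peak
maximum is exactly the requested percentage (the bias rises as activity
squared to a reference frame just below the peak and falls off
symmetrically in log-activity above it). Scatter scales with the biased
trues, so the scatter fraction is invariant under the injected bias.

## Image quality

The IEC body phantom carries six spheres (10–37 mm) on a 114.4 mm ring;
the four smallest are filled hot at a nominal 8:1 ratio to background, the
two largest are cold, and a low-density lung insert sits at the centre.
The metrics, per sphere size, from `iq_report()`:

* hot percent contrast `Q_H = 100 ((C_H/C_B) − 1)/(ratio − 1)`,
* cold percent contrast `Q_C = 100 (1 − C_C/C_B)`,
* background variability `N = 100 · SD/mean` over the background ROI means
  (sample SD),
* lung residual `100 · C_lung/C_B`.

ROIs are circles of each sphere's inner diameter in the central slice;
twelve background positions near the phantom edge are replicated on the
central slice and at ±10 and ±20 mm — 60 background samples per size.
Voxel membership is by voxel-centre-inside-circle, with no partial-volume
weighting; the generator paints spheres with the same rule, so noise-free
round-trips are exact. The mean hot contrast is computed over the four
hot spheres. The body section is modelled as a 250 mm circle (the torso's
long dimension) so that every background ROI keeps 15 mm of clearance from
the spheres and the edge; the twelve ROI angles interleave the six sphere
angles on a 90 mm ring.

`make_iq_image()` paints the phantom directly in image space at the
*measured* sphere-to-background ratios (helpers
`ratio_for_hot_contrast()` / `ratio_for_cold_contrast()` convert a target
contrast to a ratio). Optional zero-truncated Gaussian voxel noise with
per-voxel coefficient of variation `noise_cv_voxel` produces a background
variability of approximately `100 · cv/sqrt(n)` for ROIs of `n` voxels.

## What the generators do not emulate

The fixtures are image/sinogram-domain emulations with known truth, not
physics simulations. There is no Monte-Carlo photon transport, no
reconstruction (and hence no reconstruction-driven partial-volume,
Gibbs or correlation structure), no time-of-flight, no attenuation-map
errors, and the scatter/randoms shapes are stylised (Gaussian hump, flat
floor). Passing recovery tests therefore demonstrates that the estimators
are implemented correctly and are numerically stable — it does not
validate a scanner, and measured values on real data will include effects
the generators deliberately omit. Poisson mode adds counting noise at the
sinogram level and Gaussian mode at the voxel level, which brackets but
does not reproduce the noise texture of iterative reconstructions.

## Numerical choices and degenerate inputs

* Widths: log-parabola peak amplitude; natural-spline crossing search at
  0.01-sample resolution; truncated profiles (level never crossed) are
  errors, not NA.
* Peak refinement everywhere uses three-point parabolas with explicit
  degeneracy fallbacks (flat curvature → integer maximum; vertex outside
  the bracket → integer maximum).
* Negative trues after pedestal subtraction are clamped to zero and
  flagged; all-zero projections are skipped and recorded.
* Monotone NECR curves raise a "no peak" error advising a wider activity
  range; fewer than three qualifying low-activity frames is a warning,
  none is an error.
* Problem sizes: the bundled tests and the acceptance script run the full
  30-frame × 81-slice × 256 × 128 noise-free series (a few seconds each)
  and reduced sizes (2–3 slices, 32 angles) for unit and Poisson-replicate
  tests; noise-free recovery is size-independent because identical slices
  are stored once and shared.
* Seeds: every stochastic generator takes an explicit `seed` (default 0);
  noise-free outputs are deterministic by construction, Poisson outputs
  are bit-reproducible under a fixed seed.

## Files and interfaces

Volumes read and write as NIfTI-1 (via RNifti) or raw float32 + JSON
sidecar; sinogram series as a directory of raw float64 frames with a JSON
header (a deliberately simple, self-describing container); sleeve records
as CSV + JSON; every generator's ground truth as a JSON sidecar.
`run_suite()` drives the whole suite from a YAML/list config with
user-supplied acceptance limits, and `exec/petperf` wraps it for the shell.
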