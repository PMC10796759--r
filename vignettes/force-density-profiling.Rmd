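---
title: "Force-density profiling along drilled vertebral canals: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Force-density profiling along drilled vertebral canals: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drillprofile)
```

## The problem

During trans-pedicular access to a vertebra — pedicle-screw placement,
kypho-/vertebroplasty, bone biopsy — a drill passes through the cortical
shell of the neural arch into the trabecular interior. The axial force the
drill experiences is a direct mechanical readout of the tissue it traverses,
and the pre-interventional CT scan carries an imaging surrogate of the same
quantity: Hounsfield units (HU) track regional bone mineral density. If the
two agree along the drilled trajectory, pre-interventional CT can predict the
force profile of a planned trajectory — the basis for safety margins in
robot-assisted drilling, where the end-effector measures force in real time.

`drillprofile` implements the full comparison pipeline for paired pre/post
CT volumes of the same specimen plus a force recording made during drilling
at constant feed:

1. **Register** the post-interventional volume rigidly onto the
   pre-interventional one (`register_rigid()`, `resample_volume()`).
2. **Estimate the canal** from the pre-minus-post difference image: threshold,
   keep the largest 26-connected component, weighted principal component
   analysis for the axis, half-maximum refinement of the endpoints
   (`difference_volume()`, `segment_canal()`, `estimate_axis_pca()`,
   `refine_endpoints()`).
3. **Profile the density** along the canal on the pre volume with a fixed
   perpendicular-disk stencil (`extract_profile()`), convert HU to gray
   values (`hu_to_gv()`), and apply a sliding ±0.2 mm min/max/mean window
   (`windowed_stats()`).
4. **Align** the force record with the intensity profile at the point of
   insertion and resample both onto a common arc grid (`detect_insertion()`,
   `align_pair()`).
5. **Correlate**: Spearman's rank correlation with significance, Pearson's
   R², strength classification, and grouped tabulation by vertebral level,
   region, and donor (`spearman_corr()`, `pearson_fit()`, `classify_r()`,
   `grouped_correlations()`).

Because no cadaver scans are publicly deposited, the package ships a
synthetic-data module (`make_phantom()`, `carve_canal()`,
`simulate_force_trace()`) whose ground truth scores every stage.

## Geometry conventions

World coordinates are millimetres. Voxel `(i, j, k)` (1-based) holds the
value at its center, `origin + (c(i, j, k) - 1) * spacing`; continuous
positions are sampled trilinearly; positions outside the grid read as air
(−1000 HU). Only axis-aligned volumes are supported: the study design scans
specimens cranio-caudally on one scanner, and oblique orientations are
rejected at read time rather than silently resampled. Rigid transforms are
three rotation angles in degrees applied x-then-y-then-z about the volume
center, plus a translation in mm. No convention for this is universal; this
one is fixed and documented, and `transform_error()` compares transforms
convention-free via the composition with the inverse.

## The phantom and what it does (not) emulate

`make_phantom()` builds a vertebra-like scene: an ellipsoidal body of
textured trabecular bone (smoothed Gaussian field, mean ≈ 300 HU, sd 60 HU
by default) inside a ≈ 1.5 mm cortical shell at ≈ 1200 HU, on an air
background, plus two asymmetric posterior lumps standing in for the neural
arch and a lateral process. The lumps are not anatomy; they exist because a
lone smooth ellipsoid is nearly rotation-symmetric, which would make rigid
rotations almost unobservable — real vertebrae are strongly asymmetric, and
the phantom must be too for registration to be testable. All interfaces are
softened over about two voxels: CT images are band-limited by the scanner's
point-spread function, and a scene with edges sharper than the grid aliases
under resampling (one symptom is a biased registration optimum; see below).

The canal is an oblique segment entering through the shell and ending in the
interior, with the 3.05 mm outer diameter of an 11G drilling tool. Its
length is drawn from 45–62% of the smallest volume extent (28.6–39.4 mm at
the default 128³ grid of 0.5 mm voxels, the observed thoraco-lumbar range).
`carve_canal()` removes a flat-ended cylinder — a distance-to-segment rule
would carve hemispherical caps extending a radius beyond the true entry
point, which would defeat sub-voxel endpoint scoring — softens the wall over
one voxel, and applies the recorded rigid misalignment by resampling.

The force model is declared, not biomechanical: after an air approach of
`insertion_offset` mm, the clean force is affine in the gray value at the
tip position, `F(x) = a + b (GV(x - s0) - GV(0))`, plus stationary AR(1)
Gaussian noise, sampled at 1 kHz under a 2 mm/s constant feed. The study
this emulates only asserts a monotone association between force and
intensity, so the simulator's link is configurable and recorded in the
ground-truth sidecar; the goal is parameter recovery, not drilling physics
(no torque, chip evacuation, or tool wear). Defaults: intercept 0.2 N, slope
0.0025 N/GV (peak forces ≈ 5–6 N at cortical gray values, the observed
magnitude), noise sd 0.15 N with AR(1) coefficient 0.8 at 1 kHz (a ≈ 5 ms
sensor-noise correlation time). With `target_rho`, the noise sd is instead
set from the Gaussian-copula relation `rho_P = 2 sin(pi rho_S / 6)`, exact
when the density values are Gaussian.

What passing phantom tests does **not** show: performance on pathological
bone (lytic lesions, osteoporotic shells), metal artifacts, scanner-specific
HU calibration, or the behaviour of the manual steps the original workflow
contained. The phantom's trabecular texture is a smooth random field, not a
trabecular network; its cortical shell is uniform.

## Registration

The metric is the masked mean squared HU difference (body mask: fixed
volume > −500 HU), appropriate because the pair is monomodal — same scanner,
same protocol. Optimization is derivative-free Nelder-Mead over the six
rigid parameters on a three-level pyramid (block-mean downsampling by 4, 2,
1), followed by restarted polishing passes at full resolution; restarts
re-initialize the simplex, which reliably escapes premature shrinkage. Both
volumes are smoothed with a separable 1-2-1 binomial kernel before the
metric at every level: the resampled moving image carries interpolation
blur that the fixed image lacks, and without shared smoothing that asymmetry
measurably biases the metric's minimum in rotation. The recovered transform
is the correction to apply to the moving volume; the optional `init`
argument takes the role of a manual pre-alignment.

On 128³ phantoms with 30 HU noise and random misalignments up to 5° / 5 mm,
median recovery errors are on the order of 0.05° and 0.01 mm (the
acceptance script recomputes these). Equivalence to any particular
commercial implementation is not claimed — only transform recovery on known
ground truth.

## Canal estimation choices

* **Difference threshold 400 HU** (configurable): above trabecular
  partial-volume and resampling ripple, far below the ≈ 1300 HU contrast of
  trabecular bone against the air-filled canal.
* **Weighted PCA** with weights equal to the difference magnitude: rim and
  segmentation artifacts carry low weight, the canal core dominates. A
  first-to-second eigenvalue ratio below 4 raises "no dominant axis" rather
  than returning a meaningless direction.
* **Provisional endpoints** at the 0.5%/99.5% weighted quantiles of axial
  projections; **orientation** picks as entry the endpoint nearer the volume
  boundary, a stand-in for anatomical knowledge of the dorsal entry point.
* **Half-maximum endpoint refinement**: walking from the canal interior
  outward in 0.05 mm steps, the endpoint is the interpolated position where
  the perpendicular disk-mean of the difference first falls below 50% of the
  canal's median difference, capped at ±2 mm (beyond the cap the provisional
  endpoint is kept, with a warning).
* **Profile stencil**: 13 points per arc step (axis point + rings of 6 at
  r/2 and r), `ds` = 0.1 mm. The per-step mean/min/max stand in for "all
  recorded intensities" across the cross-section; the count is configurable,
  and `disk_points = 1` gives a pure axis profile. The 0.1 mm step
  reproduces the observed pairs-per-pathway-millimetre of the reference
  tabulation.

## Intensity processing

Gray values are `clamp(HU + 1026, [0, 4096])`. The printed conversion in the
source material is internally inconsistent (its second line implies a
negative slope, contradicting the result that the densest bone has the
maximum gray value), so the package adopts the stated anchor −1025 HU ↔ 1 GV
with unit slope and makes the offset configurable. This choice is provably
inconsequential: the map is affine and rank-preserving wherever unclamped,
so Spearman correlations are bit-identical under any offset and Pearson r is
unchanged by the affine part — asserted numerically in the test suite.

The ±0.2 mm "low-pass" window records, at each arc position, the minimum,
maximum and mean of all samples within 0.2 mm (a 0.4 mm window). Windows
truncate at the profile ends rather than shrinking the output. The default
correlation channel is the windowed maximum, which tracks the force record
most strongly; it is selectable (`correlation_channel`).

## Alignment

The force record is converted to displacement (`x = v t`; 0.002 mm per
sample at the defaults) and both series are anchored at the point of
insertion: baseline = mean of the first 5% of samples, onset = first
position sustained above baseline + 5% of range for 3 samples, returned with
sub-sample precision by interpolating the threshold crossing. For the
densely sampled force record the onset is found in two stages — coarse
detection on block means (one block per half profile step), then refinement
at the raw threshold crossing nearest the coarse onset — because a 3-sample
sustain at 1 kHz is meaningless against autocorrelated gauge noise. On a
noise-free record the refined crossing is the exact one, so the whole
pipeline preserves a monotone link perfectly: the aligned pair has Spearman
r = 1 to machine precision, one of the acceptance checks.

The force is linearly interpolated onto the profile's arc grid over the
overlap (interpolation, not block averaging, matching how the curves are
overlaid in the source workflow), the pre-contact air segment is excluded
(n counts in-bone pairs only), and both channels are min-max normalized.
Dynamic time warping is deliberately out of scope: the physical alignment is
a single rigid shift.

## Statistics

Spearman's r is the Pearson correlation of average ranks (average ranks are
the standard tie treatment; the source is silent on ties). The two-sided p
uses `t = r sqrt((n-2)/(1-r^2))` for n > 9 and full permutation enumeration
for n ≤ 9; the two agree within 0.02 at the crossover, which the tests
assert. Classification uses the Chan-adapted bands on |r| with left-closed
boundaries: poor < 0.3 ≤ fair < 0.6 ≤ moderately strong < 0.8 ≤ very
strong. Significance is fixed at p ≤ 0.01. Grouped tabulation pools by
concatenating per-specimen normalized pairs (pooled n is therefore the sum
of member n, which is what makes the published pair-count subtotals
recomputable); whether pooling should instead renormalize jointly is not
decidable from the source, so concatenation of per-specimen-normalized
series is the default behaviour and the bundled reference table's n sums
confirm it. Pooled correlations can legitimately differ from every member
correlation (Simpson-type behaviour); the tests assert only n-additivity
and determinism for pooling. No multiple-testing correction is applied, by
design.

`specimen_correlations()` ships the 13-row per-specimen reference table
(two donors, thoraco-lumbar levels) used by the tabulation checks; p-values
printed as "< 0.001" are stored as the upper bound 0.001, which is the only
form the p ≤ 0.01 filter ever consumes.

## Numerical choices and degenerate inputs

* Trilinear weights within 1e−9 of 0/1 are snapped, so sampling at voxel
  centers (and whole-voxel translations) is bit-exact.
* `floor(L / ds + 1e-9) + 1` profile steps guard against floating-point
  shortfall (a 29.9 mm path at 0.1 mm gives exactly 300 samples).
* Constant series raise errors ("undefined ranks", "zero range") instead of
  returning NaN; empty masks, undetected canals, missing onsets and
  sub-minimum overlaps are all errors that name the stage.
* All randomness flows from explicit seeds; `run_pipeline()` with the same
  config and seed writes byte-identical results.

## Problem sizes

The test suite and the acceptance script use 128³ phantoms (0.5 mm voxels,
30 HU noise) for the 20-case axis-recovery and registration-recovery
suites, 64³–96³ phantoms for single-case checks, and n = 400 × 50 seeds for
correlation recovery — sizes at which the full suite completes in minutes on
one core while leaving every recovery criterion a comfortable margin.

## A minimal end-to-end example

```{r example, eval = FALSE}
library(drillprofile)

cfg <- pipeline_config(seed = 42, shape = c(96, 96, 96), hu_noise_sd = 20)
run <- run_pipeline(cfg)
run$results

pair <- run$pairs[[1]]
autoplot(pair)               # normalized intensity and force vs arc position
tidy(correlate_pair(pair))   # one-row summary

ref <- specimen_correlations()
count_by_class(ref)          # strength-class tally of the reference table
```

## Known limitations

* Axis-aligned geometry only; oblique DICOM series are rejected.
* Rigid registration only — correct for cadaveric specimens between two
  scans, wrong for anything deformable.
* The simulator's force model is a declared affine link; absolute force
  prediction from HU is explicitly out of scope.
* The DICOM layer covers uncompressed explicit-VR little-endian single-frame
  CT series only.
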