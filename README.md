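# drillprofile

Bone-density profiles along drilled vertebral canals from paired CT, and
their correlation with drilling-force recordings.

## The problem

Trans-pedicular access to a vertebra (pedicle screws, vertebro-/kyphoplasty,
bone biopsy) drills through the cortical shell of the neural arch into the
trabecular body. The axial drilling force at constant feed is a mechanical
probe of the traversed tissue; the pre-interventional CT scan measures the
same tissue as Hounsfield units (HU), a surrogate for bone mineral density.
`drillprofile` quantifies how well the imaging predicts the mechanics: it
reconstructs the drilled canal from the pre/post CT pair, extracts the
density profile along it, aligns the profile with the force recording at the
point of insertion, and reports Spearman/Pearson correlations with a
strength classification — per specimen and pooled by vertebral level, region
(thoracic/lumbar) and donor.

The core quantities, in the field's notation:

* gray values `GV = clamp(HU + 1026, [0, 4096])` profiled at 0.1 mm arc
  steps along a 3.05 mm (11G) cylindrical canal, with a sliding ±0.2 mm
  min/max/mean window;
* force vs displacement `F(x)`, `x = v·t` at `v` = 2 mm/s and 1 kHz
  sampling, aligned to the intensity profile at the insertion onset;
* Spearman `r` (average ranks; exact permutation p for n ≤ 9, t
  approximation above), Pearson `R² = r²`, and the Chan-adapted bands
  |r| < 0.3 poor, 0.3–0.6 fair, 0.6–0.8 moderately strong, ≥ 0.8 very
  strong, with significance at p ≤ 0.01.

The drilled canal itself is estimated from the difference of the rigidly
registered pre/post volumes: threshold at 400 HU, largest 26-connected
component, weighted PCA for the axis, and a half-maximum rule that refines
both endpoints to sub-voxel precision.

Because the original cadaver scans are not deposited, the package includes a
synthetic phantom and force simulator with a recorded ground truth (canal
geometry, rigid misalignment, density→force link, seeds), so that every
pipeline stage is verifiable: axis/endpoint recovery, registration recovery,
shift recovery, and correlation recovery at known population ρ.

## A worked example

Three synthetic specimens, full pipeline (phantom → carve + misalign →
register → difference → axis → profile → GV + window → simulate force →
align → correlate):

```r
library(drillprofile)

cfg <- pipeline_config(seed = 42, shape = c(96, 96, 96), hu_noise_sd = 20,
                       specimens = tibble::tibble(
                         individual = c("A", "A", "B"),
                         region     = c("T", "L", "L"),
                         level      = c("T12", "L3", "L4")))
run <- run_pipeline(cfg)
run$results
#> # A tibble: 11 × 9
#>    group_type      individual region level     n r_spearman        p    R2 class
#>  1 specimen        A          T      T12     257      0.579 2.20e-24 0.741 fair
#>  2 specimen        A          L      L3      224      0.314 1.57e- 6 0.598 fair
#>  3 specimen        B          L      L4      226      0.537 2.75e-18 0.740 fair
#>  4 region          <NA>       T      <NA>    257      0.579 2.20e-24 0.741 fair
#>  5 region          <NA>       L      <NA>    450      0.381 5.02e-17 0.657 fair
#>  ...
#> 11 overall         <NA>       <NA>   <NA>    707      0.498 1.68e-45 0.685 fair
```

Each specimen row is one drilled canal: `n` aligned in-bone pairs (arc step
0.1 mm), the Spearman coefficient between the windowed gray-value maxima and
the force record (here fair, 0.31–0.58, all significant at p ≤ 0.01), and
Pearson's R². Pooled rows concatenate the normalized per-specimen pairs, so
pooled `n` is the sum of member counts. The recovered insertion shifts
(`attr(run$pairs[[i]], "shift_mm")`: 1.60, 1.75, 1.53 mm here) absorb the
drill's air travel before bone contact. `autoplot(run$pairs[[1]])` overlays
the two normalized curves; `autoplot(run$profiles[[1]])` shows the density
profile.

The bundled reference tabulation of 13 cadaveric specimens reproduces the
published strength-class tallies:

```r
ref <- specimen_correlations()
sum(ref$n)            # 4818 aligned pairs in total
count_by_class(ref)
#>   class             count
#> 1 poor                  2
#> 2 fair                  5
#> 3 moderately_strong     5
#> 4 very_strong           0
```

Real data enter through `read_ct_volume()` (NIfTI or DICOM series) and
`read_force_trace()` (CSV with `time_s`, `force_N`), and the same stage
functions apply; `inst/scripts/drillprofile.R` exposes the stages as command
verbs (`phantom`, `register`, `extract`, `align`, `correlate`, `run`).

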