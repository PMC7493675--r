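---
title: "Depth-zoned leukoaraiosis quantification: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-zoned leukoaraiosis quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lazone)
```

## The measurement model

`lazone` quantifies leukoaraiosis (LA) — FLAIR-hyperintense white matter
abnormality — as a percentage of regional white matter volume, in five
regions derived from a tissue/lobe label volume:

* three **depth zones** partitioning white matter: a periventricular band
  (WM within `pv_width_mm` of the ventricle wall), an infracortical band
  (WM within `ic_width_mm` of the cortical gray edge), and deep WM (the
  remainder);
* an **anterior/posterior** split: frontal WM vs parietal + occipital WM
  (temporal WM in neither).

Normalizing each zone's lesion volume by *that zone's* WM volume makes
the statistic a local lesion density: a small band can carry a large
percentage, which is exactly the property that makes depth profiles
informative.

All distances are Euclidean in physical millimetres. The bands are built
by thresholding an exact squared distance transform (separable
lower-envelope algorithm, implemented in C++) at `width²`, so anisotropic
voxels are handled correctly and band membership is a closed ball
(`distance ≤ width`, read from the inclusive "within"). The test suite
verifies the bands against brute-force all-pairs distances on small
grids across isotropic and anisotropic spacings, exactly.

Two widths deserve comment. Both bands default to 5 mm, the operational
zone definitions; the infracortical width is separately configurable
(e.g. 2 mm) because volumetric constructions of the gray–white boundary
band in the literature have used narrower inflations, and the choice is
a genuine degree of freedom rather than something the package should
silently decide. Where the two bands overlap (thin WM), precedence is
configurable and defaults to periventricular-first, matching the
construction order in which ventricle masks are built and subtracted
before the cortical band; `deep = WM − PV − IC` in every case, so the
partition identity `|PV| + |deep| + |IC| = |WM|` holds exactly by
construction and is asserted on every phantom in the tests.

No resampling or registration happens anywhere in the package: all
paired volumes must share a grid (dimensions and spacing), and a
mismatch is a hard error. Co-registration is an upstream concern.

## Segmentation

The segmentation stage reproduces a threshold-macro workflow: each axial
slice is thresholded independently and the 2-D masks are stacked into a
3-D mask. The threshold is

    t = location(reference) + k · scale(reference)

computed over a reference tissue (white matter by default). Defaults and
the reasoning behind them:

* **Robust statistics** (`robust = TRUE`): location/scale are the median
  and 1.4826·MAD rather than mean/SD. The reference region necessarily
  contains the lesions being segmented; at a few percent lesion burden
  the classical moments shift enough to visibly bias the threshold,
  while the median/MAD pair is unaffected. Classical moments remain
  available (`robust = FALSE`).
* **Two-pass slice statistics**: a global pre-pass flags candidate
  lesion voxels, and each slice's statistics are then computed from
  normal-appearing reference tissue only. Without this, a slice whose
  reference is dominated by confluent lesion can raise (or, for the
  median, capture) its own threshold and miss the lesion entirely. A
  slice with no clean reference voxels falls back to the global
  threshold, with a message.
* **`k = 3`** by default — the conventional hyperintensity heuristic.
* **Small-component filter** (`min_component_voxels`, default 0): the
  function default is off, because no minimum LA lesion size is part of
  the measurement definition. The *cohort pipeline* preset
  (`pipeline_seg_params()`) enables it at 5 voxels: resolving an
  infracortical fraction of 0.07 % requires the false-positive floor to
  sit far below that, and at `k = 3` thresholded noise voxels (binomial
  tail ≈ 0.1 % of WM) are overwhelmingly isolated singletons while every
  planted lesion is a compact blob of ≥ 5 voxels. This is a forward
  calculation from the noise model, not a fitted constant.
* **Gaussian pre-smoothing** (`smooth_sigma_mm`, default 0): at high
  noise, voxelwise thresholding of a sparse lesion class cannot reach
  rater-level Dice at any threshold (the false-positive term scales with
  the 98 % of WM that is lesion-free). Smoothing trades boundary
  resolution for a ~10-fold noise reduction and restores Dice ≥ 0.84 at
  a contrast-to-noise ratio of 2 in the tests. It is off by default
  because the default phantom noise does not need it.

Dice agreement between two empty masks is defined as 1 (two empty
segmentations agree perfectly; this avoids 0/0).

## Lacunae and stroke volumetrics

Lacunae are small fluid-filled cavities; radiologically they are dark,
2–15 mm lesions persisting across slices. `detect_lacunae()` operates on
a binary dark-lesion mask: 26-connected components are gated by
*equivalent-sphere diameter* (`d` of the sphere with the component's
voxel volume) in `[2, 15)` mm — the lower gate inclusive, the upper gate
strict — and by an axial slice extent of at least 2 (the "stationary
across slices" rule, configurable). Each retained lacuna is volumetrized
analytically as `(4/3)π(d/2)³` and zone-tagged at its centroid (majority
vote available). The equivalent diameter replaces a radiologist's
caliper measurement with its closest deterministic analogue.

Stroke volume is a caliper formula, not a segmentation:
`correction · d1 · d2 · n_slices · slice_thickness / 1000` mL, with
`correction = 1` as the literal two-diameter product and `0.5` exposed
for the ABC/2 ellipsoid convention. The package deliberately does not
segment strokes from intensities.

## The statistical battery

* `log_screen()`: natural log with offset 1 (admits the zeros that
  stroke and lacunae volumes contain; offset configurable), reporting
  SPSS-convention sample skewness and excess kurtosis and whether both
  lie within ±1.
* `two_sample_t()`: pooled-variance t by default (Welch optional),
  accepting raw vectors or the six summary moments — the two paths are
  algebraically identical, which the tests assert to 10 significant
  digits. Zero variance in both groups with equal means returns t = 0 by
  convention.
* `chi_square_counts()`: Pearson chi-square without continuity
  correction, df = 1.
* `mann_whitney_u()`: rank-sum U with tie-corrected normal p.
* `partial_correlation()`: residual-on-residual Pearson r controlling
  one covariate, p from the t transform with n − 3 df.
* `mixed_ancova()`: two-group × k-level split-plot ANCOVA with a
  subject-constant covariate, following the mainstream repeated-measures
  GLM convention in which the covariate enters both strata: between
  error df `N − 3`, within error df `(k − 1)(N − 3)` (so a 34-subject,
  3-level design reports F(2, 62) and its 2-level analogue F(1, 31)).
  Sums of squares are partial (Type III, sum-to-zero contrasts), effect
  sizes are partial eta squared `SS/(SS + SS_error)`, and sphericity is
  assumed (no correction) — matching how such designs are convention-
  ally reported at k = 3. The implementation is verified against an
  independent projection-matrix oracle and its interaction test is
  calibrated under the null (type-I error within Monte-Carlo bounds of
  0.05 in a 500-replicate simulation).
* `analysis_report()` runs the whole plan on a cohort table: group
  comparisons (t for approximately normal variables, U for ordinal/
  skewed clinical scores, chi-square for sex; volume variables get both
  the raw-moment t of a summary table and the log-screened t of the
  inferential battery), the 2 × 3 depth ANCOVA and 2 × 2
  anterior/posterior ANCOVA covarying TICV, and the four lobe-thickness
  partial correlations with log total LA controlling TICV. No
  multiple-testing adjustment is applied (α = 0.05), matching the
  analysis plan it reproduces.

## The phantom generator: what it emulates, and what it does not

`make_label_volume()` builds the simplest geometry that produces all
three depth zones and four lobes with controllable sizes: an ellipsoidal
brain with a 3 mm cortical ribbon, two ellipsoidal lateral ventricles,
and axis-aligned lobe planes. On the default 64³, 1 mm grid the depth
zones occupy volume shares of white matter of approximately PV 5.4 %,
deep 44.3 %, infracortical 50.3 %. These shares were fixed once, at
design time, by choosing ventricle size and WM shell thickness so that
the preset per-zone group means are mutually consistent with the preset
group totals — with zone fractions `f_z` and shares `w_z`, the total is
`Σ w_z f_z`, and the chosen geometry maps (15.6, 2.1, 0.72) % to ≈ 2.13 %
and (10.8, 0.6, 0.07) % to ≈ 0.88 %, within 2 % of the 2.1 / 0.9 %
targets. The large infracortical share is a genuine property of a small
phantom whose WM shell is thin relative to a 5 mm band, not an error.

Lesions are planted as clipped spheres (radius 1–2.5 mm by default)
wholly inside the requested zone until the zone's voxel count matches
the requested percentage exactly (a residual smaller than one minimum
blob is planted as a final fragment; blobs otherwise keep ≥ 5 voxels so
they survive the pipeline's component filter). Achieved fractions are
recomputed by independent voxel counting and reported as ground truth.

`render_flair()` assigns each tissue its configured mean (CSF 20, WM
100, cortex 115, lesion 160, lacuna 30, arbitrary units) plus iid
Gaussian noise (`noise_sd = 6` by default, i.e. CNR 10 for the
lesion–WM gap of 60 — comfortably separable, as real rater-segmentable
FLAIR lesions are). The phantom deliberately omits MRI physics: no bias
field, no partial voluming, no structured noise, no surface-based
cortical geometry. Passing recovery tests therefore demonstrate the
correctness of the measurement chain, not robustness to scanner
artifacts; on real data the segmentation `k`, smoothing, and component
filter would need tuning against expert masks.

`simulate_cohort()` draws per-subject quantities for a two-group cohort.
The `"af-pilot"` preset encodes the published group structure of a
17 + 17 atrial-fibrillation pilot cohort: zone-load means (PV 15.6/10.8,
deep 2.1/0.6, IC 0.72/0.07 %), TICV means/SDs, demographic and clinical
moments, identical 11:6 sex ratios, and stroke/lacunae presence in the
AF arm only. Design choices:

* **Log-normal subject dispersion** (`zone_cv = 0.8`): LA volumes are
  strongly right-skewed, with published SD/mean ratios near 1; no
  per-subject dispersion of *zone fractions* is published, so the CV is
  a configurable emulation, not a claimed study parameter.
* **Exact moment matching** (`empirical = TRUE`): draws are rescaled so
  each group's sample mean (and, for TICV and clinical columns, SD)
  equals the preset value exactly — the same convention as
  `MASS::mvrnorm(empirical = TRUE)`. With n = 17 and CV ≈ 1, a free
  sample mean has ≈ 24 % sampling error; fixed-seed recovery runs would
  otherwise measure the random number generator rather than the
  pipeline.
* **Thickness model**: lobe cortical thickness is generated with an
  exactly planted TICV-adjusted partial correlation against log total
  LA (temporal −0.37 in the preset, other lobes 0), planted across the
  whole sample because the correlation being emulated is a whole-sample
  quantity. The construction orthogonalizes the noise against the
  LA residual, so the planted coefficient is exact, not approximate.
* **Head-size variation**: each subject's phantom geometry is scaled by
  `(TICV / TICV_ref)^{1/3}`, clamped to ±5 % so the brain stays inside
  the grid.
* **Lacunae** are decomposed into sphere plans (diameters 3–9 mm) and
  voxelized into the phantom as dark lesions, so the detection stage is
  exercised end to end; strokes remain caliper measurements by design.

## Numerical choices and degenerate inputs

* Band membership ties (`distance = width`) are included; with
  integer-representable spacings the squared-distance arithmetic is
  exact, so the oracle-equality tests require bit-identical masks.
* A zero-width band, an empty ventricle, or a zero-semi-axis ventricle
  gives an empty mask; a missing cortical label is an error (the phantom
  is malformed); an empty region denominator is an error rather than a
  NaN percentage.
* Segmentation uses a strict `>` threshold, so a noiseless lesion-free
  volume segments to exactly the empty mask.
* Seeds: every stochastic stage takes an explicit integer seed, derived
  per group and per subject from the run seed; group arms use disjoint
  streams so either arm can be generated alone and is unchanged by the
  other's presence. RNG state is saved and restored around every seeded
  operation.

## Problem sizes used in validation

The shipped validation runs use 64³ phantoms (the scale at which the
zone-share calibration above holds), 17 + 17-subject cohorts, 500
replicates for the ANCOVA null calibration, 200 replicates for
partial-correlation recovery, and ≤ 16³ grids for the exact
distance-oracle comparisons. These sizes keep the whole suite fast while
leaving every statistic deterministic under its seed.

## Known limitations

* The phantom's cortical band is volumetric; no surface mesh, so the
  infracortical band approximates a surface-inflation construction.
* No brainstem or cerebellum: the phantom models forebrain white matter
  only, which is also the scope of the measurement definitions.
* The segmentation is a threshold heuristic, not a learned model; its
  false-positive floor, not its sensitivity, limits how small a zonal
  fraction can be resolved (hence the component filter in the pipeline
  preset).
* Real inferential results from the cohort the preset emulates are not
  reproducible — individual-level data are not public; the package
  reproduces the printed summary-statistic computations and recovers
  planted parameters on synthetic cohorts instead.
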