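# lazone — regional quantification of leukoaraiosis by white matter depth

Leukoaraiosis (LA) — white matter hyperintensity on FLAIR MRI — is a
marker of vascular brain injury whose *location* carries information its
total volume does not: lesions hugging the lateral ventricles, lesions in
the deep white matter housing the long association fasciculi, and lesions
just under the cortical ribbon (where the short U-fibers run) have
different presumed etiologies and clinical correlates. `lazone`
implements a complete, testable pipeline for this regional analysis, for
researchers who have co-registered FLAIR-like intensity volumes and
tissue/lobe label volumes and want per-region LA burdens plus the
accompanying statistical battery.

## What it computes

**Depth zoning.** White matter is partitioned into three a-priori zones
using a spacing-aware Euclidean distance transform (exact
Felzenszwalb–Huttenlocher, anisotropic voxels supported):

- *periventricular*: WM within 5 mm of the lateral ventricle wall
  (ventricle voxels excluded),
- *infracortical*: WM within 5 mm (configurable, e.g. 2 mm) of the
  cortical gray matter edge,
- *deep*: the remainder, `deep = WM − PV − IC`.

The three masks are pairwise disjoint and exactly exhaustive over WM.
An anterior (frontal WM) vs posterior (parietal + occipital WM) partition
is derived from the lobe labels; temporal WM belongs to neither.

**Segmentation.** LA is segmented by per-axial-slice intensity
thresholding against reference-tissue statistics
(`threshold = location + k · scale`, robust median/MAD by default, with a
global two-pass guard against lesion contamination of slice statistics),
stacked to 3-D, with optional Gaussian pre-smoothing and small-component
filtering. Mask agreement is scored with the Dice similarity coefficient
`2|A∩B|/(|A|+|B|)`.

**Volumetrics.** Each region's LA burden is reported as a percentage of
that region's WM volume:

    LA_region % = 100 · vol(LA ∩ region) / vol(region)

Lacunae are detected in a dark-lesion mask as 26-connected components
with equivalent-sphere diameter in the lacunar gate `[2, 15)` mm spanning
at least 2 axial slices; each is volumetrized as `(4/3)π(d/2)³` and
tagged with its depth zone. Stroke volumes use the two-diameter rule
`d1 · d2 · slices · thickness` (mm³ → mL; ABC/2 correction available).

**Statistics.** Log-transform screening (skewness/kurtosis within ±1),
pooled/Welch t-tests (from raw vectors or printed summary moments),
Pearson chi-square, Mann–Whitney U, TICV-adjusted partial correlations,
and the group × region mixed-design ANCOVA with a between-subject
covariate and partial eta squared — the repeated-measures GLM convention
with the covariate in both strata, i.e. error df `(k−1)(N−3)` within and
`N−3` between.

**Phantoms.** Because real cohorts of this kind are small and rarely
shared, the package ships a synthetic generator: ellipsoidal brain
phantoms with a cortical ribbon, two lateral ventricles, lobar WM
compartments, lesions planted to target per-zone percentages, lacunar
spheres, FLAIR-like rendering with Gaussian noise, and a two-group cohort
simulator (the `"af-pilot"` preset: 17 atrial-fibrillation vs 17 non-AF
subjects with group-mean zone loads PV 15.6/10.8 %, deep 2.1/0.6 %,
infracortical 0.72/0.07 %). Everything is seeded and byte-reproducible.

## Worked example

```r
library(lazone)

spec <- phantom_spec(zone_targets = c(pv = 15.6, deep = 2.1, ic = 0.72),
                     noise_sd = 6, seed = 42)
ph  <- make_phantom(spec)
seg <- segment_la(ph$flair, ph$labels, pipeline_seg_params())
dice(seg, ph$truth$lesion_mask)
#> [1] 0.9961816
la_profile(seg, ph$zones)
#> LA profile: total 2.149% | PV 15.676% | deep 2.117% | IC 0.733%
#>   anterior 0.970% | posterior 2.898% | LA 1183 mm^3 of WM 55048 mm^3
```

The planted loads (15.6 / 2.1 / 0.72 %) are recovered within ~1.5 % after
segmentation under noise. A full two-arm cohort with the statistical
battery:

```r
co  <- run_cohort(cohort_preset("af-pilot"), seed = 1)
print(co)
#> la_cohort: 34 subjects (AF 17 + non-AF 17), seed 1
#>   group total_pct pv_pct deep_pct  ic_pct
#>      AF     2.122   15.5    2.087 0.7194
#>  non-AF     0.886   10.8    0.603 0.0698
rep <- analysis_report(co$table)
```

`run_pipeline()` writes the cohort TSV, JSON/text reports, NIfTI masks,
and a provenance file; `inst/cli/lazone.R` exposes the stages as shell
subcommands (`phantom`, `segment`, `zones`, `metrics`, `analyze`, `run`).

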