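---
title: "Quantifying motor tract strength and testing confounding of the cCRST–walking association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying motor tract strength and testing confounding of the cCRST-walking association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tractconfound)
```

## The scientific question

After a stroke, the descending motor tracts of the lesioned hemisphere —
the corticospinal tract (CST) and the corticoreticulospinal tract (CRST)
— lose axonal projection strength, while the homologous tracts of the
contralesional hemisphere often strengthen. Whether that contralesional
CRST (cCRST) upregulation helps or harms walking has been debated: in
cross-sectional data, people with stronger cCRST tend to walk *worse*.
The hypothesis this package operationalizes is that the negative
association is confounded: greater ipsilesional damage causes both
greater compensatory cCRST upregulation and worse walking, so
conditioning on ipsilesional motor tract strength should remove the
association if cCRST upregulation has no direct harmful effect.

The package implements the full measurement-and-inference chain:

1. **Normalization** (`normalize_qa`). Voxel-wise quantitative
   anisotropy (QA) is divided by the mean QA inside a ventricular CSF
   mask from the same scan. CSF signal varies with acquisition, not
   pathology, so any multiplicative scanner gain cancels exactly; the
   result is denoted nQA.
2. **Skeleton projection** (`project_to_skeleton`). Each voxel of a
   one-voxel-thick white-matter skeleton receives the maximum nQA over
   white-matter voxels within a Chebyshev search radius, re-centring
   each participant's bundle cores onto the template skeleton and
   absorbing residual rigid misalignment.
3. **Tract measurement** (`tract_mean_nqa`, `global_wm_nqa`). Tract
   strength is the streamline-count-weighted mean of skeletonized nQA
   over the internal-capsule slab, z in [-5, 12] mm of standard space;
   the global covariate is the unweighted skeleton mean.
4. **Adjustment and standardization** (`fit_reference`,
   `adjust_tract_nqa`, `composite_corticomotor`, `tract_zscore`). On
   controls only, tract nQA (averaged over left/right) is regressed on
   global nQA; each participant's tract value is then shifted to the
   control-average global level,
   `adjusted = unadjusted − slope · (global − control_global_mean)`.
   Composite corticomotor strength is the normative-volume-weighted
   average of the adjusted CRST and CST values. Everything is z-scored
   against control means and SDs. Laterality is assigned by lesion side,
   and each control inherits its matched stroke partner's side.
5. **Inference** (`group_compare`, `fit_linear`, `assess_confounding`,
   `cooks_influence`, `loo_sensitivity`, `min_detectable_effect`).
   Stroke-control comparisons use independent t-tests; the confounding
   test compares `6MWD ~ cCRST` with `6MWD ~ cCRST + iCorticomotor` and
   declares confounding when the cCRST coefficient shrinks by strictly
   more than 10%. Model stability is probed with Cook's distance against
   the median-F threshold and leave-one-out refits.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| slab bounds | [-5, 12], inclusive | mm (voxel centres) | internal capsule; endpoints included because the region is quoted as a closed range |
| search radius | 2 | voxels | covers the ±1-voxel rigid misalignment the phantom generates, with margin |
| shrinkage threshold | 0.10 (strict >) | fraction | conventional change-in-estimate cut-off |
| t-test variant | pooled variance | — | matches the two-group linear-model contrast that produces "model estimate [95% CI]" tables; Welch available |
| influence threshold | median F(p, n−p) | — | p counts the intercept: only that convention gives F(3, 17) = 0.821 for a two-predictor model at n = 20 |
| alpha / power | 0.05 two-sided / 0.80 | — | design defaults |

## The synthetic-data generator

Participant-level MRI and clinical data of the kind this pipeline
analyzes are not openly distributable, so the package ships a generator
(`make_templates`, `make_participant_volume`, `make_cohort`,
`make_tabular_cohort`) whose **defaults are the study conditions**: 10
stroke/control pairs, a latent ipsilesional deficit `D` of 11.25 ± 3.4
control SDs, cCRST upregulation slope `delta_upreg = 0.12` z per deficit
unit, walking slope `gamma_walk = 34` m per corticomotor SD with a 537 m
intercept and 90 m noise, and a *zero* direct cCRST→walking effect
(`beta_direct = 0`) — the confounded-null scenario. These values are
derived from the published group summaries (6MWD 537 ± 77 m controls vs
156 ± 147 m stroke; composite corticomotor z −11.25; upregulation slope
−0.12); with them the generator's expected unadjusted cCRST coefficient
is ≈ −70 m per SD, matching the scale of the published estimate.

Design choices worth knowing:

* **Geometry.** Bundles are straight vertical tubes with Gaussian
  in-plane streamline profiles (CRST medial and smaller, CST lateral and
  larger), a one-voxel core line as skeleton, plus a uniform background
  white-matter box carrying a one-voxel skeleton sheet, and a
  ventricular CSF box. Simplicity is deliberate: every downstream number
  (core value, background value, slab mean, global mean) is exactly
  predictable, so pipeline tests can assert equality rather than
  similarity.
* **Planted regression structure.** Each participant draws a latent
  global nQA `g`; tract values are `mean + slope·(g − 2.658) + noise`
  with slopes 1.186 (CRST) and 2.702 (CST). The background level is
  back-solved so the *measured* skeleton mean equals `g` exactly, which
  makes slope recovery a clean errors-in-response problem. The
  between-participant global SD (0.18) is the closed-form value that
  puts the control tract-vs-global r² near 0.74/0.89 given the tract
  noise SDs (0.18/0.24), because the slope fit averages left/right and
  halves the noise variance.
* **Damage and upregulation.** Stroke ipsilesional tract deviations are
  `−0.60·D` (CRST) and `−0.88·D` (CST) in tract-SD units; contralesional
  CRST is `delta_upreg·D` plus noise (SD 1.5), contralesional CST uses
  an internal rate of `2.1·delta_upreg`. These ratios reproduce the
  published per-tract deficit/upregulation pattern relative to the
  composite.
* **Phantom nuisances.** Scanner gain is purely multiplicative and
  applied to everything including CSF (so normalization removes it
  bit-exactly); misalignment is an integer-voxel rigid shift (default
  ±1) so projection can undo it exactly; lesions are zeroed *before*
  gain and noise, mimicking tissue loss; additive voxel noise is
  truncated at zero to keep QA non-negative. The CSF box keeps an
  interior margin from the volume faces so shifts never drag edge fill
  into the mask.
* **Controls' walking** is intercept + noise only, with no dependence on
  their (normal-range) tract values; the stroke walking model is
  `537 + 34·iCM_z + beta_direct·cCRST_z + noise`, truncated at 0 m. The
  truncation is a deliberate departure from pure linearity; it touches
  ~15% of draws at the default (severe-deficit) settings, so
  linear-recovery checks of `gamma_walk` are run at milder settings
  where truncation never binds.
* **Reproducibility.** One master seed; each participant gets a derived
  substream keyed by its pair index, so cohorts are identical across the
  volume and tabular paths and stable under reordering.

What the generator does **not** emulate: anatomy (curved bundles,
crossing fibres, gyral geometry), registration error beyond rigid
integer shifts, partial-volume and distortion effects, lesion-induced
registration failure, or any raw diffusion signal (QA is generated
directly). Passing tests therefore validate the *arithmetic and
inference chain*, not robustness to realistic registration or
segmentation failure.

## Numerical choices and degenerate inputs

* Off-skeleton voxels after projection carry `NA`, an explicit no-data
  sentinel — never 0, which would bias means. All downstream means
  ignore `NA`.
* Slab membership is decided on voxel-centre z coordinates, read from
  the volume header (z origin + slice index × voxel size).
* Projection restricted to white matter; lesioned voxels are excluded
  from the search so necrotic tissue cannot be "rescued" — projection
  corrects misalignment, not damage. The local-maximum projection is
  idempotent on smooth bundle profiles (tested); on noisy input a second
  projection can only increase values, so it is applied once.
* The normative tract volume is the count of voxels with streamline
  count > 0 over the *whole* tract, not the slab.
* `fit_reference` refuses fewer than 3 controls, zero-variance global
  nQA, and adjusted values with (numerically) zero spread. The published
  constants are available as `reference_preset()` for worked examples
  and for scoring new data against the original control cohort, but are
  never a silent default. The preset documents a discrepancy in the
  published constants themselves: the z-score denominators (0.357,
  0.272, 0.718, 0.534) differ from the tabulated control SDs (0.14,
  0.22, 0.24, 0.24); this package always computes SDs from the supplied
  control data and carries both sets in the preset.
* Degenerate group comparisons (zero pooled variance) return p = 1 for
  identical groups and p = 0 otherwise instead of failing.
* Shrinkage uses absolute coefficients; a sign flip that grows the
  coefficient gives negative shrinkage, reported but never flagged. A
  numerically zero unadjusted coefficient is an error (shrinkage
  undefined).
* `min_detectable_effect` root-finds exact noncentral-t power for the t
  families; correlation power uses the Fisher z transform with the
  `r/(2(n−1))` bias correction applied to the effect size (the critical
  value is uncorrected) — the variant that reproduces the classic
  r = 0.58 target at n = 20. No multiple-testing correction is applied
  anywhere, matching the analysis this models.

## Problem sizes

The test suite and acceptance script use: 48³-voxel volumes at 2 mm for
all phantom work (one full 20-participant pipeline run takes a few
seconds), 200-control cohorts for slope recovery, 200 replicate
10-pair cohorts for the change-in-estimate behaviour, and 500-pair
cohorts for convergence checks (partial correlation, parameter
recovery). These sizes were chosen so each check's sampling error is
small relative to the effect it verifies.

## Known limitations

* The skeleton search is a Chebyshev-ball local maximum, not the
  perpendicular distance-map search of TBSS; with real, curved anatomy
  the two can differ near bundle junctions.
* The generator's causal structure is linear-Gaussian (with the
  documented truncations); it cannot probe robustness to nonlinear
  damage-upregulation relationships.
* The change-in-estimate rule is a diagnostic, not a causal estimator;
  with `beta_direct ≠ 0` the adjusted coefficient estimates the direct
  effect only under the generator's (no unmeasured confounding)
  assumptions.
* Published participant-level results (the fitted −72.17 m/SD
  coefficient, the 1.45 Cook's distance, the −2.56 → 18.59 leave-one-out
  change) depend on data available only on request; the package
  reproduces the *procedures* and the desk-scale constants, and shows
  the same qualitative behaviour on synthetic cohorts generated at the
  study conditions.

## A minimal run

```{r, eval = FALSE}
cfg <- run_config(cohort = cohort_params(n_pairs = 10, seed = 4))
report <- run_pipeline(cfg, "run4")
report$confounding
```

The report holds the fitted reference model, group comparisons, the
upregulation regression, the confounding assessment, and the influence
report; all tables are also written as CSV/JSON with a provenance
record.
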