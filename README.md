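# tractconfound

Motor tract strength quantification and confounding analysis for stroke
diffusion MRI.

## The problem

After stroke, descending motor tracts on the lesioned side — the
corticospinal tract (CST) and corticoreticulospinal tract (CRST) — lose
axonal projection strength, while their contralesional homologues often
strengthen. People with stronger contralesional CRST (cCRST) tend to
walk worse, which has been read as evidence that cCRST upregulation is
maladaptive. `tractconfound` implements the measurement pipeline and the
statistical test of the alternative explanation: ipsilesional damage
drives *both* cCRST upregulation and poor walking, so the negative
association is confounded.

The package is aimed at neuroimaging researchers who want a tested,
reusable implementation of the tract-strength metric and the
change-in-estimate confounding analysis, together with a synthetic
phantom/cohort generator that reproduces the statistical structure of
such a study, so every stage can be validated without access to
participant-level data.

## The model

For participant *i* and tract *t*, with voxel-wise quantitative
anisotropy QA:

- **nQA**: QA divided by the mean QA in ventricular CSF of the same scan
  (removes scanner gain exactly).
- **Skeleton projection**: each white-matter skeleton voxel takes the
  maximum nQA within a Chebyshev radius (default 2 voxels), absorbing
  residual misalignment.
- **Tract strength**: streamline-count-weighted mean of skeletonized nQA
  over the internal-capsule slab, z ∈ [−5, 12] mm.
- **Global adjustment** (control-fitted slope β_t, control global mean ḡ):

      adjusted_t(i) = unadjusted_t(i) − β_t · (global(i) − ḡ)

- **Composite corticomotor strength**: normative-volume-weighted average
  of the adjusted CRST and CST values.
- **z-scores**: (adjusted − control mean) / control SD, per tract role
  (iCRST, cCRST, iCST, cCST, iCorticomotor, cCorticomotor), with
  laterality assigned by lesion side (controls inherit their matched
  partner's side).
- **Confounding test**: comparing `6MWD ~ cCRST` against
  `6MWD ~ cCRST + iCorticomotor`; confounding is declared when the cCRST
  coefficient shrinks by strictly more than 10%. Stability is probed
  with Cook's distance against the median F(p, n−p) threshold and
  leave-one-out refits; design sensitivity with exact noncentral-t /
  Fisher-z minimum detectable effects.

## Worked example

Generate a 10-pair cohort at the default study conditions (planted
direct cCRST→walking effect of zero) and test for confounding:

```r
library(tractconfound)

tab <- make_tabular_cohort(cohort_params(n_pairs = 10, seed = 4))
ca <- assess_confounding(tab$six_mwd_m, tab$ccrst_z, tab$icm_z, ids = tab$id)
ca
#> exposure coefficient: -67.64 unadjusted -> -0.7067 adjusted
#> shrinkage 99.0% (threshold 10%): confounded

ca$model_unadjusted
#> OLS fit: n = 20, 2 coefficients
#>         term estimate    se      t         p
#>  (Intercept)   378.95 40.53  9.349 2.489e-08
#>     exposure   -67.64 23.61 -2.865 1.029e-02
#> Residual SE 177 on 18 df; R-squared 0.3132 (adj 0.2751)
#> F = 8.21 on 1 and 18 df, p = 0.01029

cooks_influence(ca$model_adjusted)
#> Cook's distance threshold: median F(3, 17) = 0.821
#> max Cook's distance 0.265; 0 observation(s) flagged
```

Read: stronger cCRST predicts walking ~68 m worse per control SD
(p = 0.01) — yet the cohort was generated with **no** direct effect.
Adding ipsilesional corticomotor strength collapses the coefficient to
≈ 0 (99% shrinkage), correctly exposing the association as confounding
by ipsilesional damage. No observation exceeds the 0.821 influence
threshold.

The same analysis can be run end-to-end from synthetic QA volumes
(painting, CSF normalization, skeleton projection, tract measurement,
reference fitting, statistics):

```r
report <- run_pipeline(run_config(seed = 4), "run4")
report$confounding$confounded
#> [1] TRUE
```

Design sensitivity at the study size:

```r
min_detectable_effect("between_t", n = 10)    # Cohen's d = 1.32
min_detectable_effect("within_t", n = 10)     # Cohen's d = 1.00
min_detectable_effect("correlation", n = 20)  # r = 0.58
```

A thin command-line front end is installed at
`inst/scripts/tractconfound-cli.R`
(`run`, `simulate`, `quantify`, `stats`, `power` subcommands).

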