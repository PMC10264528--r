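# nsnct — quantitative CT analysis of nonsolid pulmonary nodules

Persistent nonsolid nodules (NSNs, pure ground-glass nodules) on chest CT
are usually indolent, but a minority grow and become invasive
adenocarcinomas. `nsnct` implements a 2D software-based quantification
pipeline for predicting that growth from baseline thin-section CT, for
radiologists and imaging researchers who want a fully scripted, testable
version of the workflow:

* **Segmentation** — polygonal ROI + fixed-threshold segmentation
  (HU ≥ −800, inclusive) on the largest cross-section, largest
  8-connected component, interior holes filled.
* **Twelve features** — Feret diameter (mean of max/min calipers on the
  pixel-corner hull), perimeter (smoothed marching-squares contour),
  area, mean/median/modal/SD attenuation, linear mass density
  `LMD = area · (mean HU + 1000) / 1000` (mg/mm), histogram skewness and
  excess kurtosis (population moments), circularity `4πA/P²`, solidity
  (area / convex-hull area).
* **Growth scoring** — mass doubling time on LMD under the exponential
  model `DT = Δt · ln 2 / ln(LMD₂/LMD₁)`; growing iff `DT < 1556` days;
  baseline risk flags at skewness > 0.90 and LMD > 19.16 mg/mm.
* **Statistics** — ICC(A,1) reliability, Spearman correlation with DT,
  Mann–Whitney contrasts (exact for pooled n ≤ 12), univariate +
  backward-stepwise logistic regression, ROC/AUC with Youden-optimal
  cutoffs (AUC ≡ U/(n₁n₀), ties included).
* **Synthetic CT** — seeded generator of nodule slices (shifted-gamma
  interior attenuation with exact moment control), baseline/follow-up
  pairs realizing a configured LMD growth factor, and whole cohorts with
  known group structure, so everything is testable without patient data.

Images come in as single-frame DICOM or TSV rasters with a JSON sidecar
(both carry pixel spacing and rescale calibration); ROIs as vertex text
files; reports as CSV + markdown. A thin CLI (`exec/nsnct`) exposes
`simulate`, `segment`, `features`, `growth`, `nodule`, `cohort-stats`,
`report`.

## Worked example

Render a growing ground-glass nodule, its follow-up 1,100 days later at
a true doubling time of 900 days, and push both through the pipeline:

```r
library(nsnct)

spec <- nodule_spec(equivalent_diameter = 12, attenuation_mean = -600,
                    attenuation_sd = 150, attenuation_skewness = 1.12,
                    seed = 42)
base <- render_nodule(spec, pixel_spacing = 0.5)
fu   <- render_followup(base, growth_scenario(900, 1100, "+"))

roi1 <- matrix(TRUE, nrow(base$image), ncol(base$image))
roi2 <- matrix(TRUE, nrow(fu$nodule$image), ncol(fu$nodule$image))
run_nodule(base$image, fu$nodule$image, roi1, roi2, interval_days = 1100)
#> <nodule_record> DT 889 d (growing), baseline skewness 1.04, LMD 45.08 mg/mm, risk flag: highest
```

The estimated doubling time (889 d) recovers the configured truth
(900 d) within ~1%; the nodule is labelled growing (DT < 1556) and
flagged `highest` risk because baseline skewness exceeds 0.90 *and*
baseline LMD exceeds 19.16 mg/mm.

Cohort level — simulate 500 nodules with the default calibration
(growing prevalence 19/60, skewness and LMD as the group-separating
drivers) and run the statistics chain:

```r
co  <- simulate_cohort(cohort_config(n_nodules = 500, seed = 1))
run_cohort(co)
#> <cohort_report> 500 nodules (158 growing)
#> selected predictors: lmd, skewness
#>   ROC skewness  AUC 0.882, Youden cutoff 0.8256
#>   ROC lmd       AUC 0.828, Youden cutoff 18.51
#>   ROC model     AUC 0.910, Youden cutoff 0.3707
```

Backward-stepwise elimination recovers exactly the two features the
generator uses as growth drivers; the skewness-model AUC (0.882) and
Youden cutoff (0.83) agree with the configuration's analytic values
(`implied_separation()` gives AUC 0.878, boundary 0.886). Per-feature
correlation, group-contrast and logistic tables plus ROC point files are
written as CSV/markdown when `out_dir` is supplied.

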