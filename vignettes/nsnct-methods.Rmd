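---
title: "Quantitative CT analysis of nonsolid pulmonary nodules: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative CT analysis of nonsolid pulmonary nodules: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsnct)
```

## The problem

Persistent nonsolid nodules (NSNs, also called pure ground-glass nodules)
are hazy pulmonary opacities on thin-section CT with no solid component.
Most are indolent — they can sit unchanged for many years — but a minority
grow and progress to invasive adenocarcinoma. Separating the two groups
*at baseline*, before growth is visible, is the clinical question this
package addresses computationally: segment the nodule on its largest
axial cross-section, measure twelve densitometric and shape features,
score growth between two scans as a mass doubling time, and relate
baseline features to the growth outcome with a standard statistical
chain.

Because no patient imaging ships with the package, a synthetic CT
generator produces single slices, baseline/follow-up pairs and whole
cohorts with known ground truth; every pipeline stage is exercised and
tested against that ground truth or against brute-force oracles.

## Segmentation

The nodule is outlined with a polygonal ROI and thresholded at a fixed
attenuation value:

* **Coordinates** are 0-based `(row, col)` with pixel centers at integer
  coordinates; pixel `(i, j)` occupies `[i - 0.5, i + 0.5] x [j - 0.5,
  j + 0.5]`. Stated once here, used everywhere.
* **Rasterization**: a pixel belongs to the ROI iff its center is inside
  the polygon under the even-odd rule; centers exactly on the boundary
  are included. Self-intersecting polygons are rejected.
* **Threshold**: pixels with HU `>= -800` (inclusive) inside the ROI are
  foreground. The threshold value separates ground-glass tissue from
  aerated parenchyma (about -900 HU); inclusivity is a fixed convention
  chosen for bit-reproducibility.
* **Post-processing**: 8-connected components are labelled (run-based
  two-pass algorithm), the largest is kept (ties toward the component
  whose first pixel comes first in column-major order, logged), and
  interior holes — regions of background not 4-connected to the image
  border — are filled. Low-attenuation pixels inside a ground-glass core
  are part of the lesion; hence hole filling. Both conventions are
  arguments of `threshold_segment()`.

An empty result at threshold raises an error carrying the ROI's HU range,
which the pipeline converts into a structured segmentation-failure record.

## The twelve features

For a mask $M$ of $N$ pixels with spacing $(s_r, s_c)$ mm and interior
attenuations $x_1, \dots, x_N$:

1. **Feret diameter** — mean of the maximum and minimum caliper
   diameters. Both are computed on the convex hull of the *corner* points
   of all mask pixels, so a single pixel has max $\sqrt 2$ and min 1
   pixel rather than zero. The maximum is the largest hull-vertex
   distance; the minimum is the smallest width over hull-edge normal
   directions (the rotating-calipers optimum). Tests compare both against
   brute force over all corner pairs and a dense projection grid.
2. **Perimeter** — length of the outer boundary contour, see below.
3. **Area** — $N \, s_r s_c$ mm².
4.–7. **Mean / median / modal / SD of attenuation** — arithmetic mean;
   midpoint-interpolated median; mode on integer-HU bins with ties broken
   toward the lowest HU (non-integer inputs are rounded for the mode
   only); sample SD ($n-1$ denominator), undefined-flagged for a single
   pixel.
8. **Linear mass density (LMD)** — $\mathrm{LMD} = A\,(\bar x + 1000) /
   1000$ in mg/mm: the mass per unit slice thickness, taking air
   (-1000 HU) as zero mass and water as 1 mg/mm³. It is the 2D analogue
   of nodule mass and the quantity growth is scored on.
9.–10. **Skewness / kurtosis** — population-moment estimators
   $m_3/m_2^{3/2}$ and $m_4/m_2^2 - 3$ with $m_k = \frac1N \sum (x_i -
   \bar x)^k$. Kurtosis is *excess* (Gaussian gives 0): cohort kurtosis
   summaries that straddle zero are only consistent with the excess
   convention. Zero-variance regions are flagged rather than returning
   NaN.
11. **Circularity** — $4\pi A / P^2$, clamped to 1 with a message when
   digitization pushes it above.
12. **Solidity** — $A$ divided by the area of the pixel-corner convex
   hull; 1 for convex, indentation-free shapes.

### The perimeter convention

The boundary is traced as the marching-squares 0.5-level contour between
foreground and background (`grDevices::contourLines`). The raw polyline
is exactly hand-checkable — a single pixel is a diamond of length
$2\sqrt2$, a 2×2 block gives $4 + 2\sqrt2$ — but it systematically
overestimates the length of smooth shapes: integrating the staircase
geometry over all boundary orientations gives an asymptotic factor
$\frac{4}{\pi}(2\sqrt2 - 2) \approx 1.055$ for a disk, i.e. circularity
$\approx 0.90$ no matter how large the disk. Since circularity must
converge to 1 for digital disks to be interpretable, the default
convention applies a circular moving average (window 5 vertices) to the
contour before measuring: disk circularity is then 0.99 across radii
20–200 px while corners of genuinely angular shapes are only locally
rounded. The raw polyline (`method = "raw_contour"`) and the classical
pixel-edge count (`method = "pixel_edge"`) remain available; all
perimeter-dependent quantities state which convention produced them.

## Growth scoring

Growth is quantified by matching the LMD of the baseline and last
follow-up scans under the exponential (Schwartz) model:

$$DT = \Delta t \cdot \frac{\ln 2}{\ln(\mathrm{LMD}_2 / \mathrm{LMD}_1)}$$

A nonpositive LMD change maps to $DT = \infty$ (no positive variation),
never a negative doubling time. A nodule is **growing** iff its DT is
strictly below the 1,556-day cutoff; $DT = 1556$ exactly is nongrowing
(the two complementary definitions "< cutoff" growing / ">= cutoff"
nongrowing force strictness). Baseline risk flags use the published
operating points: skewness > 0.90 flags high risk, escalating to highest
when LMD > 19.16 mg/mm; all four constants live in `run_config()` and are
asserted in a dedicated test.

## The synthetic CT generator

`render_nodule()` emulates a 1-mm lung-window slice:

* **Background parenchyma**: i.i.d. Gaussian, default $-900 \pm 50$ HU —
  aerated lung at the noise level of a sharp reconstruction kernel.
* **Shape**: an ellipse of configurable equivalent diameter (default
  validation range 6–30 mm, the axial size band of the nodules this
  pipeline targets) and aspect ratio, optionally modulated by random
  low-order radial harmonics (`fourier_blob`) whose amplitude is the
  `boundary_irregularity` parameter; rising irregularity measurably
  lowers circularity and solidity.
* **Interior attenuation law**: a shifted gamma solved in closed form
  from the requested (mean, SD, skewness): shape $k = 4/\gamma^2$, scale
  $\theta = \sigma\gamma/2$, location $\mu - k\theta$. Ground-glass
  histograms are right-skewed, and the gamma family gives exact
  closed-form control of the first three moments. Requested skewness 0
  falls back to a symmetric Gaussian; negative skewness is rejected with
  an error naming the constraint. By default the sample mean and SD of
  the interior draw are pinned exactly by an affine correction
  (`moment_match`), which leaves skewness and kurtosis untouched and
  makes the LMD of a rendered nodule deterministic up to rasterization.
* **Compositing**: per-pixel maximum of background and nodule, so the
  nodule is never darker than parenchyma and is separable at -800 HU.
  Consequence: when the gamma's lower tail reaches down into the
  parenchyma range the tail is censored upward; the moment-recovery test
  therefore uses a spec whose support stays clear of the background
  (mean -500, SD 100), and ground truth always reports the moments of
  the *rendered* pixels.
* **Partial volume**: a one-pixel linear blend band at the boundary
  (`edge_blend`, on by default) stresses threshold segmentation the way
  real edge voxels do; it can be switched off for tests that isolate the
  attenuation law.

`render_followup()` realizes a growth scenario exactly: the configured
LMD factor $2^{\Delta t / DT}$ is split geometrically between the area
channel and the mass-per-area channel ($\bar x + 1000$), default 50/50,
because real growth couples size and density and either channel alone is
a degenerate test case. Follow-ups that would push the mean above
-200 HU (no longer nonsolid) or below -800 HU (below the segmentation
threshold) are refused with a diagnostic. The doubling-time recovery test
closes the loop: render, segment, extract, score — the true DT is
recovered within 5% for DT up to 3,000 days.

### Cohort simulation

`simulate_cohort()` draws a growing/nongrowing label per nodule (default
prevalence 19/60) and then generates features around a deliberate causal
structure: **skewness and LMD are drivers**, drawn exactly from their
configured group-conditional laws (normal and log-normal respectively,
parameterized by median and IQR; Gaussian copula correlation 0.3 between
their latents). Every other feature is a noisy correlate regressed on
the standardized drivers and is *conditionally independent of the group
given them*; the regression weight is calibrated so each feature's
per-group medians converge to the configured targets. This mirrors the
substantive finding the package is built around — histogram asymmetry
and slice mass carry the growth signal; size and shape features are
correlated surrogates — and it makes backward-stepwise selection a
genuine parameter-recovery exercise (the truth is "skewness + LMD").

Two modelling consequences are accepted and documented rather than
hidden. First, the within-group spread of the correlate features is
wider than their configured IQRs, because they inherit the driver
variance on top of their idiosyncratic noise; medians are exact, IQRs
approximate. Second, an alternative generator drawing all twelve
features independently from their group margins was rejected: with
twelve independently informative predictors the full logistic model
quasi-separates and stepwise elimination becomes arbitrary, which is
both unrealistic (real nodule features are strongly collinear) and
useless as a recovery test.

Covariates (age, sex, smoking, cancer history, emphysema, lobe) follow
the reference cohort's prevalences and are independent of the outcome by
default. True doubling times are log-uniform on [250, cutoff) for
growing nodules; nongrowing nodules are stable (infinite DT, probability
0.3) or log-uniform on [cutoff, 6·cutoff]; scan intervals are log-normal
with median 1,136 days and quartiles matching 748–1,818. These scales
reproduce the reference cohort's reported interval and DT summaries to
first order and are held fixed.

What the generator does **not** emulate: spatial texture and
autocorrelation inside the nodule (pixels are i.i.d. given the law),
scanner physics beyond a linear partial-volume band, vessels or bronchi
crossing the lesion, the deterministic identities among real features
(a simulated cohort's LMD column is drawn, not computed from its area
and mean columns), and 3D structure. Passing tests therefore certify
the measurement and statistics chain, not performance on real CT.

## The statistics chain

* **Reliability**: two-way single-measurement ICC, default the
  absolute-agreement form
  $\mathrm{ICC}(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)}$,
  with the consistency form `C1` available. Zero between-nodule variance
  is flagged degenerate. `simulate_repeat_measurement()` generates
  second readings whose noise variance is solved from a target ICC.
* **Spearman correlation**: average ranks under ties, two-sided p from
  the t approximation on $n-2$ df. Infinite doubling times of stable
  nodules are legitimate inputs because only ranks enter.
* **Mann–Whitney U**: rank-sum U with average ranks; exact two-sided p
  by complete enumeration of group assignments when $n_a + n_b \le 12$
  (valid under ties), otherwise the normal approximation with tie and
  continuity corrections.
* **Logistic regression**: maximum likelihood by IRLS (`stats::glm`),
  Wald z p-values, odds ratios $e^\beta$. Complete or quasi-complete
  separation is detected (fitted probabilities numerically 0/1 or
  vanishing deviance) and flagged instead of silently reporting huge
  odds ratios.
* **Backward stepwise**: candidates enter after univariate screening at
  p < 0.05; the largest-p predictor is dropped while its Wald p exceeds
  0.10, refitting until stable; the elimination trace is kept. The
  removal threshold 0.10 is the common backward-elimination default;
  both thresholds are configurable. Note that with ~18 screened
  candidates an all-noise design still admits about one false entry on
  average ($18 \times 0.05$) — the attainable null property is "few
  spurious predictors", not "none", and that is what is tested.
* **ROC**: candidate cutoffs are midpoints between consecutive distinct
  scores (a case is positive when its score exceeds the cutoff, matching
  the "greater than cutoff" reading of the published operating points);
  the AUC is computed from ranks, so the identity AUC $= U/(n_1 n_0)$
  holds exactly, ties included, and is asserted against an $O(n^2)$
  pair-counting oracle. The optimal cutoff maximizes Youden's
  $J = \mathrm{sens} + \mathrm{spec} - 1$, ties toward the lower cutoff;
  a cost-ratio criterion can be layered on the returned curve. Scores
  for the combined model are fitted logistic probabilities.

`implied_separation()` converts a cohort configuration into its analytic
binormal AUC and Youden boundary for any feature — the calibration
target the simulated-cohort tests compare against, rather than any
number measured after the fact.

## Problem sizes and tolerances

The test suite uses: moment recovery on ~1.1·10⁴ interior pixels (3 MC
SEs, with the skewness-estimator SE ≈ 0.038 measured at that n);
LMD-factor realization at 0.35 mm spacing (< 2%, rasterization only);
doubling-time recovery at 0.5 mm spacing for DT 600–3,000 days (< 5%);
logistic recovery at n = 5,000 (3 SEs); cohort recovery at n = 500 over
20 seeds (driver retention in ≥ 90% of seeds, mean AUC within 3 MC SEs
of the analytic target, mean Youden cutoff within 0.1 of the analytic
boundary); Feret oracles on 50 random blobs (max exact; min within the
first-order discretization error of a 1,800-direction grid). These sizes
are the package's choices for a fast, deterministic suite; all scale up
by changing one constant per test.

## Known limitations

2D only (largest cross-section, as in the underlying measurement
protocol); no interactive ROI drawing; DICOM support is limited to
single-frame uncompressed little-endian transfer syntaxes with the
rescale/spacing attributes honored; the synthetic cohort's correlate
features match group medians but not IQRs exactly; covariate-outcome
associations (e.g. age, emphysema) are not simulated by default, so the
pipeline's covariate handling is exercised only under the null.
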