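---
title: "Classifying uric acid urinary stones from single-energy CT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying uric acid urinary stones from single-energy CT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakstone)
```

## The clinical problem

Uric acid (UA) urinary stones can be dissolved in vivo by urine
alkalization, while calcium-based (non-UA) stones cannot, so telling the
two apart at the time of the first CT scan changes patient management.
In vivo composition analysis is usually done with dual-energy CT, which
has limited availability in emergency settings. `peakstone` implements a
purely quantitative workflow that predicts UA versus non-UA composition
from the routine non-enhanced *single-energy* CT scan.

## The feature pair: maxHU and ppLapl

Two point estimates are read from each stone:

* **maxHU** — the attenuation (HU) of the single highest-attenuating
  voxel inside the stone.
* **ppLapl** (peak point Laplacian) — the value of a scaled Laplacian
  filtered image at that same voxel. With normalised neighbour weights
  this equals maxHU minus the weighted mean of the 26 surrounding voxels
  in 3D, i.e. a local peakedness measure.

Both are point estimates at a single voxel, so they are essentially
independent of how the stone is segmented — only the identity of the
brightest voxel matters. The physical rationale: a small calcium stone
and a large UA stone can share the same peak attenuation, but the
attenuation drop from the peak to the surrounding voxels is generally
much larger in the calcium stone (dense crystalline core), so the
(maxHU, ppLapl) pair separates the classes better than either feature
alone.

### The Laplacian kernel

The filter is `value(v) - sum(w_n * value(n))` over the 26 neighbours of
the 3×3×3 stencil, with replicate padding at the volume border. The exact
neighbour weighting behind the original measurements is not public, so
two schemes are provided and documented as assumptions:

* `"inverse-distance"` (default): weights 1, 1/√2, 1/√3 for face, edge
  and corner neighbours (voxel units), normalised to sum 1. This is the
  standard 27-point discrete Laplacian family.
* `"uniform"`: all 26 neighbours equal.

Neither is claimed to be bit-identical to the original software; both
satisfy the defining identity "peak minus weighted neighbour mean" and
the published worked examples are cutoff decisions, which are robust to
the choice. The stencil is defined in voxel units on the 1 mm isotropic
axial reformat the method was developed for; anisotropic spacing triggers
a warning and `resample_isotropic()` offers trilinear resampling.

## The three classifiers

* **Rigid cutoffs (`classify_cutoff`)** — non-UA iff maxHU ≥ 1000 HU *or*
  ppLapl ≥ 195 HU; the UA region is the rectangle [0, 1000) × [0, 195).
  Stones exactly on a cutoff line classify non-UA, following the
  published decision rule verbatim.
* **maxHU only (`classify_maxhu`)** — UA iff maxHU < 745 HU (strict).
* **kNN (`classify_knn`)** — majority vote among the k = 9 nearest
  training stones in the raw (maxHU, ppLapl) plane under Euclidean
  distance. Both features are in HU, so raw distances are meaningful and
  standardization defaults to off (a flag enables z-scoring for
  sensitivity analysis). k is required to be odd, so a binary vote cannot
  tie; distance ties at the k-th rank are broken by training-point order,
  making predictions deterministic. `classify_knn(..., vote = TRUE)`
  returns the UA vote fraction, the natural score for ROC analysis.

The annotated 126-stone dataset behind the original kNN model is not
public. The package therefore ships a loader for user-supplied training
CSVs and a surrogate training-set generator (below); results obtained
with the surrogate are statements about the method, not about the
original fitted model.

## Evaluation statistics

`cross_tabulate` builds the 2×2 confusion matrix with UA as the positive
class, excluding stones whose reference label is `mixed` (20–80% UA
fraction; no reliable reference standard exists for them, and predictors
are never allowed to output `mixed`). `diagnostic_metrics` computes
sensitivity, specificity and accuracy with exact Clopper–Pearson
intervals obtained by beta-quantile inversion; raw proportions are kept
internally and integer-percent rounding (half up) happens only at the
reporting layer. `mcnemar_exact` is the exact two-sided binomial test on
the discordant pairs (mid-p and continuity-corrected chi-square variants
are options; the published paired p-value itself is not reproducible
because per-stone pairing is not printed). `roc_auc` is the midrank
Mann–Whitney statistic, equivalent to trapezoidal integration over all
thresholds; for the maxHU method the score orientation is reversed
(lower attenuation is more UA-like).

A reproduction note: from the printed cross-tabulation counts the
package reproduces all nine published point estimates and 19 of the 21
published interval bounds exactly. Two printed bounds (the 18/18
sensitivity lower bound of 82% and the 121/124 accuracy upper bound of
100% in the one-stone-per-patient subgroup) are inconsistent with every
standard binomial interval — the exact interval gives 81% and 99% — and
appear to be source typos; the corresponding test expectations are left
failing deliberately rather than special-cased.

## The synthetic phantom generator

No images are distributed with the method, so the package carries a
first-class simulation module that renders stones with known ground
truth. It is designed so that the *extracted* features of a simulated
cohort follow the published group distributions of the reference data.

**Geometry.** A near-equant ellipsoid (semi-axes 0.9, 1, 0.95 times half
the largest axial diameter — renal calculi are roundish) embedded in a
soft-tissue background of 30 HU. Diameters are drawn per class from the
reference size distributions (UA 7.3 ± 4.1 mm, non-UA 6.3 ± 2.5 mm,
truncated to the 3–20 mm inclusion range).

**Imaging model.** The imaged field is rendered analytically at voxel
centres rather than by discretely convolving a sampled profile, which
would alias sub-voxel cores. The total smoothing combines the
reconstruction point-spread function (default sigma 0.4 mm, about 1 mm
FWHM, consistent with a 0.6 mm detector acquisition reformatted at 1 mm)
with the voxel aperture (variance spacing²/12 per axis), giving an
effective sigma of about 0.49 mm at 1 mm voxels. The blurred stone
boundary follows an erf edge model on the signed surface distance; this
edge partial volume is what keeps the noisy attenuation peak interior to
the stone, as in real scans. Uncorrelated Gaussian noise (default SD
30 HU, typical of a 1 mm abdominal reformat) is added last; every
realization is fixed by a seed.

**Composition profiles.** UA stones are flat at their target plateau
attenuation (drawn from the reference UA maxHU distribution, 537 ± 155 HU
on [223, 794]); their measured ppLapl arises from noise-extreme selection
(≈ 100–130 HU, matching the reference UA ppLapl of 122 ± 39) and, for
stones under about 4 mm, from edge partial volume — reproducing the
clinically observed failure mode where only the smallest UA stones cross
the 195 HU cutoff. Non-UA stones draw a target (maxHU, ppLapl) pair from
a truncated bivariate normal with the reference moments (maxHU 1286 ±
292 on [536, 1796]; ppLapl 282 ± 96 on [51, 546]; within-class
correlation 0.6, a value chosen once on the grounds that both features
grow with mineral density), and the width of an imaged Gaussian core
that realises that ppLapl contrast at the drawn peak is solved per stone
by inverting the 26-neighbour kernel response. The core sits on a
plateau at half the peak attenuation (`edge_fraction = 0.5`). The
intrinsic pre-blur core implied by the closed-form quadrature relation
is sharper and denser than the imaged one, as micro-CT of calcium stones
shows.

**What the generator does not emulate.** Beam hardening, streak
artifacts, spatially correlated noise, non-ellipsoidal and laminated
stone morphologies, and the true empirical joint feature distribution
beyond its first two moments and ranges. Measured features also carry a
small positive bias relative to their targets because the peak voxel is
the maximum of a noisy field. Consequently, passing simulation tests
demonstrates that the pipeline and classifiers behave correctly on data
*statistically similar* to the reference cohort; it does not re-validate
the clinical accuracy figures. On simulated cohorts of 37 UA + 106
non-UA stones the rigid-cutoff classifier recovers about 92–95% of
compositions (the bivariate normal model is intrinsically less separable
than the real scatter, in which almost all low-attenuation calcium
stones still show high peak contrast), and the kNN and maxHU AUCs come
out near 0.98–0.99.

## Numerical and design choices

* **Peak ties** break to the lexicographically smallest (slice, row, col)
  index; a peak on the volume border is legal but flagged, since
  replicate padding distorts its neighbourhood.
* **Segmentation** is seeded 26-connected region growing at a 130 HU
  threshold (well below any stone, above soft tissue), clipped to a
  40 mm cube centred on the seed; a component touching the clip boundary
  is flagged as possibly truncated. The result is independent of the
  seed voxel within a component, up to the clip window.
* **Size** is the automated analogue of the manual axial caliper: per
  axial slice, the maximum pairwise distance between member-voxel
  footprints (centres extended by the projected half-voxel at each end),
  maximised over slices. A single voxel at 1 mm spacing measures 1 mm.
* **Indices**: in-memory objects use R's native 1-based indices; all CSV
  output writes 0-based voxel indices (documented per writer), matching
  the convention of the surrounding imaging toolchains.
* **Problem sizes** in the test-suite and acceptance script — cohorts of
  143 stones, five replicate seeds, 200-point surrogate training sets,
  10,000-draw moment checks — were chosen as the smallest sizes at which
  the checked statistics are stable to well within their tolerances.
* **Truncated sampling** is by rejection, with a guard against
  degenerate truncation regions; an infeasible specification (range not
  containing the mean, or empty) is rejected at construction.

## Known limitations

* The original Laplacian weighting and any mask-restriction of the
  neighbour mean are unknown; this implementation uses the full-volume
  neighbourhood and documents both weight schemes as assumptions.
* The kNN decision surface depends on the training set; with the
  surrogate generator it approximates, but is not identical to, the
  original published model.
* The paired McNemar p-value and the confidence interval of the accuracy
  difference reported for the clinical cohort require unpublished
  per-stone pairing and are deliberately out of scope.
* Mixed-composition stones are excluded, never predicted: the method is
  strictly binary UA / non-UA.
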