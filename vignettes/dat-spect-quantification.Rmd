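---
title: "Quantifying striatal DAT SPECT: methods and design notes"
author: "DATspect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying striatal DAT SPECT: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DATspect)
```

## The problem

Dopamine transporter (DAT) SPECT with ⁹⁹ᵐTc-TRODAT-1 images the density of
presynaptic dopamine transporters. The striatum carries by far the highest
DAT density, so it appears as two hot foci in an otherwise moderately
counting brain, and striatal uptake falls as Parkinson's disease (PD)
progresses. The classical analysis draws regions of interest over the
striatum and a reference region and reports an uptake ratio; that approach
is operator-dependent and ignores the rest of the volume. `DATspect`
implements the alternative this package is built around: describe the
*whole-brain count histogram* with shape statistics, measure the *striatal
activity volume* by 3D region growing, and feed both kinds of features into
three-group stage classifiers (healthy; mild, Hoehn–Yahr 1–3; severe,
Hoehn–Yahr 4–5) with a complete validity panel.

## Segmentation

**Whole-brain mask.** A single count threshold separates head from
background. The default is 15 counts — in this acquisition regime the
background just outside the scalp stays below that level — and inclusion is
strict (`count > 15`). The threshold applies to raw reconstructed counts;
if your volumes are rescaled, scale the threshold with them
(`pipelineConfig(threshold = ...)`).

**Striatal region.** Seed region growing from a seed voxel, joining any
connected voxel with `count ≥ f × seed count`. Three choices deserve
comment:

* *Seed localization.* The seed is the global count maximum inside the
  whole-brain mask. In DAT imaging the striatum is reliably the hottest
  structure, so this automates the operator's "maximum count within the
  axial section of the striatum". `findSeed()` accepts an explicit seed or
  an axial `sliceRange` restriction for pathological cases (e.g. tracer
  pooling artifacts). Ties are broken by the lexicographically smallest
  (i, j, k) index so results never depend on memory layout.
* *Inclusion rule.* The growth stopping rule is a genuinely open design
  point: we use the relative half-maximum rule `f = 0.5` because the
  50%-of-maximum isocontour is the standard nuclear-medicine volumetric
  convention, and expose `includeFraction` and an optional `absoluteFloor`
  for sensitivity analyses. The rule uses non-strict `≥` so boundary
  voxels are kept (the whole-brain threshold, by contrast, is strict).
* *Connectivity.* Default 26 (full 3D neighbourhood); 6 is available for
  comparison. The grown set is the exact connected component of the seed
  under the rule, independent of traversal order — the test suite checks
  it against an independently written breadth-first flood fill.

**Bilaterality.** Striatal uptake is bilateral, but at the half-maximum
level the two striata may or may not merge into one connected component
(they do when blur bridges the midline gap, and need not otherwise).
`growStriatum()` therefore grows a second region from the hottest voxel
outside the primary region and unions it in, but only when that secondary
seed reaches 70% of the primary seed count (`secondaryRatio`) — a cortical
maximum never qualifies, a contralateral striatum essentially always does.
Explicit left/right separation is out of scope.

## Features

Let \(x_i\) be the count of voxel \(i\) in the whole-brain sample,
\(\bar x\), \(Md\), \(SD\) its mean, median and standard deviation
(sample, \(n-1\), denominator throughout, matching the printed \(n-1\)
factors of the defining formulas), and \(d_i = x_i - \bar x\):

* **SK** \(= \dfrac{\sum d_i^3/(n-1)}{(\sum d_i^2/(n-1))^{3/2}}\)
* **KUR** \(= \dfrac{\sum d_i^4/(n-1)}{(\sum d_i^2/(n-1))^{2}}\), minus 3
  when `excess = TRUE`
* **CSK** \(= (n_{below} - n_{above})/n_{total}\), bounded in \([-1, 1]\)
* **MES** \(= 3(\bar x - Md)/SD\), bounded in \([-3, 3]\)
* **DTAV** \(= \sum_{\text{slices}} (\text{member area} \times
  \text{slice thickness})\), reported in mL; algebraically the member-voxel
  count times the voxel volume
* **DTAM**: the maximum count inside the grown region (default), or the
  largest single-slice volume (`mode = "max_slice_volume"`)

Two conventions are deliberately configurable because the field's usage is
inconsistent:

* *Kurtosis.* Reported group values in the staging literature (healthy
  ≈ 5, severe ≈ 2.7, discussed against the normal benchmark of 3) are on
  the **non-excess** scale even when the formula is printed with a "−3".
  The package defaults to non-excess and exposes `kurtosisExcess`.
* *DTAM units.* The area-based definition would make DTAM a volume, yet
  reported values (hundreds) are clearly peak counts. The default is
  `max_count`; the literal slice-volume formula remains available.

Degenerate inputs fail loudly rather than silently: constant samples make
the moment ratios and MES undefined (error), empty regions make DTAV/DTAM
undefined (error), and an over-aggressive threshold that empties the brain
mask raises an error naming the threshold. CSK handles ties at the mean by
counting them in neither \(n_{below}\) nor \(n_{above}\) while keeping
them in \(n_{total}\) — the only reading under which the formula is
well-defined for every input. Medians of even-sized samples are the
midpoint of the two central order statistics.

## Group statistics

Descriptives use a t-based 95% CI, \(\bar x \pm t_{0.975,\,n-1}\,
SD/\sqrt n\); with healthy groups as small as n = 6 a z interval would be
badly anticonservative. Group comparisons are rank-based throughout
(count-derived features are not plausibly normal): Mann–Whitney U and
Kruskal–Wallis with tie correction — counts tie heavily — and Dunn's post
hoc z tests with the pooled tie-corrected standard error,

\[ z_{ij} = \frac{\bar R_i - \bar R_j}
   {\sqrt{\Big(\frac{N(N+1)}{12} - \frac{\sum_t (t^3-t)}{12(N-1)}\Big)
   \Big(\frac{1}{n_i}+\frac{1}{n_j}\Big)}}, \]

with two-sided p-values Bonferroni-multiplied by the number of pairs and
capped at 1 (reported tables in this literature print capped values like
0.999). The normal approximation is used without continuity correction so
that the two-group Kruskal–Wallis and Mann–Whitney p-values coincide
exactly; exact small-sample p-values are a non-goal.

## Classification

The cohort is split once into halves (ceiling(n/2) train, floor(n/2)
test) — the percentage-split validation strategy — stratified by stage by
default since the allocation protocol in the source studies is unstated.
Five predictor groups are modelled: SK, KUR, FAV = {DTAV},
FAD = {SK, KUR} and FADV = {SK, KUR, DTAV}.

* **LR** is multinomial logistic regression (the softmax generalization of
  \(P(X) = e^{f(x)}/(1+e^{f(x)})\), \(f(x) = \beta_0 + \beta_1 x_1 +
  \dots\)), fitted unstandardized with an intercept. Near-complete
  separation (diverging coefficients) triggers a refit with a small ridge
  penalty and a logged note.
* **SVM** is a one-vs-one RBF-kernel machine with C = 1 and, on features
  standardized by the training mean and SD, γ = 1/d (i.e. 1/(d·variance)) —
  conventional defaults standing in for unstated tool settings.
  Per-class scores for AUC are aggregated pairwise decision values, which
  keeps prediction fully deterministic (Platt probability calibration uses
  an internal random cross-validation and is avoided).

The validity panel reports per-class one-vs-rest sensitivity, specificity,
PPV and NPV plus their prevalence-weighted averages, accuracy, macro
one-vs-rest AUC via the rank (Mann–Whitney) formulation, and Cohen's kappa
\((p_o - p_e)/(1 - p_e)\). The averaging convention had to be chosen here:
published three-class tables in this area report single
sensitivity/specificity values without defining the reduction, and their
internal inconsistencies (e.g. NPV = 1.000 alongside specificity = 0.500)
cannot be reconciled with any standard averaging — so the per-class
breakdown is always kept alongside the weighted averages. Classes absent
from a test half get NA one-vs-rest metrics and are excluded from the
averages with a warning. A degenerate confusion matrix concentrated in one
cell has \(p_e = 1\); kappa is defined as 0 there, with a warning.

## The phantom

The generator exists so that every downstream stage is testable without
patient data. It emulates:

* an ellipsoidal brain (semi-axes 70 × 85 × 60 mm) sampled on a
  128 × 128 × 64 grid at 3.9 mm isotropic spacing (the acquisition matrix
  of the emulated scanner; the physical spacing of the source scans is
  never stated, so the default is a documented assumption);
* a **graded cortical background** (plateau 200 counts falling 30% toward
  the rim) over a dimmer deep interior (60 counts, inner 55% of the brain
  semi-axes) in which the striata sit. The gradient is the one departure
  from a strictly piecewise-constant model: with flat compartments the
  whole-brain histogram is too bimodal to reproduce the reported
  stage-dependent shape pattern, while the graded shell yields unimodal
  histograms with a hot striatal tail whose balance shifts with stage —
  right-skewed and strongly leptokurtic for healthy subjects through
  left-skewed and flatter for severe PD;
* two **bilateral striatal ellipsoids** per stage, elongated
  anterior–posteriorly, 4 mm apart at the midline, with analytic pair
  volumes ≈ 34 / 16 / 10 mL and peaks 450 / 465 / 450 counts for
  healthy / mild / severe;
* per-subject biological variability as lognormal jitter (CV 4% on
  striatal size and peak, 5% on global intensity), **Gaussian
  reconstruction blur** (σ = 4 mm ≈ 9.4 mm FWHM, emulating filtered back
  projection resolution without implementing it), and **Poisson counting
  noise** drawn around the blurred intensity.

Defaults were calibrated once so that simulated cohort feature means fall
in the qualitative reported pattern (SK sign flipping from healthy to
severe, KUR and DTAV decreasing with stage) and then frozen; exact
patient-table values are expressly *not* targets. The `separation`
parameter interpolates the stage-specific striatal geometry toward its
across-stage mean: `separation = 0` removes all stage information and is
used as the negative control.

What the phantom does **not** emulate — and hence what passing tests do not
show about real data: anatomical striatal shape (the comma of
caudate+putamen), asymmetric or unilateral disease, attenuation and
scatter, reconstruction artifacts and correlated noise (Poisson noise here
is independent per voxel, whereas filtered back projection correlates it),
patient motion, and the overlap of real stage distributions. Real cohorts
separate far less cleanly than the default phantom; the classifier
accuracies reached on simulated cohorts characterize the pipeline, not
clinical performance.

## Numerical choices and problem sizes

Seeds are explicit everywhere (subject seeds are drawn reproducibly from a
master seed; fixed seed ⇒ bit-identical volumes) and the split and model
grid are deterministic given their seed. Blur is applied as a separable,
row-normalized Gaussian so flat fields keep their level at the volume
edges. Feature-formula agreement with naive oracles is asserted to 1e−9
relative tolerance; mask and flood-fill equivalences are exact.

The test suite and the acceptance script run the phantom at the full
default grid; cohort-level checks use 30 subjects per stage, which is
ample for the orderings and classifier recovery they assert (the whole
suite runs in about two minutes). The acceptance script additionally
reports a zero-separation control, whose accuracy should sit near the
majority-class rate of the test half.

## Known limitations

* The half-maximum growth rule measures the blurred object; for structures
  small relative to the resolution (severe-stage striata approach this)
  partial-volume effects bias DTAV and the noisy seed maximum biases the
  threshold slightly upward. The ±15% agreement asserted against the
  analytic phantom volume reflects that bias budget.
* DICOM/PACS ingestion, attenuation/scatter correction and image
  registration are out of scope; NIfTI-1 is the only on-disk format.
* The statistics stage offers no exact permutation p-values.
* Hyperparameter search and cross-validation beyond the single percentage
  split are non-goals; C and γ defaults are conventional, not tuned.
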