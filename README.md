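# DATspect

Quantification and stage classification of dopamine transporter (DAT) SPECT
brain imaging for Parkinson's disease (PD).

In ⁹⁹ᵐTc-TRODAT-1 SPECT the tracer binds the dopamine transporter on
presynaptic striatal neurons, so the striatum is the hottest structure in
the reconstructed count volume and its uptake falls as PD progresses.
`DATspect` implements a whole-volume, histogram-based alternative to the
classic striatal uptake-ratio analysis:

1. **Whole-brain segmentation** — a single count threshold (default 15;
   inclusion is strict, `count > 15`) separates the brain from background.
2. **Striatal segmentation** — 3D seed region growing from the hottest
   brain voxel, joining neighbours with
   `count ≥ f × seed count` (default `f = 0.5`, the half-maximum
   isocontour; 26-connectivity), with a second pass for the contralateral
   striatum.
3. **Six features per subject** —

   | Feature | Definition | Region |
   |---|---|---|
   | SK  | skewness `(Σd³/(n−1)) / (Σd²/(n−1))^{3/2}`, `d = xᵢ − x̄` | whole brain |
   | KUR | kurtosis `(Σd⁴/(n−1)) / (Σd²/(n−1))²` (non-excess by default) | whole brain |
   | CSK | Cyhelsky's skewness `(n_below − n_above)/n_total` | whole brain |
   | MES | Pearson's median skewness `3(x̄ − Md)/SD` | whole brain |
   | DTAV | DAT activity volume: Σ slice area × slice thickness (mL) | grown region |
   | DTAM | DAT activity maximum (peak count in the grown region) | grown region |

4. **Group statistics** — per-stage descriptives with t-based 95% CIs,
   Mann–Whitney U, tie-corrected Kruskal–Wallis, and Dunn–Bonferroni post
   hoc comparisons across the three stages (healthy, mild = HYS 1–3,
   severe = HYS 4–5).
5. **Classification** — multinomial logistic regression and RBF-kernel SVM
   on five predictor groups (SK, KUR, FAV = {DTAV}, FAD = {SK, KUR},
   FADV = {SK, KUR, DTAV}) over a stratified 50/50 percentage split, each
   scored with a full validity panel: sensitivity, specificity, PPV, NPV,
   accuracy, one-vs-rest AUC and Cohen's kappa.

Because clinical DAT scans are rarely shareable, the package ships a
**digital striatal phantom**: an ellipsoidal brain with a graded cortical
background and two bilateral striatal ellipsoids whose volume and peak
depend on stage, plus Gaussian reconstruction blur and Poisson counting
noise. Every stage of the pipeline is exercised end-to-end on simulated
cohorts; see the methods vignette (`vignettes/dat-spect-quantification.Rmd`)
for the model, its calibration and its limitations.

## Worked example

```r
library(DATspect)

params <- phantomParams()                       # default study conditions
cohort <- generateCohort(c(6, 10, 10), params, seed = 11)
ff     <- featureFrame(extractFeatures(cohort))

aggregate(cbind(SK, KUR, DTAV) ~ stage, ff, function(x) round(mean(x), 2))
#>     stage    SK  KUR  DTAV
#> 1 healthy  0.77 7.05 33.26
#> 2    mild  0.03 4.17 14.09
#> 3  severe -0.27 2.79  9.89

kruskalWallis(split(ff$DTAV, ff$stage))
#> $statistic 21.88782   $df 2   $p_value 1.766523e-05

dunnBonferroni(split(ff$DTAV, ff$stage))
#>    group1 group2        z      p_value   p_adjusted
#>   healthy   mild 2.025825 4.278272e-02 1.283481e-01
#>   healthy severe 4.558106 5.161689e-06 1.548507e-05
#>      mild severe 2.924027 3.455352e-03 1.036606e-02
```

The feature means recover the expected stage structure: the healthy
whole-brain histogram is right-skewed and strongly leptokurtic while the
severe one is left-skewed and flatter, and the striatal activity volume
falls from ~33 mL (healthy) through ~14 mL (mild) to ~10 mL (severe). The
Kruskal–Wallis test rejects equality of DTAV across stages; Dunn–Bonferroni
localizes the differences to the severe contrasts (the healthy group is
small, n = 6, so its pairwise test against mild does not reach 0.05).

Classification on a larger cohort:

```r
ff   <- featureFrame(extractFeatures(generateCohort(c(30, 30, 30), params, seed = 42)))
grid <- runModelGrid(ff, seed = 7)
grid$SVM.FADV
#> ValidityReport: SVM / FADV
#>   sensitivity 0.978  specificity 0.989  PPV 0.979  NPV 0.989
#>   accuracy 0.978  AUC 0.993  kappa 0.967
```

A command-line wrapper with `simulate`, `extract`, `stats`, `classify` and
`run-all` subcommands is installed at
`system.file("scripts", "datspect.R", package = "DATspect")`.

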