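# gdeeg — task-based occipital EEG biomarkers of Gaming Disorder

`gdeeg` is an R package plus a scripted analysis workflow for studies
that contrast Gaming Disorder (GD) and healthy-control (HC) subjects
using two-channel occipital EEG (O1/O2 at 256 Hz) recorded during a
visual task. It is aimed at researchers who want the entire chain —
cohort simulation, preprocessing, band decomposition, feature
extraction, effect screening, and subject-independent classification —
as tested, reproducible code rather than a collection of ad-hoc scripts.

Because task-EEG datasets of this kind are rarely deposited, the package
ships a first-class synthetic cohort generator that emulates the study
design (15 GD / 15 HC, 600 s per subject, band-structured oscillations
with injected "spectral slowing": elevated Delta/Theta/Alpha power,
raised Delta variability, reduced Beta power, altered Gamma entropy,
plus mains noise, drift and sporadic high-amplitude artifacts). Every
downstream stage is tested against it.

## What it computes

* **Preprocessing** — zero-phase 4th-order Butterworth band-limiting
  (0.5–50 Hz) with a 50 Hz IIR notch before the final low-pass; 20 s
  boundary trims (600 s → 560 s analyzable); rejection of 10-s epochs in
  which either channel exceeds ±100 µV (with ±75/±125 µV sensitivity
  analyses) and exact retention accounting with Welch group comparisons.
* **Band decomposition** — 6-level periodized orthonormal db4 DWT;
  band-limited reconstructions Delta 0–4, Theta 4–8, Alpha 8–16 (dyadic
  realization of 8–15), Beta 16–32, Gamma from D2 restricted to
  30–45 Hz; Welch-PSD purity validation.
* **Features** — per channel × band: absolute/relative power
  (`P_abs = mean(x²)`, `P_rel = P_band / ΣP`), temporal moments, Hjorth
  Activity/Mobility/Complexity (`Activity = var(x)`,
  `Mobility = √(var(x′)/var(x))`, `Complexity = Mobility(x′)/Mobility(x)`),
  Shannon entropy `H = −Σ pᵢ log₂ pᵢ` of the amplitude histogram,
  normalized spectral entropy, peak frequency, Theta/Alpha–Theta/Beta–
  Beta/Alpha PSD ratios and O1+O2 composites; concatenated or
  segment-wise (10-s) aggregation — 156 features per subject.
* **Group statistics** — Welch's t (summary-statistic or raw-sample
  form), pooled-SD Cohen's d signed GD − HC, Benjamini–Hochberg FDR
  across the feature family, Spearman label correlations.
* **LOSO evaluation** — leave-one-subject-out cross-validation with all
  transforms (z-scoring, Spearman pruning at |ρ| > 0.9, ANOVA-F top-8
  selection) fitted per fold on training subjects only; five classifiers
  (depth-3 Gini decision tree, 100-tree random forest, k = 5 KNN, RBF
  SVM with C = 1, 16-unit ReLU MLP); accuracy k/n with Wilson 95 %
  intervals and correctness SD/SEM; directional misclassification
  tables; and a LOSO-preserving permutation test,
  `p = (1 + #{acc_perm ≥ acc_obs}) / (B + 1)`.

## Worked example

```r
library(gdeeg)

cohort <- simulate_cohort(n_per_group = 8, effect = default_gd_effect(),
                          artifact_spec = artifact_spec(),
                          duration = 180, seed = 1)
pp <- preprocess_cohort(cohort)
rep1 <- pp$reports[[1]]
cat(sprintf("subject %s: %.0f of %.0f s retained (%.1f%% rejected)\n",
            rep1$subject_id, rep1$retained_s, rep1$analyzed_s, rep1$rejected_pct))
#> subject GD01: 120 of 140 s retained (14.3% rejected)

fm <- build_feature_matrix(pp$clean)
et <- effect_table(fm)
head(et[, c("feature", "mean_GD", "mean_HC", "p", "cohens_d")], 3)
#>   feature                mean_GD mean_HC       p cohens_d
#> 1 O1_Alpha_Mobility        0.312   0.316 0.00163    -1.96
#> 2 O1_Alpha_Complexity      1.57    1.55  0.00250     1.87
#> 3 O2_Gamma_PeakFrequency  35.7    33    0.00467      1.79

res <- permutation_test(fm, model_spec("decision_tree", seed = 1),
                        B = 500, seed = 1)
res
#> <loso_result> decision_tree: accuracy 0.688 (11/16), Wilson 95% [0.44, 0.86], SEM 0.116
#>   permutation p = 0.2016 (B = 500)
```

The first block reports per-subject retention after filtering, trimming
and ±100 µV epoch rejection. The effect table ranks features by |d|; at
this reduced size (8/group, 180 s) the strongest contrasts are large but
the decision tree does not separate the groups significantly (p = 0.20)
— an expected small-sample outcome. At the full study scale the picture
sharpens: running the staged workflow

```sh
Rscript analysis/01_simulate_and_screen.R   # cohort, retention, threshold sensitivity
Rscript analysis/02_features.R              # band purity + feature matrices
Rscript analysis/03_group_stats.R           # effect screening, correlations, RF importance
Rscript analysis/04_evaluate.R              # LOSO x 5 models + permutation tests
```

writes its tables under `results/` and, at the default master seed
(n = 15/group, 600 s), prints slow-wave features at the top of the
effect ranking (O1_Delta_Kurtosis d = 1.39, O1_Theta_Min d = −1.26) and

```
decision_tree: accuracy 0.800 (24/30), Wilson 95% [0.63, 0.90], SEM 0.073
  permutation p = 0.0340 (B = 1000)
random_forest: accuracy 0.900 (27/30)
knn:           accuracy 0.700 (21/30), permutation p = 0.0470
svm_rbf:       accuracy 0.767 (23/30)
mlp:           accuracy 0.733 (22/30)
```

i.e. interpretable tree-based rules recover the injected contrast with
subject-independent accuracy well above the permutation null.

## Repository layout

```
R/                  package code (generator, preprocessing, DWT, features,
                    statistics, LOSO/permutation, EDF & delimited I/O)
analysis/           numbered workflow drivers writing tables to results/
scripts/acceptance.R  headline-quantity recomputation (JSON)
tests/testthat/     unit, property and acceptance suites
vignettes/          methods vignette (model, parameters, design choices)
```
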