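---
title: "Methods: task-based occipital EEG biomarkers of Gaming Disorder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: task-based occipital EEG biomarkers of Gaming Disorder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and model of the data

`gdeeg` implements a complete analysis pipeline for two-channel occipital
EEG (O1/O2, 256 Hz) studies contrasting Gaming Disorder (GD) subjects with
healthy controls (HC) during a visual task. Because raw recordings of this
kind are typically not publicly deposited, the package treats the cohort
generator as a first-class, tested module: every downstream stage
(preprocessing, wavelet band decomposition, feature extraction, group
statistics, leave-one-subject-out classification) is exercised against
synthetic cohorts whose statistical structure matches what the analysis
assumes about real task EEG.

A simulated recording is the sum of:

* five band-limited oscillatory processes — Delta (0–4 Hz), Theta (4–8),
  Alpha (8–15), Beta (15–30), Gamma (30–45) — each a unit-RMS core scaled
  by the band's `mean_amp` (µV RMS) and by a slow (≤ 0.1 Hz) log-normal
  envelope whose coefficient of variation is `amp_cv`;
* a slow sinusoidal electrode drift, a 50 Hz mains component, and
  Poisson-timed high-amplitude raised-cosine transients (~0.25 s);
* O2 as a correlated copy of O1: band envelopes are fully shared, band
  innovations are mixed with correlation 0.6, so the inter-channel
  correlation is positive but below 1.

The `entropy_knob` of each band interpolates the width of the occupied
sub-band from a pure centre-frequency tone (0) to noise filling the whole
band (1). We chose bandwidth interpolation rather than tone/noise
amplitude mixing because the analysis constrains only band power and
entropy-type contrasts, not waveform shape, and a single bandwidth
parameter gives a monotone, easily calibrated handle on spectral flatness.

### Default study conditions

The defaults encode the emulated design: 15 subjects per group, 600 s
recordings at 256 Hz, alpha-dominant occipital amplitudes (Delta 8, Theta
6, Alpha 10, Beta 4, Gamma 2 µV RMS; `amp_cv` 0.3). No published value
pins the absolute amplitude scale beyond the ±100 µV rejection bound, so
amplitudes are conventional occipital magnitudes chosen to sit well inside
that bound while injected transients (180 µV, 0.7/min) sit clearly above
it; at these rates roughly 10–15 % of 10-s epochs are rejected, a
realistic dry-electrode artifact burden.

Between-subject variability has two components, both drawn from streams
derived from the master seed:

* log-normal band-amplitude jitter with CV 0.25 (a realistic
  between-subject spread of band power, and the denominator that the
  effect-size calibration works against);
* additive N(0, 0.05) jitter on each band's entropy knob. Without this,
  any group shift of a shape feature (entropy, Hjorth complexity, peak
  frequency) is near-deterministic and produces absurd effect sizes
  (|d| > 3); with it, shape contrasts have realistic sampling behaviour.

All subject-level jitters are drawn from single sequential streams rather
than one short stream per subject: short streams seeded from an arithmetic
sequence measurably violated group exchangeability (a systematic null
effect of |d| ≈ 0.13), which single-stream draws eliminate.

### The GD effect profile and its calibration

`default_gd_effect()` encodes task "spectral slowing": elevated
Delta/Theta/Alpha power, increased Delta and Beta variability, mildly
reduced Beta power, and reduced Gamma irregularity. The Delta amplitude
multiplier is not a free dial: `calibrate_amp_multiplier()` solves the
log-normal power model

$$d(m) = \frac{m^2 - 1}{\sqrt{e^{4s^2} - 1}\,\sqrt{(1 + m^4)/2}},
\qquad s^2 = \log(1 + \mathrm{CV}^2),$$

for the multiplier $m$ that yields a target population Cohen's d on band
power (default 0.9) under the configured between-subject jitter, with a
correction for the mean-power boost of the increased GD Delta envelope CV
($E[g^2] = 1 + \mathrm{CV}_{\mathrm{env}}^2$). Across 20 seeded cohorts at
the default conditions the realized O1 Delta power contrast averages d ≈
0.95. Note the irreducible sampling error of an effect-size estimate at
n = 15/group is SE(d̂) ≈ 0.38, so individual cohorts legitimately realize
d anywhere in roughly 0.4–1.5. The Gamma entropy multiplier (0.80) was
calibrated against the entropy jitter to land a moderate negative
spectral-entropy contrast (mean d ≈ −0.5).

### What the generator does not emulate

No dipole/forward modelling, no eye-blink or EMG waveform morphology, no
non-stationarity beyond the slow envelopes, and only two channels. Tests
passing on these cohorts show that the pipeline's statistics behave
correctly under the assumed data model — not that the biological claims
hold on real recordings.

## Preprocessing

`apply_filters()` implements a three-stage zero-phase chain: 4th-order
Butterworth high-pass at 0.5 Hz, an RBJ second-order IIR notch at 50 Hz
(Q = 30, ≈ 1.7 Hz bandwidth), then a 4th-order Butterworth low-pass at
50 Hz — the notch deliberately precedes the final low-pass. Each stage is
applied forward–backward over an odd-reflected padding of ≈ 3 s, so there
is no group delay (verified by zero cross-correlation lag) and edge
transients never reach the data; the 20-s boundary trims
(`trim_boundaries()`) make any residue immaterial. 600-s inputs leave
560 s of analyzable signal.

`reject_artifacts()` scans consecutive non-overlapping 10-s epochs and
rejects an epoch when **either** channel exceeds the amplitude criterion.
The "±100 µV peak-to-peak" phrasing common in this literature is
internally inconsistent (a ± bound is absolute, peak-to-peak is a range);
the default reads it as the stricter absolute bound `max|x| > threshold`,
with the literal range reading (`range > 2·threshold`) available via
`criterion = "peak_to_peak"`. An epoch whose extreme equals the threshold
exactly is retained — a documented tie rule for bit-reproducibility.
Accounting is exact: rejected + retained seconds equal the analyzed
duration for every subject and threshold. `retention_summary()` and
`threshold_sensitivity()` (±75/100/125 µV) reproduce the usual
retention-table layout, including a two-sided Welch t-test on rejected
seconds. In GD-effect cohorts the GD group loses a few percent more data
than HC because elevated slow-wave amplitude interacts with the fixed
threshold; this is a property of the generator conditions, not a
preprocessing bias.

## Wavelet band decomposition

`dwt_decompose()` is a 6-level multilevel DWT with the 8-tap Daubechies-4
(db4) filters, implemented as a periodized orthonormal transform: each
level correlates the circularly-extended signal with even shifts of the
scaling/wavelet filters, the inverse is the transpose, reconstruction is
exact to numerical precision and coefficient energy equals signal energy
exactly. Signals are last-value padded to a multiple of $2^6$ and
reconstructions truncated back. We use periodization as the single
extension mode (rather than symmetric extension at runtime) because it
gives exact Parseval behaviour and perfect reconstruction; with 20-s
boundary trims upstream, circular boundary effects are immaterial.

At 256 Hz the level-to-band mapping is dictated by the dyadic frequency
axis: D2 → 32–64 Hz (Gamma source), D3 → 16–32 (Beta), D4 → 8–16 (Alpha),
D5 → 4–8 (Theta), A6+D6 → 0–4 (Delta). A first-level-detail = Gamma
mapping cannot hold at this rate (D1 spans 64–128 Hz), so the stated band
ranges take precedence over level numbering; Delta combines A6 with D6
because A6 alone stops at 2 Hz. The nominal Alpha/Beta bands are realized
as their 8–16/16–32 dyadic counterparts; `band_purity()` therefore reports
against dyadic ranges by default with nominal ranges available alongside.
The Gamma reconstruction is restricted to 30–45 Hz by an exact zero-phase
FFT mask — a Butterworth band-pass places −6 dB corners exactly at the
band edges after forward–backward application and its in-band roll-off
loss is avoided entirely by the mask.

One consequence is worth stating plainly: db4's level-2 detail carries a
non-trivial share (~14 % in alpha-dominant signals) of sub-30 Hz content
through its wide transition band. Restricting Gamma to 30–45 Hz removes
that compensating leakage from the five-band sum, so the sum reconstructs
the ideal 0.5–45 Hz content with a residual of ~7 % RMS, not arbitrarily
small. The tests assert the exact pre-mask linear identity (the five
dyadic reconstructions sum to the input minus D1) and hold the masked sum
to the 10 % dyadic-leakage tolerance.

## Feature extraction

Per channel and band, 14 features: absolute band power (mean squared
amplitude, µV²; the length-normalized reading of the power sum — the
distinction is irrelevant after z-scoring but fixed for reproducibility),
relative power (share of the five-band total, summing to 1 to machine
precision), mean, SD, min, max, population skewness and raw kurtosis
(Gaussian ≈ 3, not excess), Hjorth activity/mobility/complexity (first
differences, unscaled by fs — the ratios make complexity unit-free),
Shannon entropy of the amplitude histogram (64 equal-width bins over the
per-signal range; constant signals give 0 by convention), normalized
spectral entropy, and peak frequency. "Std" features are the SD of the
band-limited time series (not of a band-power time course) — the common
reading of time-domain dispersion per band. Channel-level Theta/Alpha,
Theta/Beta and Beta/Alpha ratios are integrated from the broadband Welch
PSD, and O1+O2 composite band powers are arithmetic channel means (no
published formula specifies the composite; the mean is the natural
choice). Spectral bins in 45–55 Hz are excluded from all PSD
integrations, keeping every feature clear of the mains frequency.

`welch_psd()` uses Hamming windows with 50 % overlap and per-segment mean
removal: 2-s windows (0.5 Hz resolution) on full-length signals, 1-s
windows on 10-s segments so each segment still averages ≥ 19 periodograms.
Peak-frequency ties resolve to the lowest frequency.

Two aggregation modes build the subjects × 156 feature matrix:
`concatenated` evaluates every feature once on the full cleaned signal;
`segmentwise` cuts the cleaned band signals into 10-s segments, computes
features per segment and averages within subject. On stationary inputs
the two agree (power features exactly, within 5 % generally), which is the
designed check that concatenation does not drive the low-frequency
results.

## Group statistics

Welch's t (with Satterthwaite df, two-sided p) is implemented from the
summary-statistic formula so that published group means/SDs can be
re-tested without raw data; the raw-sample path computes the summaries
first and agrees with `t.test()` to 1e−12. Cohen's d is the classic
pooled-SD variant, signed GD − HC (Hedges' correction via a flag);
positive d always means the GD mean is larger, and the effect table
asserts that consistency. BH-FDR is applied across the full feature
family jointly — with ~156 exploratory features there is no defensible
narrower family. Spearman label correlations (GD = 1) flag
constant features as NA and exclude them from the ranking.

## LOSO evaluation

Each of the n subjects is held out once. Fitted exclusively on the
remaining n−1 subjects, in order: per-feature z-scoring (zero-SD features
are centred and left constant, which excludes them downstream); Spearman
collinearity pruning — among any pair with |ρ| > 0.9 the later feature in
registry order is dropped (deterministic tie rule); two-group ANOVA-F
top-8 selection (features with undefined F are unscoreable; if fewer than
8 survive, all survivors are used with a warning); classifier fit. The
frozen transforms are then applied to the held-out subject. The
no-leakage property is asserted by fingerprinting the fitted fold state
under perturbations of the held-out subject's features.

Classifiers (hyperparameters fixed across folds): depth-3 Gini decision
tree (`rpart`; depth 3 matches a small set of threshold-like rules),
100-tree random forest, k = 5 Euclidean KNN, RBF SVM with C = 1 and the
standard 1/p kernel scale on z-scored features, and a single-hidden-layer
16-unit ReLU MLP trained by full-batch Adam on cross-entropy for a fixed
500 epochs with no early stopping — the fixed budget, together with
per-fold seeds derived from the master seed, makes stochastic models
bit-reproducible end to end. The MLP is implemented in the package
because the specified architecture is a ReLU network trained with
cross-entropy.

Aggregates over the n held-out predictions (GD positive): confusion
counts, accuracy k/n, per-class and macro precision/recall/F1, the Wilson
95 % score interval, the SD/SEM of the binary correctness vector under
the population convention √(p̂(1−p̂)) (this convention reproduces four of
five published SEM values of the emulated design; the fifth, 0.075 for
24/30, matches neither the population nor the sample convention and is
documented as non-reproducible), and directional error counts
(GD→HC = FN, HC→GD = FP). The Wilson upper bound for 24/30 is 0.9049;
a published figure of 0.91 for that cell can only be obtained by rounding
0.905 half-up a second time.

A caveat the interval inherits from its binomial assumption: LOSO
correctness outcomes share training sets and are positively correlated,
so accuracy is overdispersed relative to Binomial(n, p) and the nominal
95 % Wilson interval under-covers somewhat (we measure ~70–85 % coverage
of chance on null cohorts, model-dependent). The interval is reported
because it is the field's convention; its nominal level should be read
with that caveat.

`permutation_test()` permutes labels across subjects and recomputes the
full LOSO evaluation per permutation. The label-independent stages
(z-scoring, collinearity pruning) are cached per fold — they cannot see
labels, so the cached run is exactly equivalent to recomputation — while
selection and fitting are redone every time. The p-value uses add-one
smoothing, p = (1 + #{acc_perm ≥ acc_obs})/(B + 1), which is strictly
positive and standard practice; B defaults to 5000 with B ≥ 100 enforced.
Null calibration (P(p ≤ 0.05) ∈ [0.01, 0.10] at B = 200) is verified on
directly simulated null feature matrices — labels independent of Gaussian
features — because the property under test is a property of the
permutation machinery in feature space, and 100 independent replicates of
the full EEG simulation would add hours of runtime without changing what
is being tested. Random-forest Gini importance over the full matrix is
descriptive only and is never used as a selection stage inside LOSO.

## Problem sizes used by the test suite

The packaged tests scale the study design rather than weaken assertions:
module tests use 60–120 s recordings and 3–10 subjects/group; the
statistical calibration uses 12 null EEG cohorts (8/group, 120 s; 1872
feature-tests) for the Welch type-I check, 100 null feature-matrix
replicates at B = 200 for permutation calibration, and the full 600-s,
15/group design across 20 seeds for Delta effect recovery. The analysis
scripts under `analysis/` run the full 30-subject, 600-s design.

## Known limitations

* The dyadic Alpha/Beta realization (8–16/16–32 Hz) is an honest
  approximation of the nominal 8–15/15–30 bands; purity is reported
  against both.
* The five-band sum under the 30–45 Hz Gamma restriction reconstructs the
  0.5–45 Hz content only up to db4 transition-band leakage (~7 % RMS).
* Wilson/SEM uncertainty summaries treat LOSO outcomes as independent;
  they are not, and coverage is below nominal.
* EDF export quantizes to 16 bits over a per-file symmetric range
  (round-trip error ≤ one quantization step); delimited export is exact.
* The generator makes no claim of biophysical realism; see the generator
  section for what passing tests do and do not establish.
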