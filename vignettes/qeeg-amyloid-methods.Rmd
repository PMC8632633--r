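---
title: "Methods: qEEG band-power features, generational feature search, and vote-ensemble classification of amyloid status"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: qEEG band-power features, generational feature search, and vote-ensemble classification of amyloid status}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qeegamyloid)
```

## The problem

Amyloid-β plaque burden — the molecular hallmark used to gate Alzheimer's
drug prescription — is normally established with PET imaging, which is
expensive, invasive and poorly accessible. In pre-dementia patients
(subjective cognitive decline, SCD, and mild cognitive impairment, MCI),
resting-state eyes-closed EEG shows group-level spectral differences
between amyloid-positive and amyloid-negative individuals: relative delta
and low-beta power tend to be elevated over fronto-central electrodes in
the positive group, while alpha and gamma are reduced. This package
implements a complete, testable pipeline that turns raw 19-channel EEG
into a per-subject amyloid score:

1. **Spectral features** — 152 relative band-power features (19 channels
   of the 10–20 montage × 8 bands).
2. **Cohort preparation** — stratified holdout, split-half augmentation of
   the minority (positive) class, split-half reliability screening.
3. **Univariate screening** — per-feature Welch *t* maps ("topography
   tables").
4. **Generational combinatorial feature search** — exhaustive evaluation
   of low-dimensional feature combinations, frequency-based propagation of
   recurrent features into higher-dimensional generations.
5. **Vote ensemble** — the best sub-models vote; the positive-vote
   fraction is the subject's score, thresholded at a diagnosis-specific
   cutoff.

Because the underlying clinical EEG/PET data are not publicly deposited,
the package ships a synthetic cohort generator that emulates the group
spectral structure. Every stage is exercised end-to-end against it.

## Feature definition

Channels are the 19 sites of the International 10–20 system in a fixed
canonical order (`eeg_channels`). Bands tile [1, 45] Hz without overlap:
delta [1,4), theta [4,8), alpha1 [8,10), alpha2 [10,12), beta1 [12,15),
beta2 [15,20), beta3 [20,30), gamma [30,45]. The half-open right edge
(gamma closed at 45 Hz) resolves the touching band edges; a bin at
exactly 10 Hz belongs to alpha2.

Spectra are averaged modified periodograms (Welch): Hann windows of
`fs / 0.25` samples (4 s, honoring the 0.25 Hz resolution), 50 % overlap,
per-window mean removal before tapering to keep DC leakage out of delta.
Absolute band power integrates the one-sided PSD over each band's bins;
relative power divides by the channel's total over the eight bands, so
each channel's eight features sum to one. Recordings are re-referenced to
the common average first, which removes any common-mode signal and makes
the features independent of the recording montage.

Two physical invariants follow and are tested: absolute band powers
partition the total [1,45] Hz PSD integral, and doubling the signal
amplitude quadruples absolute powers while leaving relative powers
untouched.

One estimator caveat worth knowing: a pure tone *on* a band boundary
(e.g. exactly 10 Hz) leaks one Hann side-bin (1/6 of its energy) into the
lower band. This is windowing physics, not an assignment ambiguity — the
10 Hz bin itself is counted in alpha2.

## The synthetic cohort generator

The generator is specified by its band-power contract: every subject has
a 19 × 8 template of relative band powers, and the synthesized signal's
expected (in fact, exact — see below) band powers match it.

* **Baseline template** (all channels): delta .20, theta .15, alpha1 .18,
  alpha2 .12, beta1 .08, beta2 .09, beta3 .10, gamma .08 — a typical
  eyes-closed profile with dominant alpha and a pink-like decay across
  bands.
* **Group profiles**: the amyloid-positive profile adds a single
  effect-size shift (default 0.03 in relative-power units) to delta over
  twelve fronto-central/posterior channels and beta1 over six frontal
  channels, and subtracts it from alpha (split across alpha1/alpha2 on
  eight channels) and gamma (six channels); rows are renormalized. The
  channel lists follow the direction topography the analysis is designed
  to detect. No published effect magnitudes exist; 0.03 with
  between-subject `noise_sd = 0.04` gives per-feature effects of
  *d* ≈ 0.6, large enough that the planted-feature recovery and screening
  power properties hold at the documented sample sizes, small enough that
  single features do not trivialize the search.
* **Between-subject variability**: additive Gaussian noise per
  channel × band (`noise_sd`), floored at 10⁻³ and renormalized per
  channel.
* **Signal synthesis**: each channel is built in the frequency domain on
  the bins of [1,45] Hz. Within a band the carrier spectrum is flat with
  a narrowband 10 Hz alpha resonance added; coefficients get random
  Gaussian phases, and each band's coefficient vector is rescaled so the
  realized band power equals the template exactly (a constrained
  realization, as in surrogate-data methods). Two design points deserve
  explanation:
  * *Flat-in-band carriers.* A 1/f tilt inside the delta band would pile
    energy onto the 1 Hz edge, where the Hann window leaks part of it
    below 1 Hz and biases the recovered template by ~0.02. With flat
    carriers the generator's templates are recovered within 0.02 at
    180 s. The across-band envelope still decays like real EEG because
    the template itself does.
  * *Amplitude constraint.* With free Gaussian amplitudes a band of
    bandwidth *B* observed for *T* seconds fluctuates by ~1/√(BT) —
    about 4 % for delta at 180 s — which would dominate the roundtrip
    error budget. Constraining amplitudes leaves Welch's own
    time-local estimation noise as the only discrepancy.
* **Determinism**: per-subject seeds derive from the design seed and the
  subject index, so a cohort is bit-reproducible and extending *n* never
  reshuffles existing subjects.
* **Defaults**: 180 s at 250 Hz (200 Hz also standard), positive:negative
  prevalence roughly 1:2.5 as in the study population, total per-channel
  power 100 µV² (10 µV rms).

What the generator does *not* emulate: artifacts (eye blinks, muscle,
electrode drift — inputs are artifact-free by construction, as the
denoising step of the original acquisition chain is out of scope),
cross-channel correlation (volume conduction), non-stationarity,
inter-site hardware differences, and any realistic relationship between
diagnosis strata beyond their labels. Passing tests therefore demonstrate
the *pipeline's* correctness and statistical behavior, not clinical
performance on real EEG.

## Cohort preparation

`holdout_split()` assigns a test fraction (default 20 %) within each
(diagnosis, amyloid label) stratum, apportioning the overall rounded test
count by largest remainder — a stratum of 35 at 0.2 contributes exactly 7
test subjects.

`augment_positives()` implements split-half augmentation: each
amyloid-positive *training* subject's recording is cut into its first and
second temporal halves and each half's feature vector becomes a separate
row, exactly doubling the positive training count (the classes are
roughly 1:2.5 imbalanced). The two halves carry a `lineage` pointer to
their parent; every downstream step (CV folds, inner validation,
statistics) groups by lineage so the halves never separate — otherwise a
subject could sit on both sides of a fold boundary and leak. Test rows
are never augmented. When only feature tables exist (no recordings), the
fallback duplicates rows and warns: it rebalances class weights but adds
no information.

`split_half_reliability()` correlates each channel's first-half and
second-half PSD over [1,45] Hz; a recording passes when all 19
correlations exceed 0.90. The screen uses 0.5 Hz resolution rather than
the 0.25 Hz feature resolution: on 90 s halves, 0.25 Hz bins have enough
estimator noise to cap the correlation near 0.93 for *any* stationary
signal, which would make the screen measure the estimator instead of the
recording. At 0.5 Hz each bin averages twice as many windows and the
default generator passes with margin (minimum ≈ 0.95 across seeds),
failing only genuinely unstable signals. Screening is advisory (a flag),
not a hard filter: the study reported the check but no rejection rule.

## Univariate screening

`feature_group_tests()` applies Welch's two-sample *t*-test per feature
between the amyloid groups. (A paired test cannot apply to independent subject groups; Welch's unpaired test is the defensible choice, robust to unequal variances and group sizes.) Augmented halves are collapsed to their
parent's mean first, so no subject is counted twice. No multiplicity
correction is applied by default — the screening topography is
descriptive and does not gate the search — but `significant_topography()`
accepts `adjust = "BH"`. Under the null generator the per-feature flag
rate at α = 0.05 is calibrated (checked against a binomial band over 500
replicate tables).

## The generational feature search

The search treats each of the 152 features as a gene and a k-feature
combination as a genotype:

1. Enumerate **all** combinations of the current pool at dimension *k*
   (k = 1..3 exhaustively over all 152 features by default; the enumeration sizes — 11,476 pairs, 573,800 triples, 21,374,050 quadruples, 632,671,880 quintuples — are computed exactly by `count_combinations()`).
2. Score each combination by stratified, lineage-grouped five-fold CV of
   the classifier (below), with feature standardization fit inside each
   training fold.
3. Keep the "good models" — the top 1 % by CV accuracy with a floor of
   50 (ties: higher CV sensitivity, then canonical combo order) — and
   tally how often each feature occurs in them.
4. For the next dimension, restrict the pool to the features with the
   highest merged tally across all completed generations (ties: best
   accuracy of a top model containing the feature, then canonical order).
   Defaults: 40 features at k = 4 (91,390 models) and 30 at k = 5
   (142,506), keeping every generation desk-scale.
5. Return every model whose CV accuracy exceeds the retention threshold
   (default 0.75) plus a per-generation mean/max accuracy summary.

No crossover or mutation is involved: the "genetic" element is purely
frequency-based propagation of recurrent features. Two properties anchor
the tests: on small instances whose full enumeration fits the generation
budget, the search *is* exhaustive and must match a brute-force oracle
exactly; and under pool reduction pressure a strongly planted 3-feature
effect must still be recovered. Mean top-model accuracy rising across
generations is a stochastic property of the default cohort, checked over
seeds.

### Classifier

The default sub-model is a linear-kernel SVM (`e1071::svm`, C = 1,
features standardized per training fold). A pooled-covariance linear
discriminant (`classifier = "lda"`, with a 10⁻⁸ ridge and class-prior
offset) is provided as a fast alternative: a fold-precomputed
cross-product implementation fits in ~0.2 ms versus ~2.7 ms for the SVM,
which matters when an experiment evaluates 10⁵–10⁶ combinations. The
large seeded experiments in the test suite (oracle equivalence, recovery,
permutation nulls) use the LD classifier for this reason; the
monotone-generation check and all defaults use the SVM.

### Numerical and degeneracy choices

* Fold assignment is seeded and retried with an incremented seed (bounded)
  if any fold's training part lacks a class.
* Constant features within a training fold get unit scale (they become
  exactly zero after centering and cannot influence either classifier).
* All tie-breaks (top-model selection, pool ranking, candidate ordering)
  end in canonical feature order, so every result is bit-reproducible
  under a fixed seed.
* A generation whose enumeration exceeds the evaluation budget
  (`max_models`, default 2·10⁵) refuses to run and asks for a smaller
  pool rather than silently subsampling.

## Ensemble, cutoff, evaluation

`select_submodels()` refits the best 20 retained candidates on the full
training data. Ranking uses the *worse* of CV accuracy and a selection
accuracy ("high accuracy in both" made conservative): by default the
selection accuracy comes from an inner stratified validation subset
carved out of training (25 % of lineage groups), so the holdout is never
touched; `mode = "holdout"` reproduces the study-style selection that
reuses the test set, and the resulting object is labelled accordingly.

`ensemble_score()` is the vote fraction: with 20 sub-models, scores live
on the grid 0, 0.05, …, 1.0 (all-positive votes = 1.0, half = 0.5,
none = 0). Note that a published cutoff like 0.58 falls *between*
attainable 20-vote fractions (11/20 = 0.55, 12/20 = 0.60); with the
`score ≥ cutoff → positive` rule it behaves exactly like 0.60.

`fit_cutoff()` maximizes Youden's J over the observed score grid, tie
broken toward the lower cutoff (favoring sensitivity), with 0.5 as the
documented fallback when no cutoff beats J = 0. How the study derived its
cutoffs (0.58 SCD, 0.45 MCI) is unstated, so a fixed-cutoff mode echoes
any published value for replication attempts.

`evaluate_ensemble()` audits the split in strict mode (every row tagged
test, no lineage shared with training), thresholds scores, builds the
confusion matrix and derives sensitivity, specificity, accuracy and
balanced accuracy via `metrics_from_confusion()` — which, fed the
published confusion matrices, reproduces the printed percentages to one
decimal (85.7/89.3/88.6/87.5 for SCD; 83.3/85.7/84.6/84.5 for MCI).

## Problem sizes used in the shipped experiments

The test suite and `scripts/acceptance.R` run everything at desk scale,
chosen as the smallest sizes at which the statistical properties are
stable: oracle equivalence on 12-feature instances (10 tables, 40+40
subjects); recovery of a planted 3-feature effect among all 152 features
at n = 100/100 over 20 seeded runs with pools reduced to 40 (k ≤ 3) and
12 (k = 4); generation monotonicity on the default 20/50 cohort over 5
seeds with pools 25/18/14/12; type-I calibration over 500 null tables of
30/30; and an end-to-end pipeline at the study's cohort composition
(SCD 34/146, MCI 29/34) with pools 30/20/15/12. The full default
schedule (k ≤ 3 exhaustive over 152 features, 573,800 models) is
supported by the same code path and the budget guard, just not exercised
inside the suite.

## Known limitations

* Synthetic channels are statistically independent given their templates;
  real EEG has strong volume-conduction correlation, which common-average
  referencing then redistributes. Effect attenuation by re-referencing is
  therefore milder here than it would be on real data.
* The generator plants additive relative-power shifts; real group
  differences may be multiplicative, topographically smooth, and
  confounded with age or site.
* The search's CV accuracies are model-selection statistics: after
  selecting the maximum over thousands of combinations they are
  optimistically biased, which is exactly why the ensemble is evaluated
  only on the untouched holdout.
* Split-half augmentation treats two halves of one recording as
  exchangeable samples; under non-stationarity (not modelled here) the
  halves would be correlated less than duplicates but more than
  independent subjects, and the lineage-grouping guard is what keeps that
  from inflating CV estimates.

## A minimal run

```{r example, eval = FALSE}
library(qeegamyloid)

tab <- generate_feature_table(cohort_design(n_positive = 20, n_negative = 50,
                                            seed = 5))
cfg <- search_config(k_max = 4, k_exhaustive = 1,
                     pool_size = c("2" = 25, "3" = 15, "4" = 12),
                     top_min = 20, seed = 5)
pip <- amyloid_pipeline(tab, cfg)
pip
glance(pip)
autoplot(pip$search)       # generation performance curve
autoplot(pip$evaluation)   # score-by-group boxplot with cutoff
```
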