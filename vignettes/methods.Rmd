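---
title: "Methods: permutation-based placebo response analysis and its synthetic testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: permutation-based placebo response analysis and its synthetic testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical models the package implements, the
choices that were genuinely open, and what the synthetic testbed does and
does not establish.

## The responder model

The primary outcome is a stream of twice-daily 0–10 VAS pain ratings per
subject across five trial periods (BL 14 d, T1 14 d, W1 7 d, T2 14 d,
W2 7 d, delimited by six visits). Rather than declaring response by an
arbitrary percent-change cutoff, each subject is tested against their *own*
rating variability: the pooled-variance two-sample *t* between baseline and
a treatment period is referred to a permutation null built by reshuffling
the period labels over the pooled ratings.

Choices made where the procedure was underdetermined:

* **Pooled vs Welch t.** Pooled is the default (the classical permutation
  pairing); Welch would change little since both periods come from the same
  subject, and period variances are similar in practice.
* **Sidedness.** The permutation p is two-sided by default (a one-sided
  variant is available). Response additionally requires the *direction*
  check `mean(treatment) < mean(baseline)`, so a significant worsening is
  never a response. This makes the responder call conservative: its
  realized type-I rate on null subjects is roughly half the nominal α.
* **p estimator.** `(b + 1) / (n_perm + 1)` (add-one correction), so
  Monte-Carlo p values are never exactly zero; tied statistics count as
  exceeding.
* **Duplicate ratings.** The 30-minute deduplication rule is stated
  pairwise; for chained runs (10:00, 10:20, 10:40) we scan left to right
  and let each new in-window entry supersede the current candidate, so a
  run collapses to its final member — the simplest reading consistent with
  "keep the last rating". Gaps are never interpolated: the temporal
  structure of missingness is left intact.
* **Period assignment** uses half-open intervals `[visit_k, visit_{k+1})`;
  an entry timestamped exactly at a visit belongs to the later period.
* **Per-subject RNG streams** are derived by hashing the subject id with a
  cohort-level seed, so results are invariant to subject order.

Magnitude of response is `mean(BL) − mean(last 7 calendar days of T_k)`,
maximized over the two treatment periods, and %analgesia divides by the
baseline mean. The "last week" window uses all retained entries in the
final 7 days before the period-closing visit.

## Questionnaire screen

Subscales are scored with the >20 %-missing rule (mean imputation within
the subscale otherwise). The screen runs, per subscale, a two-sample *t*
between responder groups — the exact group-difference statistic was an open
choice; *t* is the field default and is configurable — and a Pearson
correlation with %analgesia, flagging at the Bonferroni level `0.05 / m`.
`m` defaults to 37 (the familywise budget used for the group contrast
figure the design mirrors) although 38 subscales exist; both are exposed.
Subjects that are 3-SD outliers on magnitude are excluded first, in a
single pass (mean and SD are not recomputed after exclusion).

## Network statistics

Edges are Fisher-z transformed Pearson correlations. The edgewise test is a
mass-univariate pooled *t* per edge with a permutation null from group-label
shuffles; the *same* shuffles are applied to every edge so the null
preserves cross-edge dependence, and Benjamini–Hochberg FDR (BH, not BY —
no dependency qualifier was attached to "FDR-corrected") is applied across
all edges. One numerical interaction worth knowing: with the add-one
correction the smallest attainable p is `1/(n_perm + 1)`, so detecting `k`
true edges among `m` at FDR α requires roughly `n_perm > m / (α k)`
shuffles. The defaults (5000 shuffles) are adequate for hundreds of edges;
for the full 7381-edge mask, users hunting a handful of edges should raise
`n_perm`.

Louvain consensus: 100 partitions per subject (node order shuffled per
repetition, since the greedy pass is order-dependent), co-assignment
averaged over all `subjects × 100` partitions, agreement thresholded at
0.5, and the final modules taken as connected components of the thresholded
agreement graph — "thresholding" alone does not define a partition, and
connected components are the simplest deterministic completion. The Louvain
resolution parameter defaults to 1 (exposed). Negative weights are dropped
(set to zero) for the modularity pass only, with the count recorded on the
result, because the underlying implementation requires nonnegative weights;
the agreement matrix itself is unaffected.

The subcortical asymmetry ratio sums right-hemisphere accumbens, amygdala
and hippocampus volumes and divides by the left sum. Covariate control
(peripheral gray matter volume, age, sex) is implemented as residualization
before the group contrast, mirroring an ANCOVA adjustment.

## Cross-validated prediction

Both learners run a nested leave-one-out: outer leave-one-subject-out for
unbiased prediction, inner stratified 10-fold for tuning. All feature
normalization uses training-fold statistics only; the no-leakage property
(corrupting a held-out subject's outcome never changes that subject's
prediction) is asserted in the test suite.

* **SVM (classification).** RBF kernel; box constraint and kernel scale
  tuned over `10^{-3..3}` (7 log-spaced points each — the grids were an
  open choice and are fixed in configuration for reproducibility); least
  inner misclassification error wins, first grid point on ties.
* **LASSO (magnitude).** Optional in-fold feature selection by robust
  simple regression (IRLS, Tukey bisquare, tuning constant 4.685 — the
  standard default for "robust regression" — with the slope's large-sample
  *t* p value) at p < 0.001; λ tuned on the training fold's own λ-path by
  least mean inner CV error (not the 1-SE rule, matching "least error");
  an empty selection falls back to predicting the training mean.
* **Consensus weights** average each feature's weight over all outer folds
  (absent = 0); "selection frequency" counts folds where the feature
  carried a nonzero weight; frequencies above 0.84 are flagged (with 43
  folds that requires ≥ 37 selections).
* **Calibration.** The null accuracy distribution repeats the entire nested
  procedure on scrambled labels; significance is `z > 1.96` against that
  null. Accuracy, sensitivity and specificity all carry exact
  Clopper–Pearson 95% CIs.
* **Model comparison.** Two prediction vectors are compared by their mutual
  correlation and a joint regression of the actual outcome on both; arm
  specificity uses the Fisher r-to-z two-sample contrast.

## Blinding

`make_scrambled_codes()` emits the real labeling plus two decoys that are
random permutations constrained to exact class counts (cell scrambling —
Bernoulli relabeling would change group sizes and hence power), shuffled in
order, with the real index sealed behind a checksum until `reveal()`. The
seal is procedural, not cryptographic.

## The synthetic testbed

`generate_cohort()` emulates the trial's conditions: arms of 43 (placebo)
and 20 (no treatment) with responder fractions 24/43 and 4/20 (exact
rounded counts, randomly positioned); per-subject baseline drawn from
6.10 ± 1.33 VAS and truncated to the >4/10 inclusion range; responders'
ratings drop by a planted %analgesia — mean 33, between-subject SD 10, a
generator addition needed so that magnitude has spread for correlation and
regression targets; non-responders jitter around zero effect. Analgesia
onsets one day after treatment start and is fully retained during washout
(carryover 1.0, since observed analgesia plateaus persist through washout).
Ratings sit on a 2/day grid at 9:00/21:00 ± 2 h, carry white noise of SD 1
VAS (a realistic within-subject spread; an AR(1) parameter is exposed but
defaults to 0 because within-subject autocorrelation of app ratings is not
established), are truncated to [0, 10], and go missing with probability
0.1.

Questionnaires use a Gaussian copula: each subscale's latent mixes the
standardized planted analgesia (placebo arm only — the no-treatment arm
carries *no* association, which is what makes the prediction models
arm-specific) with independent noise, then maps through a Beta(2, 2) margin
onto a 0–40 range; margins are therefore non-normal while correlations land
within a few hundredths of their targets. Defaults plant six subscales at
r = 0.40–0.60, emulating the handful of interoception/openness-type scales
that track response.

Connectivity matrices come from a latent-factor (6-community) population
matrix, per-subject loading jitter (SD 0.1), planted Fisher-z offsets at
parameterized edges for responders (non-persistent edges only at the
pre-treatment scan V2), an eigenvalue-clipping repair if an offset breaks
positive semi-definiteness, and finally the sample correlation of 200
multivariate-normal draws — so every emitted matrix is a valid correlation
matrix with realistic sampling noise. Volumes plant a +0.05 right/left
ratio offset in responders over plausible structure volumes.

**What passing tests show — and don't.** The testbed verifies the
machinery: calibration of the permutation tests, FDR control, power against
planted effects of stated size, leakage-freedom of the cross-validation,
and recovery of planted features. It does not emulate autocorrelated
symptom dynamics, rating scale clumping, site or scanner effects,
head-motion artifacts, or heavy-tailed questionnaire margins; conclusions
about real cohorts still require real data.

## Problem sizes and numerical choices

The test suite and acceptance script scale Monte-Carlo counts to the
property being checked: 2,000 permutations per subject for type-I
calibration on 200 null subjects, 2,500–3,000 shuffles for edgewise power
runs on 20-node (190-edge) networks, 400–500 for null FDR repeats, and
reduced SVM grids where only the nested mechanics are under test. These
sizes give Monte-Carlo errors comfortably below the tolerances asserted;
the package defaults (10,000 / 5,000 / 1,000) remain the analysis-grade
settings. Degenerate inputs have defined behavior throughout: identical
constant periods give p = 1, zero pooled SD makes the effect size an error,
zero-variance features are skipped in selection and left unscaled in
normalization, and |r| = 1 is clipped before `atanh` with a warning.
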