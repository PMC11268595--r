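---
title: "Group-fairness auditing and equalized-odds mitigation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-fairness auditing and equalized-odds mitigation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fairmhc)
```

## The problem

Automated mental-health assessment classifiers are trained on small,
demographically heterogeneous interview cohorts. Even when the cohort's
label composition shows no demographic dependence, a trained classifier can
still select, or err, at different rates across gender, race, age or
education groups. `fairmhc` provides the full evaluation loop for that
setting: a composition audit of the cohort itself, four group-fairness
ratio metrics computed over repeated cross-validation, a post-training
equalized-odds mitigation step, and a synthetic cohort generator so that
every stage is testable without access to protected clinical data.

## Metrics

For a sensitive attribute $k$ with groups $G_k$ and a designated privileged
group $g^\*$, let $S_g$, $TPR_g$ and $FPR_g$ be the selection rate, true
positive rate and false positive rate of the classifier in group $g$. The
package computes:

* overall demographic parity ratio
  $D^k = \min_g S_g \,/\, \max_g S_g$;
* privilege-referenced demographic parity ratio
  $D^k_{g^\*} = \min_{g \neq g^\*} S_g \,/\, S_{g^\*}$;
* overall equalized odds ratio
  $O^k = \min\!\big( \tfrac{\min_g TPR_g + \delta}{\max_g TPR_g + \delta},
  \tfrac{\min_g FPR_g + \delta}{\max_g FPR_g + \delta} \big)$;
* privilege-referenced equalized odds ratio
  $O^k_{g^\*} = \min\!\big( \min_{g \neq g^\*}
  \tfrac{TPR_g + \delta}{TPR_{g^\*} + \delta},
  \min_{g \neq g^\*} \tfrac{FPR_{g^\*} + \delta}{FPR_g + \delta} \big)$.

A ratio of 1 means parity; values further from 1 mean larger disparity.
The smoothing constant $\delta$ defaults to 0.001 and only guards the
equalized-odds denominators; no smoothing is applied to the parity ratios.

Three deliberate choices here:

* **The privilege-referenced FPR term is asymmetric** — the privileged FPR
  sits in the numerator while the privileged TPR sits in the denominator of
  its term. This orientation is kept verbatim: it reads as "how much worse
  off is the worst unprivileged group", with higher false-alarm exposure and
  lower sensitivity both pulling the ratio below 1. A consequence is that
  both privilege-referenced ratios can exceed 1 when an unprivileged group
  out-performs the privileged one; we do not clip them, and instead offer
  `symmetric_disparity()` (`min(x, 1/x)`), clearly labelled as an extension,
  for users who want a folded summary.
* **Undefined rates are flagged, never zero-filled.** A group with no
  positives has no TPR; substituting 0 would silently collapse the EOR.
  Such groups are dropped from a ratio with a warning, and downstream
  reports carry explicit `NA` rows with reason notes.
* **Per-group macro-F1** averages the two class F1 scores; a class absent
  from both truth and predictions inside a group contributes F1 = 1 (a
  degenerate but perfect outcome), while a class absent from truth but
  predicted contributes 0. This avoids punishing perfect predictions on
  one-class groups, which are common at per-group sizes of 10–30.

## Dataset audit

`audit_composition()` reports per-(attribute, group, label) counts and
selection rates, Pearson chi-square tests of group x label independence,
and two-sided Mann-Whitney comparisons of age and education between label
classes. Conventions:

* Labels are either a clinician-assigned binary or a scale cutoff
  "score strictly greater than 10" (PHQ-9 for self-rated depression, GAD-7
  for self-rated anxiety); a score of exactly 10 is negative.
* Groups with fewer than 5 subjects (configurable) are excluded *from that
  attribute's analyses only*; the subjects remain in every other
  attribute's analyses, and the exclusion log records what was dropped.
* The chi-square is the plain Pearson statistic without continuity
  correction; when any expected cell is below 5 a fragility note is
  attached rather than silently switching tests.
* The Mann-Whitney test is exact for small tie-free samples and otherwise
  uses the normal approximation with tie correction (the behaviour of
  `stats::wilcox.test`).
* No multiple-testing correction is applied; the report instead states the
  number of tests performed so users can correct at their chosen level.

## Evaluation protocol

`run_repeated_cv()` implements repeated label-stratified K-fold
cross-validation (defaults R = 100, K = 5). Within each class, shuffled
subjects are dealt round-robin into folds, so per-fold class counts are
within one subject of proportionality. Per training fold and per modality
a classifier is fitted and the held-out fold scored; the shipped reference
classifier is an L2-regularized linear logistic model (ridge penalty 0.05)
with within-fold standardization — a minimal probability-calibrated scorer,
not a claim about any particular feature pipeline. Scores above 0.5
(strictly) are classified positive everywhere unmitigated.

Two late-fusion rules combine modalities at the decision level: majority
vote (ties under an even number of members broken by the
probability-weighted rule) and probability-weighted voting (mean member
score thresholded at 0.5).

Fairness metrics are computed **per repeat from the pooled test folds**:
at n near 73 and K = 5, per-fold group cells are far too small for stable
TPR/FPR, so pooling the K test folds of a repeat gives one full-cohort
prediction set per repeat and hence R values per metric, summarized by
median, IQR and 1.5-IQR outliers. Distributions are compared between
conditions with two-sided Mann-Whitney rank-sum tests at the 0.05 level.

## Equalized-odds mitigation

`fit_eo_policy()` learns per-group randomized thresholds that maximize
accuracy subject to all groups operating at one common (FPR, TPR) point:

1. Per group, enumerate the ROC operating points of the score (one per
   distinct threshold, rule `score > t`) and take their upper convex hull
   (monotone-chain). Randomizing between two thresholds realizes any point
   on a chord of the curve, so the hull is exactly the achievable region.
2. The feasible equalized-odds set is the intersection of the group hulls.
   It is scanned along an FPR grid (step `grid_resolution`, default 0.001):
   at each grid FPR the largest jointly achievable TPR is the minimum of
   the per-group hull heights, scored by
   $acc = \pi\,tpr + (1-\pi)(1-fpr)$ with $\pi$ the pooled prevalence.
   Ties break toward smaller FPR. The diagonal is always feasible, so the
   optimum is never worse than the majority-class rule.
3. Each group's rule mixes the two hull vertices bracketing the target FPR
   (weight `p` between thresholds `t_lo`, `t_hi`), which reaches that
   group's hull boundary. A group whose hull lies *above* the common
   target additionally carries an ignore probability `p_ignore`: with that
   probability the score is discarded and the subject is classified
   positive with probability equal to the target FPR. A two-point
   threshold mixture alone can only reach chords between realizable
   operating points — a finite set of heights at any fixed FPR — so exact
   equalization of a non-binding group requires this third component; for
   the binding group `p_ignore = 0`. On the fitting data the expected
   per-group (FPR, TPR) equals the target up to floating point
   (`policy_expected_rates()` verifies this without Monte-Carlo noise).

The grid scan was chosen over a linear program deliberately: it is
transparent, dependency-free, and its error is bounded by the grid step,
which an exhaustive chord-enumeration oracle confirms in the test suite.

Policies are fitted on the **training fold's own scores** and applied to
the test fold. Whether fitting on training or pooled folds is the better
protocol is genuinely open; training-fold fitting avoids any test-label
leakage at the price of in-sample ROC optimism, and the pooled alternative
remains available via `mitigate_fit = "pooled"`. Randomization at apply
time draws from a stream keyed by (seed, subject id), so predictions are
reproducible row-wise regardless of table order. Groups degenerate in the
training fold (a single class) fall back to the pooled accuracy-optimal
single threshold rather than failing the fold.

## Synthetic cohort generator

The generator defines the study conditions under which the pipeline is
exercised:

* Demographic group counts are exact (not sampled); attributes are
  independent by default, with an optional joint count table to induce
  dependence for power checks of the audit's chi-square test.
* The binary clinical label is Bernoulli per group of a designated label
  attribute. The demo configuration emulates a 73-subject interview cohort
  (overall positive rate 0.70, matching a 51/22 case-control frame, with
  small non-binary and Hispanic groups below the n = 5 analysis threshold).
* Scale scores are label-conditional rounded clipped Gaussians (PHQ-9:
  positive class mean 15, sd 4.5; negative 5, sd 3.5; GAD-7: 13/4 and
  5/3), giving realistic overlap at the >10 cutoff within the instrument
  ranges.
* Features are label- and group-conditional spherical Gaussians: the two
  class means are `separation` apart, so within-group Bayes accuracy under
  balanced classes is `pnorm(separation / (2 * noise_sd))` — an analytic
  handle used to validate the separability knob. The disparity
  configuration (`disparity_cohort_config()`: n = 400, separations 2.5 vs
  0.5, noise sd 1) makes one group's task easy (Bayes accuracy 0.89) and
  the other's hard (0.60), which reliably induces a pre-mitigation overall
  EOR median below 0.6 for the reference classifier.
* Exact-rate prediction fixtures construct confusion counts exactly (a
  TPR of 0.9 with 10 positives is exactly 9 true positives; a
  non-representable rate is an error naming the nearest representable
  one), making them machine-precision oracles for the metric formulas. A
  sampled mode exists for stochastic tests.

What the generator does *not* emulate: raw audio/video signals, feature
correlation structure across modalities, non-Gaussian feature
distributions, label noise, or clinician rating bias. Passing tests
therefore demonstrate the correctness of the pipeline's computations and
the qualitative mitigation trade-off under controlled separability gaps —
not the fairness properties of any real assessment system.

## Numerical choices and problem sizes

* $\delta$ = 0.001; decision threshold strictly greater than 0.5; policy
  grid step 0.001 (coarser grids are used in some tests where an
  exhaustive oracle must share the grid).
* Sentinel thresholds are $\pm\infty$; JSON serialization carries them as
  strings with 17 significant digits so policies round-trip exactly.
* The test suite and the bundled end-to-end script use scaled-down problem
  sizes chosen to exercise every code path at desk scale: R = 20 repeats
  (rather than the protocol default 100) and n = 400 cohorts for the
  mitigation-direction check, 1,000 randomized tables for the metric
  oracle, and 10,000-draw permutation oracles for the chi-square
  comparison.

## Known limitations

* Group-fairness ratios only; no calibration, individual- or
  counterfactual-fairness notions.
* Post-training threshold adjustment only; in-training constraint methods
  and adversarial debiasing are out of scope.
* Mitigation optimizes equalized odds for a single attribute at a time.
* The privilege-referenced ratios' values above 1 complicate a naive
  "closer to 1 is fairer" reading; consult the symmetric column when
  ranking classifiers.
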