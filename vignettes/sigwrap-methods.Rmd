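---
title: "Methods: significance-based wrapper selection of molecular signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: significance-based wrapper selection of molecular signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Untargeted omics experiments (LC-HRMS metabolomics peak tables, microarray
expression matrices) routinely produce hundreds to thousands of features for
a few dozen samples. When the goal is a molecular signature -- a short list
of features that a binary classifier actually needs to discriminate two
groups of samples -- most selection strategies rank features and cut the
list at a threshold chosen by eye, or let a penalised model decide. Wrapper
approaches instead evaluate candidate subsets through the classifier's own
prediction accuracy, but classical wrappers stop at "accuracy did not drop",
without asking whether a subset's contribution is distinguishable from
noise.

`sigwrap` implements a wrapper that makes that question explicit: a feature
subset is retained only if destroying its information (by permutation in
held-out test sets) *significantly* degrades prediction accuracy. The output
is, per classifier, a final signature tier **S** and "runner-up" tiers
**A**-**E** of features discarded in the last to earliest rounds.

# The selection procedure

Given a samples-by-features intensity matrix and a two-level class, one
round of selection for a given classifier runs three steps.

**1. Bootstrap resampling.** `boot` (default 50) stratified bootstrap
resamples are drawn; each class is resampled with replacement to its own
size, so training sets keep the original class balance. The out-of-bag
(OOB) samples of each draw form the test set; draws whose OOB set is empty
or single-class are redrawn, since balanced accuracy is undefined there.
One model is trained per resample and evaluated on its OOB set with the
balanced accuracy (mean of sensitivity and specificity). No further model
is ever fitted during the significance testing below -- this is what keeps
the procedure fast.

**2. Feature ranking.** Each of the `boot` models ranks the features by its
own importance metric: variable importance in projection (VIP) for PLS-DA,
error-rate-based variable importance for Random Forest, squared primal
weights for the linear SVM. The per-model ranks are aggregated by taking
each feature's median rank and ranking the medians (ties: mean rank, then
feature index).

**3. Subset significance by permutation + half-interval search.** For a
candidate rank f, the candidate subset is every feature with aggregated
rank >= f. Its significance is tested by independently permuting each
candidate feature's values within each OOB test set, re-predicting with the
frozen models, and counting the bootstraps in which the permuted accuracy
is at least the original one. If that non-exceedance proportion exceeds
`alpha` (default 0.05, strictly), the subset is *not* significant.
Searching all p candidate ranks would cost p permutation evaluations; since
subsets are nested, a half-interval (binary) search over ranks finds the
boundary f_ns -- the lowest rank whose subset is not significant -- in
O(log p) evaluations. The search starts at rank 1 (permute everything),
keeps the last significant and last non-significant candidate ranks as
interval ends, probes the midpoint (half rounded away from zero, clamped
into the open interval), and stops when the interval is empty.

Features with rank below f_ns are this round's significant set; the table
is restricted to them and the round repeats. If no feature is significant,
the most important half (ceiling(p/2) lowest ranks) is kept but *not*
credited, so the search continues on a smaller table. The procedure
converges when a round finds every incoming feature significant (tier S) or
when nothing is left to test (empty signature; with a single remaining
non-significant feature we terminate with an empty signature, as there is
no smaller table to try). Discarded features are binned reverse-
chronologically: last round's discards are tier A, the previous round's B,
then C and D, everything earlier lumped into E.

The final model, when S is non-empty, is a single training on all samples
restricted to S. Reported accuracies of the full, S, and S+A models are
mean OOB balanced accuracies over `boot` fresh bootstrap resamples -- an
estimator documented here prominently because published accuracy figures
for this family of methods do not always state theirs, and OOB means are
not directly comparable to cross-validation or training-set estimates.

# The wrapped classifiers

* **PLS-DA** (own engine). The class is coded as a numeric response in
  {-0.5, +0.5}; features are mean-centred and unit-variance scaled
  (zero-variance features are centred with divisor 1 and flagged); PLS1
  components are extracted by NIPALS. A new component h is admitted while
  it explains at least 1% of the response variance (R2Y_h >= 0.01) and its
  7-fold cross-validated Q2Y_h = 1 - PRESS_h/RSS_(h-1) is at least 0 -- or
  at least 0.05 when n < 100, guarding small-sample optimism. RSS_0 is
  (n-1)var(y). Components are capped at min(10, n-1, p); the admission rule
  stops far earlier in practice. The model's predictive ability is the
  cumulative Q2Y, 1 - prod(1 - Q2Y_h). CV folds are stratified by class and
  seeded; with stratification every training part keeps both classes, which
  is why a plain random 7-fold is not used. When no component is admitted
  the model is flagged non-informative: one component is still fitted so
  that VIP ranking stays defined for the selection loop, but predictions
  fall back to the training majority class (ties toward the positive
  level), which avoids biasing OOB accuracy upward. Predicted scores are
  thresholded at 0; an exact 0 maps to the negative level.
* **Random Forest** via the `randomForest` package: 500 trees, mtry =
  floor(sqrt(p)) (at least 1), unscaled features, error-rate-based
  (mean-decrease-in-accuracy) importance, seeded.
* **Linear SVM** via `e1071` (libsvm): cost = 1, linear kernel on
  centred/scaled features, no class weighting; importance is the squared
  primal weight per feature. With duplicated columns the weight mass splits
  arbitrarily between the copies; only the sum over the copies is stable.

VIP is the Wold sum-of-squares-weighted form,
`VIP_j = sqrt(p * sum_h SS_h (w_jh/||w_h||)^2 / sum_h SS_h)` with
`SS_h = c_h^2 t_h't_h`, so the squared VIPs always sum to p. This is the
form implemented across the PLS software ecosystem.

# Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `boot` | 50 | bootstrap resamples per round; stability of the resulting signatures is flat above ~20-50 resamples, and 50 keeps the permutation test's granularity at 1/50 = 0.02 around `alpha` = 0.05 |
| `alpha` | 0.05 | strict threshold on the non-exceedance proportion; at boot = 50, exactly 2 non-drops (0.04) is still significant, 3 (0.06) is not |
| `methods` | all three | classifiers are run independently and intentionally disagree; the union and intersection of the S tiers are both informative |
| `seed` | -- | master seed; every stochastic step (splits, RF bagging, CV folds, permutations) derives a sub-seed from it, so reruns are bit-identical |
| `max_rounds` | 20 | safety cap; convergence normally takes < 10 rounds since unregistered rounds at least halve the table |

# What the synthetic generator emulates

`simulate_planted()` produces balanced two-class tables of Gaussian
features on a log-intensity-like scale: noise features N(0, sd) in both
classes, planted features shifted by `d * sd` in the "case" class, and an
optional equicorrelated block driven by a shared latent factor. This
captures the two properties the selection engine actually exercises --
a small number of truly discriminant features among exchangeable noise, and
p >> n -- but *not* several features of real peak tables: heavy-tailed and
heteroscedastic intensities, feature-wise missingness, adduct/isotope
correlation structure, batch effects. Passing the null-control and
planted-recovery checks therefore demonstrates the engine's operating
characteristics under clean Gaussian conditions, not performance on any
particular instrument's output.

`spike_semisynthetic()` complements it from the opposite direction: starting
from any table (in practice, a real one), every feature univariately
significant for the class (two-sided Wilcoxon rank-sum,
Benjamini-Hochberg FDR <= 0.05; the purge is iterated until no survivor is
significant) is removed, and one surviving target feature is amplified in
one class by the largest factor -- found by bisection on (1, 10] -- that
keeps it BH-undetectable. The result has a known target that univariate
screening cannot see. The Wilcoxon/BH choice matches the univariate
methodology standard in this field; the multiplication acts on stored
values as-is, so on a log-scale table it is a power transform of raw
intensities. Default conditions used throughout the tests: n = 40 balanced
samples, p = 100 (null control) or 200 (planted recovery), effect size
d = 3, within-class sd = 1.

# Evaluation toolkit

* **Balanced accuracy**: mean of sensitivity and specificity; a constant
  classifier scores 0.5 at any class imbalance. Which level is "positive"
  must be stated; it defaults to the lexicographically larger level purely
  for determinism.
* **Stability**: the selector is rerun on 10 subsets, each containing 90%
  of the samples, built as complements of a seeded stratified 10-fold
  partition (the construction is this package's choice; any scheme holding
  out 10% per subset would do). Stability is the mean Lustgarten
  chance-adjusted similarity over the 45 signature pairs:
  `(|a n b| - |a||b|/p) / (min(|a|,|b|) - max(0, |a|+|b|-p))`, 0 by
  convention for empty sets or a zero denominator. Its expectation under
  random selection is 0, and it accommodates signatures of different sizes.
* **Performance**: harmonic mean of accuracy and stability (0 when both
  are 0), penalising selectors that are accurate but unstable or vice
  versa. The accuracy entering it is the signature model's mean OOB
  balanced accuracy from the full-data run (the full model's when the
  signature is empty).
* **Q2Y permutation test**: the class labels are permuted (default 1000
  times), the full PLS-DA fit -- including automatic component selection --
  is rerun per permutation, and the p-value is the proportion of permuted
  cumulative Q2Y values >= the observed one; ties count toward the
  p-value, the conservative reading. For a non-informative fit the
  cumulative Q2Y of the single forced component (typically negative) is
  used, which keeps the null distribution honest.

# Comparator baselines

* **VIP filter**: one full-data PLS-DA fit, keep features with VIP >= 1 or
  >= 1.5 (the two conventional presets; the boundary is inclusive). A
  non-informative model yields an empty set with a warning.
* **RFE**: recursive feature elimination with the same bootstrap/ranking
  machinery as the main engine: per iteration, mean OOB balanced accuracy
  over `boot` fresh resamples is recorded and the worst-ranked
  max(1, floor(0.2 p)) features are dropped (so the size path from p = 10
  is 10, 8, 7, 6, 5, 4, 3, 2, 1), down to one feature; the visited size
  with the best accuracy wins, ties toward the smaller size. Bootstraps
  are redrawn each iteration so that OOB sets never come from models that
  saw removed features.

# Numerical choices and degenerate inputs

* Midpoints in the half-interval search use round-half-away-from-zero and
  are clamped into the open interval between the last significant and last
  non-significant ranks; the first candidate is always rank 1.
* Permutations are per-feature and fresh per candidate evaluation (no
  caching): each candidate feature's class association is destroyed
  individually, rather than jointly shuffling sample rows of the block.
* Rank ties anywhere resolve by ascending feature index, making every
  ranking a permutation of 1..p and every run reproducible.
* Odd-p halving keeps ceiling(p/2) features, never dropping the top-ranked
  feature on a tie between halves.
* Missing or non-finite values are rejected at validation, with the sample
  and feature named; constant features are retained (guarded scaling)
  rather than dropped, so degenerate synthetic inputs stay well-defined.
* Tier letters beyond E are lumped into E.

# Problem sizes used by the test-suite and acceptance script

The packaged checks run at desk scale, chosen to exercise the claimed
operating characteristics within a few minutes on one core: 20 null-control
datasets and 10 planted-recovery datasets in the test-suite (5 + 5 in the
acceptance script), each n = 40, p = 100-200, boot = 50; formula-level
checks run against brute-force oracles on exhaustive small inputs (label
vectors to length 6, all subset pairs of a 6-feature universe, monotone
search oracles to p = 16).

# Known limitations

* Binary classes only; no multi-class or continuous response.
* The permutation test conditions on the frozen per-round models; it
  quantifies each subset's contribution to *these* models' predictions,
  not a population-level variable-importance parameter.
* Signatures are classifier-specific by design; disagreement between the
  three classifiers is expected and informative, not a defect.
* OOB accuracy estimates are slightly pessimistic relative to full-data
  cross-validation (training sets contain ~63% unique samples).
* The bootstrap-count default (50) trades permutation-test granularity
  against runtime; below ~20 resamples the significance test becomes
  coarse (1/boot steps) and signatures destabilise.

# A worked example

```{r, eval = FALSE}
library(sigwrap)

d <- simulate_planted(n_per_class = 20, p = 100, n_informative = 2, d = 2.5,
                      seed = 42)
fit <- select_signature(d, class = "class", boot = 50, seed = 42)
fit            # per-classifier signatures and accuracies
tidy(fit)      # long feature x method tier table
autoplot(fit)  # tier tile plot
write_tiers(fit, "run1")  # tiers.tsv, accuracies.tsv, report.json
```
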