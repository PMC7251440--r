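---
title: "Exact interpretation of piecewise-linear connectivity classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact interpretation of piecewise-linear connectivity classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plnnfc)
```

## The problem

Resting-state functional connectivity (rsFC) studies summarize each subject
as a vector of pairwise correlations between the mean BOLD signals of brain
parcels (ROIs). Classifiers trained on these vectors can separate clinical
groups, but a clinician cannot act on a black box: the question is always
*which connections* drove a given prediction, and whether the answer is
stable across subjects. `plnnfc` addresses this by using a network whose
predictions can be interpreted exactly, per subject, with no sampling or
surrogate fitting.

## Feature extraction

For each subject with `T` timepoints and `p` ROIs we compute the `p × p`
Pearson correlation matrix, apply the Fisher transform `z = atanh(r)`
off the diagonal, and flatten the strict upper triangle in row-major order
into `d = p(p−1)/2` features. Choices worth stating:

- **Clipping.** `atanh(±1)` is infinite; correlations are clipped to
  `±(1 − 10⁻⁷)` first. At that bound `z ≈ 8.4`, far outside the range of
  realistic connectivity values, so the clip changes nothing material while
  making the transform total.
- **Flattening order.** Row-major over the upper triangle, 1-based:
  (1,2), (1,3), …, (1,p), (2,3), … This is arbitrary but must be fixed and
  public — every feature index in exports, decision-feature tables and the
  planted-edge ground truth refers to it. `edge_index_map()` is the single
  source of truth.
- **Degenerate inputs.** A zero-variance ROI (e.g. a parcel outside the
  field of view) makes the correlation undefined; such series are rejected
  by name rather than silently propagating `NA`.
- **Normalization convention.** Sample vs population variance cancels in the
  correlation ratio; either convention yields the same matrix.

## The classifier

The network is a stack of two fc–BatchNorm–LeakyReLU blocks followed by a
single sigmoid output unit (`d`–64–32–1 by default), trained with minibatch
Adam on binary cross-entropy, with dropout after each hidden block. Batch
normalization uses batch statistics during training (running statistics
updated with momentum 0.1, unbiased variance) and the frozen running
statistics at prediction time, so eval-mode output is a deterministic
function of the model and the input. Parameters that matter:

- `hidden` (default `c(64, 32)`): hidden widths. For the small synthetic
  cohorts used throughout the tests we use `c(16, 8)` — with ~200 features
  and a few hundred subjects, 64/32 units mostly add variance.
- `leaky_slope` α (default 0.01, dimensionless): the negative-branch slope.
  It appears explicitly in the folded weights, so it is exposed rather than
  hard-coded. α = 0 (ReLU) is accepted with a warning; the interpretation
  stays exact.
- `dropout` (default 0.8): the probability of *dropping* a unit — the
  "dropout ratio" convention. The default matches the reference
  architecture at width 64/32. For the 16/8-unit networks used in the
  synthetic experiments we set `dropout = 0.2`: dropping 80% of 16 units
  leaves ~3 active per step, which is not a regularizer but a demolition;
  0.2 is what a practitioner would configure at this width. Dropout is
  inactive in eval mode, so the interpretation is unaffected either way.
- `learning_rate` (5e-4), `batch_size` (32), `epochs` (200 by default; the
  synthetic experiments use 60–100, which the loss curves show is past
  convergence at those problem sizes). No early stopping — reproducibility
  over marginal generalization gains.
- `standardize` (default `FALSE`): optional per-column z-scoring. Off by
  default because Fisher-z edge features are already on a common scale;
  when on, the scaler is folded back into the reported local weights so
  interpretation remains in Fisher-z units.
- `bn_epsilon` (1e-5): variance floor; also guards the folded BN slope when
  a neuron's running variance is ~0.
- Initialization: He-style `N(0, 2/((1+α²)·fan_in))`, zero biases, BN
  γ = 1, β = 0; fully determined by `seed`.
- Labels: positive class = 1, so sensitivity is the detection rate of the
  clinical group.

Cross-validation is stratified (the class imbalance of a typical cohort
would otherwise leave folds with very different base rates), with fold
assignment and per-fold training seeds derived from one seed. Metrics are
the confusion-matrix quartet (sensitivity, specificity, accuracy, F1) plus
AUC by the Mann–Whitney rank formula with averaged ties.

## Exact local linearization

At prediction time each hidden block acts on its input `z` as
`a = r ∘ (s ∘ (Wz + b) + t)` where `(s, t)` is the BN affine form
(slope `γ/√(Var+ε)`, intercept `β − γE/√(Var+ε)`) and `r` is the per-neuron
LeakyReLU branch slope (1 or α) recorded for the instance at hand — the
*activation pattern*. Composing the blocks and the output layer gives
`logit(x) = Ŵx + b̂` exactly, inside the activation region of `x`.

Numerical and convention choices:

- **Intercept.** The weight product alone does not reproduce the logit; the
  BN intercepts and biases must be accumulated through the same recursion.
  `local_linear()` always returns `b̂`, and the faithfulness check
  `verify_faithfulness()` would fail without it.
- **Boundary convention.** A pre-activation of exactly 0 takes the slope-1
  branch (`u ≥ 0`). On that measure-zero boundary both branches agree in
  value, so the reconstruction is exact either way; the convention only
  fixes which region's `(Ŵ, b̂)` is reported.
- **LeakyReLU intercept.** Both branches pass through the origin, so the
  activation contributes slope only; the recursion still carries an
  activation-intercept term so other piecewise-linear activations could be
  folded with no structural change.
- **Precision.** All folding is done in double precision; the test suite
  asserts residuals `< 10⁻⁷` and observes `~10⁻¹⁵`. The linear form is the
  network, not an approximation: the tests also confirm region consistency
  (instances sharing a pattern share `(Ŵ, b̂)`) and agreement of `Ŵ` with
  finite-difference logit gradients away from region boundaries.

## Decision features

Each interpreted instance contributes its top-K features; a feature kept by
at least a fraction ε of instances enters the decision feature set.

- **Ranking.** Default is by `|Ŵ|`: a strongly negative weight is exactly as
  decision-relevant as a strongly positive one (it pushes toward the control
  class). A `signed` mode ranks by raw weight for compatibility with the
  "highest weight" reading.
- **Threshold.** Kept when `n_f / n ≥ ε` (inclusive).
- **Population.** Two supported modes: interpret every subject with one
  model trained on all data (`full`, the default in the pipeline), or pool
  held-out interpretations across CV folds so each subject is interpreted by
  a model that never saw it (`cv`, via `pooled_cv_interpretations()`). The
  `cv` mode is the right choice when the decision set itself is a claim
  about generalizable structure.
- Monotonicity (|F| nondecreasing in K, nonincreasing in ε) follows from
  nested top-K sets and the inclusive threshold, and is asserted over the
  full K = 5…300 × ε = 0.70…0.95 grid in the tests.

## Perturbation ("hacking") evaluation

Zeroing a feature in Fisher-z space sets that edge to "no connectivity",
which is the natural removal semantics for correlation features. After
zeroing, the forward pass recomputes activation patterns from scratch — the
hacked input may land in a different linear region, and freezing the old
pattern would understate the effect. Reported: mean CPP, NLCI (label flips
at 0.5), and post-hack sensitivity/accuracy against the *original* labels.
Two controls:

- **Random sets** (20 seeded draws of the same size): a well-attributed set
  should beat their median CPP by a wide margin; on the synthetic cohorts
  the contrast is two orders of magnitude.
- **Linear SVM**: the top-N features by |primal coefficient| are used to
  hack the SVM itself. Its "probability" is the logistic squash of the
  orientation-corrected decision value — Platt scaling would add internal
  cross-validation randomness to what should be a deterministic baseline.

CPP uses probabilities only, so it is invariant to relabeling; monotonicity
of CPP in the size of the zeroed set is *not* asserted for the network
(region changes can go either way) — only the closed-form behaviour of a
purely linear model is.

## Group statistics

Per mined edge: group means, mean difference, and an independent two-sample
t test — Welch by default (equal variances across clinical groups is an
assumption we need not make), pooled as an option. Means can be reported in
Fisher-z units (the model's input space) or back-transformed per value with
`tanh` to correlation units. No multiplicity correction by default, because
the table is a descriptive companion to a feature set already selected by
the model; a Benjamini–Hochberg option is provided and recommended whenever
the set is large or the p-values themselves are the claim. Type-I
calibration under the null is tested (fraction of p < 0.05 within
0.05 ± 0.02 over 1000 null features).

## The synthetic cohort generator

Real rsFC cohorts cannot be redistributed, so validation uses generated
cohorts with known ground truth. Both groups share a latent-factor
correlation matrix (3 Gaussian factors of total strength `base_density`
plus unit idiosyncratic noise, normalized to a correlation matrix); the
positive group's target adds `delta` to the planted edges and is projected
back to a valid correlation matrix by eigenvalue clipping at 10⁻⁶ followed
by renormalization — deterministic, and verified to move non-planted
entries by less than `delta/10`. Each subject gets a small symmetric jitter
(sd 0.02, PD-repaired) around the group target, and `t_len` rows are drawn
from the resulting Gaussian; an AR(1) option adds temporal autocorrelation
while preserving the stationary cross-ROI correlation.

Default condition for the end-to-end experiments: `p = 20`, 200 subjects
per group, `T = 150`, 5 planted edges at `delta = 0.3` — a group difference
of ~0.31 in Fisher-z units, comfortably detectable by a t test at this
sample size but planted in only ~2.6% of the 190 edges, so recovering it
requires the attribution to be specific, not just the classifier to be
accurate. At this scale the full pipeline runs in seconds, and the planted
set is recovered (≥ 3 of 5 edges at K = 10, ε = 0.70) in at least 4 of 5
seeded replicates; a 116-ROI, 871-subject configuration is a
`cohort_spec()` call away for larger manual runs.

What the generator deliberately does **not** emulate: non-Gaussian BOLD
marginals, hemodynamic autocorrelation structure beyond AR(1), multi-site
acquisition effects, motion artefacts, and heterogeneous (subject-varying)
effect locations. Passing tests on these cohorts therefore demonstrate the
*mechanics* — exact interpretation, consistent mining, causally load-bearing
attributions — not clinical-grade performance on real multi-site data,
where accuracies near 70% rather than 95%+ are the realistic regime.

## Known limitations

- Training is plain R; at the full 6670-feature, 871-subject scale a fit
  takes minutes rather than seconds. Fine for analysis, slow for sweeps.
- The interpretation is exact only in eval mode; train-mode BN (batch
  statistics) is not a fixed affine map and is out of scope.
- The decision-feature set depends on (K, ε) and, mildly, on the training
  seed; the sweep table is the honest way to present it.
- Only LeakyReLU/ReLU activations are supported for folding, though the
  recursion is written to admit any piecewise-linear activation.
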