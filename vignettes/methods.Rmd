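---
title: "Methods: synthetic external control arms, their evaluation, and the design choices behind synarm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(synarm)
```

## The problem

A single-arm oncology trial compares an experimental treatment against an
external control arm assembled from registry patients. Registry extracts of
a few hundred patients with high-cardinality features (age in years,
survival time in months) are both hard to synthesize faithfully — few
examples per genuine feature combination — and easy to re-identify.
`synarm` operationalizes one answer: synthesize the control arm, quantify
whether the synthetic arm supports the same treatment-effect conclusions,
and quantify what it leaks.

## Reversible generalization

**Model.** For each selected continuous feature, edges
`b_0 < … < b_N` are placed at empirical quantiles so each of the `N` bins
holds roughly equal numbers of patients (`fit_quantile_bins`). Bins are
half-open `[b_n, b_{n+1})` with the top bin closed so the observed maximum
is representable. After synthesis, a binned value is replaced by a draw
from a truncated normal on its bin, with per-bin mean and standard
deviation estimated from the original per-bin population — the only
population carrying real continuous values — under the Laplace mechanism.

**Privacy accounting.** The mean of a width-`w` bin containing `m` patients
has L1 sensitivity `w/m`; the same bound is used for the standard
deviation (a valid upper bound). The per-feature budget ε is split 50/50
between mean and sd. Bins partition the patients, so parallel composition
applies: a feature spends ε once, not `N·ε`; features compose
sequentially. Bin *counts* are taken as public (only the distribution
parameters are noised); this mirrors the position that only mean and sd
need private estimation, and is flagged here as an interpretation.

**Numerical choices.** `N = 10` bins by default; sd clamped to
`[w·10⁻³, w]` (zero-variance bins would otherwise degenerate); noisy means
clamped into their bin; empty bins fall back to a uniform draw on the bin
(midpoint mean, `w/√12` spread). The default reversal budget is ε = 1 per
feature — deliberately small, because only two scalars per bin are
estimated. The truncated-normal sampler is a numerically guarded
inverse-CDF; when the bin carries essentially no normal mass the draw
collapses to the clamped mean. Survival-time reversals are additionally
clamped non-negative.

## Generators

All generators share `fit(spec, data, seed)` / `sample(fitted, n, seed)`
and always emit data validating against the training schema.

* `dummy` replicates the training arm (resampling with replacement when
  `n` differs) — the upper bound of achievable quality and the worst case
  for memorization.
* `uniform` samples each feature independently and uniformly over its
  observed support — the lower quality bound.
* `independent` samples empirical marginals; useful as a mid baseline.
* `privbayes` is a differentially private Bayesian network over
  categorical features (continuous features must be generalized first).
  Structure: greedy ordering in which each `(node, parent set ≤ k)` pair is
  drawn by the exponential mechanism with plug-in mutual information as
  quality, sensitivity `log₂(n)/n + (n−1)/n·log₂(n/(n−1))`, spending
  `ε_structure/(d−1)` per step; `k = 0` forces independent marginals.
  Parameters: per-table counts perturbed with Laplace noise at one unit of
  sensitivity and an equal share `ε_params/d` per table, clipped at zero
  and renormalized (all-zero rows → uniform). Total ε is the sequential sum
  of the two phases; default ε = 10 with a 50/50 split, `k = 2`.
* `external` is the plugin contract for GAN-family generators: any object
  exposing `sample(n, seed)` built from the training data. Reimplementing
  GAN training loops is out of scope by design.

When the benchmark runs *without* generalization, `privbayes` still needs
categorical input; it then receives fine equal-frequency binning (40 bins)
with uniform within-bin reversal and no DP parameter estimation. This is
the high-cardinality regime the reversible generalization is meant to
improve upon, and it is what the "no generalize" arm of the benchmark
measures.

## Evaluation suite

**Resemblance.** Continuous features are compared by the two-sample
Kolmogorov–Smirnov statistic, categoricals by the Jensen–Shannon distance
(base-2, square root, hence a [0,1] metric). Feature relationships are
probed by training a linear (ridge-logistic) and a tree-ensemble (bagged
CART) classifier for the event indicator on original vs synthetic data and
comparing hold-out accuracies; survival time is excluded from the
covariates because it would leak the label. This target definition is this
package's choice — the underlying study's exact classification task is not
public.

**Utility (control arm only, configurable).** Cox beta distance: the
Euclidean norm between log-hazard-ratio vectors of Efron-tied Cox fits,
with categorical covariates expanded against the shared schema so
coefficients align; non-convergence is an error, never a silent number.
Median survival distance: first-crossing-of-0.5 medians of the two
Kaplan–Meier curves; an undefined median errors by default, with an
explicit restricted-mean fallback. Survival curve distance: exact
piecewise-constant integration of `|S₁ − S₂|` on the merged step grid up
to the shorter maximum follow-up. Predicted survival distance: one
flexible parametric model per dataset — natural cubic spline (2 internal
knots at the 33rd/67th percentiles of event log-times) on the log
cumulative hazard plus linear covariate effects, maximum likelihood with a
monotonicity guard and Nelson–Aalen-based initialization — then the mean
over original patients of the mean absolute difference between the two
predicted curves on a 24-point grid up to the 0.95 follow-up quantile.

**Privacy.** Records are compared with a Gower-style mean of per-feature
distances (range-normalized absolute difference for continuous, 0/1
mismatch for categorical), ranges taken from the training data. CAP is
reported in safety orientation (1 − attribution rate) with majority-vote
attacks on key-matching synthetic records; ties break deterministically by
category order, and a missing key match counts as an attacker failure.
Detection is the stratified 5-fold cross-validated AUROC of a boosted-tree
classifier separating original from synthetic records. Two choices here
deserve emphasis. First, fold assignment is *paired* when the class sizes
match: a synthetic record that is an exact duplicate of an original (the
Dummy regime) otherwise sits in the training fold with the opposite label
and drags the AUROC far below 0.5, which would misread the most-memorizing
generator as the least detectable. Second, the booster subsamples
candidate columns at every node (the colsample idea): greedy gain search
is blind to interaction-only structure (e.g. duplicated covariates), and
without subsampling the detector cannot see precisely the kind of planted
dependence a uniform sampler destroys. DCR and NNDR are medians of
nearest-neighbour statistics against the training data, with the same
statistics computed for an untouched hold-out split as the calibration
baseline; `DCR < DCR_holdout` raises the memorization flag.

**Ranking.** Each measure ranks the generators (1 = best under its declared
orientation, ties averaged); ranks are averaged within a category and
min-max normalized to [0,1]; the overall score repeats this across all
measures. Run-level values are averaged *before* ranking — the alternative
(rank per run, then average) is equally defensible; the choice is recorded
in the report object. A complete tie normalizes to all zeros.

## The simulated cohort

The fixture emulates the structure of an advanced-NSCLC registry extract:
397 control (chemotherapy-like) and 248 active (immunotherapy-like)
patients; ten balanced binary covariates (success probabilities jittered in
[0.45, 0.55], latent Gaussian equicorrelation 0.2 so generators have
dependence to capture), one 3-level categorical, age as a truncated normal
(68 ± 9 on [40, 90]); overall survival from a Weibull
proportional-hazards model (shape 1.2, scale 16 months — control median
near 12 months, a realistic figure for advanced NSCLC under chemotherapy),
linear predictor = arm effect (log HR = log 0.65 favouring the active arm)
plus small alternating covariate effects bounded by 0.3; censoring =
uniform accrual over 57 months with an administrative cutoff 3 months
after accrual end. What the fixture does *not* emulate: the real registry's
marginal distributions, covariate meanings, or non-proportional hazards —
a green test establishes that the machinery behaves as specified on a
cohort of this shape, not that any real-data figure is reproduced.

## Known limitations

* The spline survival model assumes proportional hazards and complete
  data; competing risks and time-varying effects are out of scope.
* PrivBayes follows the standard published algorithm at summary level; no
  θ-usefulness parent-set capping, so very wide tables under small ε can
  be noise-dominated — visible in the benchmark as reduced utility.
* Privacy metrics are empirical re-identification proxies, not proofs;
  formal membership-inference auditing is out of scope.
* The CLI covers simulate/benchmark/hybrid; figure rendering is left to
  the returned tidy tables.
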