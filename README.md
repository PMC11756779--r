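# synarm — synthetic external control arms for survival trials

Single-arm drug trials often borrow a comparator ("external control arm")
from registry data, but releasing registry-level patient records carries
re-identification risk, and small high-cardinality cohorts make both privacy
and faithful synthesis hard. `synarm` implements a complete pipeline for
replacing the empirical control arm with a *synthetic* one and deciding
whether that replacement is trustworthy:

1. **Reversible data generalization** — high-cardinality continuous features
   (age, survival time) are mapped to `N` equal-frequency bins
   `x ↦ [b_n, b_{n+1})` before synthesis; afterwards each binned value is
   restored by a draw `x̂ ~ TruncNormal(μ_n, σ_n)` on its bin, with `(μ_n,
   σ_n)` estimated under ε-differential privacy via the Laplace mechanism
   (noise scale = sensitivity/ε, sensitivity `w/m` for a width-`w` bin with
   `m` patients).
2. **Generators** behind one `fit`/`sample` contract: `dummy` (replicates
   the training arm — the upper quality bound), `uniform` (uniform marginal
   sampling — the lower bound), `independent` (empirical marginals), and a
   native differentially private Bayesian network (`privbayes`: greedy
   structure search by the exponential mechanism with mutual-information
   quality, Laplace-noised conditional tables, ancestral sampling). GAN-type
   generators attach through the `external` plugin kind.
3. **Evaluation suite**:
   *resemblance* — per-feature Kolmogorov–Smirnov and Jensen–Shannon
   distances, train-on-synthetic vs train-on-original classifier agreement;
   *utility* — Cox beta distance `‖β_orig − β_synth‖₂`, Kaplan–Meier median
   survival distance, integrated survival-curve distance
   `∫|S_orig − S_synth| dt`, and a predicted-survival distance from
   spline-based proportional-hazards (Royston–Parmar-type) models;
   *privacy* — CAP categorical (safety orientation), boosted-tree detection
   AUROC, distance-to-closest-record (DCR) and nearest-neighbour distance
   ratio (NNDR) with an untouched hold-out split as the "safe distance"
   baseline and a memorization flag when `DCR < DCR_holdout`.
4. **Ranking** — per measure, generators get ranks 1..G (ties averaged);
   ranks are averaged per category and min-max normalized to [0, 1], lower
   is better.
5. **Hybrid-arm analysis** — synthetic control + original active arm;
   bootstrapped Cox hazard ratios compare the hybrid conclusion against the
   original two-arm analysis.

A simulated two-arm oncology cohort (645 patients: 397 control, 248 active;
≥75% binary covariates; Weibull survival with uniform accrual and
administrative censoring) makes every stage testable without any data
download.

## Worked example

```r
library(synarm)

cfg <- benchmark_config(
  default_nsclc_config(seed = 2),
  list(dummy     = generator_spec("dummy"),
       uniform   = generator_spec("uniform"),
       privbayes = generator_spec("privbayes", epsilon = 10)),
  n_runs = 3, seed = 42)
res <- run_benchmark(cfg)
res$rank_report
#> <rank_report> normalized rank scores (lower = better)
#>  generator resemblance utility privacy   overall
#>      dummy   0.0000000     0.0     1.0 0.0000000
#>    uniform   1.0000000     1.0     0.0 1.0000000
#>  privbayes   0.7142857     0.5     0.5 0.7142857
```

Read: `dummy` (a verbatim copy of the control arm) is the best achievable
resemblance/utility and the worst privacy; `uniform` is the reverse; the
DP Bayesian network lands in between on every axis — the sanity ordering a
healthy benchmark must reproduce.

```r
d  <- simulate_cohort(default_nsclc_config(seed = 2))
hy <- hybrid_analysis(d, generator_spec("privbayes"), n_runs = 3, B = 200,
                      seed = 9)
quantile(hy$hr_original,      c(.025, .975))   # 0.494 .. 0.724
quantile(hy$hr_hybrid_pooled, c(.025, .975))   # 0.471 .. 0.800
```

Both hazard-ratio intervals sit well below 1 and overlap substantially: the
treatment-effect conclusion survives the replacement of the control arm by
its synthetic counterpart.

## Command line

```sh
Rscript inst/cli/synarm.R simulate  --out cohort.csv
Rscript inst/cli/synarm.R benchmark --config cfg.json --outdir out/
Rscript inst/cli/synarm.R hybrid    --config cfg.json --outdir out/
```

Configs are JSON (YAML accepted when the `yaml` package is available).

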