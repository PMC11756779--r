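# End-to-end orchestration: fit -> (generalize) -> synthesize -> reverse ->
# evaluate -> rank, plus the hybrid-arm use case.

measures_meta_ <- function() {
  data.frame(
    name = c("ks_mean", "js_mean", "clf_linear_gap", "clf_forest_gap",
             "cox_beta", "median_surv", "surv_curve", "pred_surv",
             "cap", "detection", "dcr", "nndr"),
    category = rep(c("resemblance", "utility", "privacy"), each = 4L),
    orientation = c(rep("lower_better", 8L), rep("higher_better", 4L)),
    stringsAsFactors = FALSE)
}

#' Score one synthetic dataset against the training data
#'
#' Computes the full measure suite: resemblance (mean KS over continuous
#' features, mean JS over categoricals, linear and forest classifier
#' accuracy gaps), utility (Cox beta, median survival, survival curve and
#' predicted survival distances, control arm only), and privacy (CAP,
#' detection AUROC, DCR, NNDR).
#'
#' @param train Original training split the generator saw.
#' @param holdout Hold-out split (classifier evaluation, privacy baseline).
#' @param synthetic Synthetic dataset.
#' @param keys,target CAP configuration (defaults as in [privacy_report()]).
#' @param seed Integer seed.
#' @return Named numeric vector over [measures_meta()] names, with the
#'   privacy report attached as attribute `privacy`.
#' @export
evaluate_synthetic <- function(train, holdout, synthetic,
                               keys = NULL, target = NULL, seed = NULL) {
  res <- resemblance_report(train, synthetic, holdout,
                            seed = seed_child_(seed, 1L))
  covs <- covariate_names(train$schema)
  util <- c(
    cox_beta = cox_beta_distance(train, synthetic, covs),
    median_surv = median_survival_distance(train, synthetic, fallback = "rmst"),
    surv_curve = survival_curve_distance(train, synthetic),
    pred_surv = predicted_survival_distance(train, synthetic, covs))
  priv <- privacy_report(train, holdout, synthetic, keys = keys,
                         target = target, seed = seed_child_(seed, 2L))
  out <- c(res$summary[c("ks_mean", "js_mean", "clf_linear_gap",
                         "clf_forest_gap")],
           util,
           cap = priv$cap_score, detection = priv$detection_score,
           dcr = priv$dcr, nndr = priv$nndr)
  names(out) <- measures_meta_()$name
  attr(out, "privacy") <- priv
  out
}

#' @rdname evaluate_synthetic
#' @export
measures_meta <- function() measures_meta_()

#' Configure a generator benchmark
#'
#' @param dataset A two-arm `trial_dataset` (or a [cohort_config()], which is
#'   simulated on demand).
#' @param generators List of [generator_spec()]s; names label the report.
#' @param generalize Apply reversible generalization as pre/post-processing
#'   for every generator (default `TRUE`). Without it, generators needing
#'   categorical input (privbayes) fall back to fine equal-frequency binning
#'   (`fine_bins` bins) with uniform within-bin reversal — the
#'   high-cardinality route the generalization is meant to improve on.
#' @param gen_features Features to generalize; default all continuous ones.
#' @param n_bins Coarse bins per generalized feature (default 10).
#' @param gen_epsilon Laplace budget per generalized feature for the reversal
#'   parameters (default 1).
#' @param fine_bins Bins for the no-generalization fallback (default 40).
#' @param n_runs Fit/sample repetitions per generator (default 10).
#' @param holdout_fraction Control-arm hold-out fraction (default 0.2).
#' @param keys,target CAP configuration (optional).
#' @param seed Master seed.
#' @return An object of class `benchmark_config`.
#' @export
benchmark_config <- function(dataset, generators,
                             generalize = TRUE, gen_features = NULL,
                             n_bins = 10, gen_epsilon = 1, fine_bins = 40,
                             n_runs = 10, holdout_fraction = 0.2,
                             keys = NULL, target = NULL, seed = 1L) {
  check_(is_count_(n_runs), "n_runs must be >= 1")
  if (inherits(dataset, "cohort_config")) dataset <- simulate_cohort(dataset)
  check_(inherits(dataset, "trial_dataset"), "dataset must be a trial_dataset")
  check_(length(generators) >= 1L &&
           all(vapply(generators, inherits, TRUE, "generator_spec")),
         "generators must be generator_spec objects")
  if (is.null(names(generators)) || any(!nzchar(names(generators))))
    names(generators) <- vapply(generators, `[[`, "", "name")
  check_(!anyDuplicated(names(generators)), "generator names must be unique")
  structure(as.list(environment()), class = "benchmark_config")
}

# Fit + sample + reverse for one generator run. Returns the synthetic
# trial_dataset in the original (continuous) representation.
synthesize_once_ <- function(spec, train, cfg, seed) {
  needs_cat <- spec$kind == "privbayes"
  if (cfg$generalize) {
    map <- fit_generalization_map(train, features = cfg$gen_features,
                                  n_bins = cfg$n_bins,
                                  budget = privacy_budget(cfg$gen_epsilon),
                                  reversal = "truncnorm",
                                  seed = seed_child_(seed, 1L))
  } else if (needs_cat) {
    map <- fit_generalization_map(train, features = cfg$gen_features,
                                  n_bins = cfg$fine_bins,
                                  reversal = "uniform",
                                  seed = seed_child_(seed, 1L))
  } else map <- NULL
  train_in <- if (is.null(map)) train else generalize(train, map)
  g <- fit_generator(spec, train_in, seed = seed_child_(seed, 2L))
  syn <- sample_generator(g, n_patients(train), seed = seed_child_(seed, 3L))
  if (!is.null(map)) syn <- reverse_generalize(syn, map,
                                               seed = seed_child_(seed, 4L))
  list(synthetic = syn, epsilon_generalization = if (is.null(map)) 0
       else map$epsilon_total,
       epsilon_generator = if (spec$kind == "privbayes")
         spec$hyperparameters$epsilon else NA_real_)
}

#' Run the full generator benchmark
#'
#' For each generator and run: fit on the (optionally generalized) control
#' arm training split, sample `n = |train|` records, reverse the
#' generalization, and score with the full measure suite. Run-level values
#' are averaged into a [metric_matrix()] and ranked with
#' [aggregate_ranks()]. A failed (generator, run) is recorded in the
#' manifest and excluded from the averages with a warning, never imputed.
#'
#' @param cfg A [benchmark_config()].
#' @return An object of class `benchmark_result`: `metric_matrix`,
#'   `rank_report`, `runs` (long data frame), `manifest`, `train`, `holdout`.
#' @export
run_benchmark <- function(cfg) {
  check_(inherits(cfg, "benchmark_config"), "cfg must be a benchmark_config")
  arms <- arm_split(cfg$dataset)
  control <- arms[[1L]]
  parts <- split_holdout(control, cfg$holdout_fraction,
                         seed = seed_child_(cfg$seed, 999L))
  train <- parts$train; holdout <- parts$holdout
  meta <- measures_meta_()
  gnames <- names(cfg$generators)
  runs <- list(); manifest <- list()
  for (gi in seq_along(cfg$generators)) {
    spec <- cfg$generators[[gi]]
    for (r in seq_len(cfg$n_runs)) {
      seed_gr <- seed_child_(cfg$seed, gi * 1000L + r)
      t0 <- proc.time()[["elapsed"]]
      out <- tryCatch({
        syn <- synthesize_once_(spec, train, cfg, seed_gr)
        vals <- evaluate_synthetic(train, holdout, syn$synthetic,
                                   keys = cfg$keys, target = cfg$target,
                                   seed = seed_child_(seed_gr, 5L))
        list(vals = vals, eps = syn$epsilon_generalization, status = "ok")
      }, error = function(e) list(vals = NULL, eps = NA_real_,
                                  status = conditionMessage(e)))
      manifest[[length(manifest) + 1L]] <- data.frame(
        generator = gnames[gi], run = r, seed = seed_gr,
        epsilon_generalization = out$eps, status = out$status,
        wall_time = proc.time()[["elapsed"]] - t0)
      if (!is.null(out$vals))
        runs[[length(runs) + 1L]] <- data.frame(
          generator = gnames[gi], run = r, measure = meta$name,
          value = unname(out$vals))
      else
        warning(sprintf("generator '%s' run %d failed (%s); excluded from averages",
                        gnames[gi], r, out$status))
    }
  }
  check_(length(runs) > 0L, "every benchmark run failed")
  runs <- do.call(rbind, runs)
  manifest <- do.call(rbind, manifest)
  ok_gen <- intersect(gnames, unique(runs$generator))
  if (length(ok_gen) < length(gnames))
    warning(sprintf("generator(s) dropped (no successful run): %s",
                    paste(setdiff(gnames, ok_gen), collapse = ", ")))
  avg <- stats::aggregate(value ~ generator + measure, data = runs, FUN = mean)
  values <- matrix(NA_real_, length(ok_gen), nrow(meta),
                   dimnames = list(ok_gen, meta$name))
  for (i in seq_len(nrow(avg)))
    values[avg$generator[i], avg$measure[i]] <- avg$value[i]
  mm <- metric_matrix(values, meta, ok_gen)
  rr <- if (length(ok_gen) >= 2L) aggregate_ranks(mm) else NULL
  structure(list(metric_matrix = mm, rank_report = rr,
                 runs = runs, manifest = manifest,
                 train = train, holdout = holdout, config = cfg),
            class = "benchmark_result")
}

#' Build a hybrid dataset: synthetic control arm + original active arm
#'
#' @param synthetic_control Synthetic control-arm `trial_dataset` (all rows
#'   carrying the control arm label).
#' @param original_active Original active-arm `trial_dataset`.
#' @return The row-concatenated `trial_dataset`; the original control arm is
#'   excluded by construction.
#' @export
build_hybrid <- function(synthetic_control, original_active) {
  s1 <- synthetic_control$schema; s2 <- original_active$schema
  check_(identical(names(s1), names(s2)) &&
           identical(schema_types_(s1), schema_types_(s2)),
         "schemas of the two arms do not match")
  ac <- arm_col_(s1)
  lv <- s1[[ac]]$categories
  check_(all(synthetic_control$data[[ac]] == lv[1L]),
         "synthetic control arm must carry the control arm label")
  check_(all(original_active$data[[ac]] == lv[2L]),
         "active arm must carry the active arm label")
  trial_dataset(rbind(synthetic_control$data, original_active$data), s1)
}

#' Bootstrapped Cox hazard ratios for the arm effect
#'
#' Case-resamples the dataset `B` times and refits a Cox model with the arm
#' as single covariate; returns the exponentiated coefficients. A resample
#' with zero events or a single arm is redrawn (at most 10 attempts).
#'
#' @param d A two-arm `trial_dataset`.
#' @param B Number of bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @return Numeric vector of `B` hazard ratios, with the point-estimate HR as
#'   attribute `point`.
#' @export
bootstrap_hazard_ratios <- function(d, B, seed = NULL) {
  check_(is_count_(B), "B must be >= 1")
  sch <- d$schema
  ac <- arm_col_(sch)
  tt <- d$data[[surv_col_(sch)]]
  ev <- as.numeric(d$data[[event_col_(sch)]] == "1")
  arm <- as.numeric(d$data[[ac]] == sch[[ac]]$categories[2L])
  hr_of <- function(idx) {
    if (sum(ev[idx]) == 0 || length(unique(arm[idx])) < 2L) return(NA_real_)
    fit <- suppressWarnings(survival::coxph(
      survival::Surv(tt[idx], ev[idx]) ~ arm[idx], ties = "efron"))
    exp(unname(coef(fit)))
  }
  point <- hr_of(seq_along(tt))
  hrs <- with_seed_(seed, vapply(seq_len(B), function(b) {
    for (attempt in 1:10) {
      hr <- hr_of(sample.int(length(tt), replace = TRUE))
      if (is.finite(hr)) return(hr)
    }
    abort_("bootstrap resample degenerate after 10 attempts",
           "synarm_convergence_error")
  }, numeric(1L)))
  attr(hrs, "point") <- point
  hrs
}

average_km_ <- function(curves) {
  grid <- sort(unique(unlist(lapply(curves, function(c) c(0, c$times)))))
  vals <- vapply(curves, surv_at, numeric(length(grid)), t = grid)
  list(times = grid, survival = rowMeans(vals))
}

#' Hybrid-arm use case: KM curves and hazard-ratio histograms
#'
#' Repeats synthetic-control generation `n_runs` times with a single
#' generator, and for each run derives the synthetic-control KM curve and the
#' bootstrapped hazard ratios of the hybrid dataset (synthetic control +
#' original active arm). Also reports the averaged synthetic KM curve
#' (pointwise mean on the merged grid) and the original-data bootstrap as
#' reference.
#'
#' @param d A two-arm `trial_dataset`.
#' @param spec A [generator_spec()].
#' @param n_runs Generation repetitions (default 10).
#' @param B Bootstrap replicates per histogram (default 500).
#' @param generalize,n_bins,gen_epsilon Generalization settings as in
#'   [benchmark_config()].
#' @param seed Master seed.
#' @return An object of class `hybrid_result`.
#' @export
hybrid_analysis <- function(d, spec, n_runs = 10, B = 500,
                            generalize = TRUE, n_bins = 10, gen_epsilon = 1,
                            seed = 1L) {
  arms <- arm_split(d)
  control <- arms[[1L]]; active <- arms[[2L]]
  cfg <- benchmark_config(d, list(spec), generalize = generalize,
                          n_bins = n_bins, gen_epsilon = gen_epsilon,
                          n_runs = n_runs, seed = seed)
  curves <- list(); hr_hybrid <- list()
  ac <- arm_col_(d$schema)
  ctl_label <- d$schema[[ac]]$categories[1L]
  for (r in seq_len(n_runs)) {
    seed_r <- seed_child_(seed, 5000L + r)
    syn <- synthesize_once_(spec, control, cfg, seed_r)$synthetic
    # the arm column is structural bookkeeping: a synthetic control record
    # is a control record by construction (DP noise can flip the label)
    syn$data[[ac]] <- factor(ctl_label, levels = d$schema[[ac]]$categories)
    curves[[r]] <- km_from_dataset_(syn)
    hyb <- build_hybrid(syn, active)
    hr_hybrid[[r]] <- bootstrap_hazard_ratios(hyb, B,
                                              seed = seed_child_(seed_r, 9L))
  }
  structure(list(
    control_curve = km_from_dataset_(control),
    synthetic_curves = curves,
    synthetic_curve_avg = average_km_(curves),
    hr_original = bootstrap_hazard_ratios(d, B, seed = seed_child_(seed, 7L)),
    hr_hybrid = hr_hybrid,
    hr_hybrid_pooled = unlist(hr_hybrid),
    B = B, n_runs = n_runs, generator = spec$name),
    class = "hybrid_result")
}
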