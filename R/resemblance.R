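# Statistical similarity between synthetic and original data: univariate
# Kolmogorov-Smirnov / Jensen-Shannon comparisons plus a train-on-synthetic
# classifier-agreement check.

#' Kolmogorov-Smirnov statistic between two samples
#'
#' Supremum distance between the two empirical CDFs; 0 for identical
#' distributions, 1 for disjoint supports.
#'
#' @param a,b Non-empty numeric vectors.
#' @return A value in \[0, 1\].
#' @export
ks_statistic <- function(a, b) {
  check_(is.numeric(a) && length(a) > 0L, "a must be a non-empty numeric vector")
  check_(is.numeric(b) && length(b) > 0L, "b must be a non-empty numeric vector")
  pts <- sort(unique(c(a, b)))
  Fa <- stats::ecdf(a)(pts)
  Fb <- stats::ecdf(b)(pts)
  max(abs(Fa - Fb))
}

#' Jensen-Shannon distance between two probability vectors
#'
#' Square root of the base-2 Jensen-Shannon divergence, a metric on
#' probability vectors with range \[0, 1\].
#'
#' @param p,q Probability vectors over the same support, each summing to 1
#'   (tolerance 1e-9).
#' @return A value in \[0, 1\].
#' @export
js_distance <- function(p, q) {
  check_(length(p) == length(q), "p and q must share support length")
  check_(all(p >= 0) && all(q >= 0), "probabilities must be non-negative")
  check_(abs(sum(p) - 1) < 1e-9 && abs(sum(q) - 1) < 1e-9,
         "p and q must each sum to 1")
  m <- (p + q) / 2
  kl <- function(x, y) {
    nz <- x > 0
    sum(x[nz] * log2(x[nz] / y[nz]))
  }
  jsd <- 0.5 * kl(p, m) + 0.5 * kl(q, m)
  sqrt(max(0, min(1, jsd)))
}

category_freqs_ <- function(d, feature) {
  tab <- tabulate(d$data[[feature]],
                  nbins = length(d$schema[[feature]]$categories))
  tab / sum(tab)
}

#' Train-on-original vs train-on-synthetic classifier agreement
#'
#' Fits a linear (logistic) and a tree-ensemble (bagged forest) classifier
#' for the event indicator on the original and the synthetic data, evaluates
#' all four on the hold-out, and reports the absolute accuracy gap per model
#' family. Survival time is excluded from the covariates (it would leak the
#' label); the arm column is likewise excluded.
#'
#' @param original,synthetic,holdout `trial_dataset`s sharing a schema.
#' @param seed Integer seed for the forest fits.
#' @return List with `linear` and `forest`, each
#'   `c(original =, synthetic =, gap =)` accuracies, plus `majority_rate`.
#' @export
classifier_agreement <- function(original, synthetic, holdout, seed = NULL) {
  sch <- original$schema
  target <- event_col_(sch)
  covs <- covariate_names(sch)
  enc <- function(d) encode_features_(d, covs)
  yy <- function(d) as.numeric(d$data[[target]] == "1")
  y_o <- yy(original); y_s <- yy(synthetic); y_h <- yy(holdout)
  check_(length(unique(y_o)) == 2L && length(unique(y_s)) == 2L,
         "single-class event indicator in a training set")
  Xo <- enc(original); Xs <- enc(synthetic); Xh <- enc(holdout)
  acc <- function(p) mean((p > 0.5) == y_h)
  lin_o <- acc(logistic_predict_(logistic_fit_(Xo, y_o), Xh))
  lin_s <- acc(logistic_predict_(logistic_fit_(Xs, y_s), Xh))
  rf_o <- acc(forest_predict_(forest_fit_(Xo, y_o,
                                          seed = seed_child_(seed, 1L)), Xh))
  rf_s <- acc(forest_predict_(forest_fit_(Xs, y_s,
                                          seed = seed_child_(seed, 2L)), Xh))
  list(linear = c(original = lin_o, synthetic = lin_s, gap = abs(lin_o - lin_s)),
       forest = c(original = rf_o, synthetic = rf_s, gap = abs(rf_o - rf_s)),
       majority_rate = max(mean(y_h), 1 - mean(y_h)))
}

#' Full resemblance report
#'
#' Per-feature KS statistics (continuous features) and JS distances
#' (categorical features, over the schema's category frequencies), plus the
#' classifier-agreement accuracies when a hold-out is supplied. The arm
#' column is skipped (constant within a single-arm dataset).
#'
#' @param original,synthetic `trial_dataset`s sharing a schema.
#' @param holdout Optional `trial_dataset` for classifier agreement.
#' @param seed Integer seed.
#' @return An object of class `resemblance_report`: `per_feature` (tidy data
#'   frame), `classifier`, and `summary` (named vector: `ks_mean`, `js_mean`,
#'   and classifier gaps).
#' @export
resemblance_report <- function(original, synthetic, holdout = NULL,
                               seed = NULL) {
  sch <- original$schema
  feats <- setdiff(names(sch), arm_col_(sch))
  rows <- lapply(feats, function(f) {
    if (sch[[f]]$ftype == "continuous") {
      data.frame(feature = f, metric = "ks",
                 value = ks_statistic(original$data[[f]], synthetic$data[[f]]))
    } else {
      data.frame(feature = f, metric = "js",
                 value = js_distance(category_freqs_(original, f),
                                     category_freqs_(synthetic, f)))
    }
  })
  per_feature <- do.call(rbind, rows)
  ks_vals <- per_feature$value[per_feature$metric == "ks"]
  js_vals <- per_feature$value[per_feature$metric == "js"]
  clf <- if (!is.null(holdout))
    classifier_agreement(original, synthetic, holdout, seed = seed)
  summary <- c(ks_mean = if (length(ks_vals)) mean(ks_vals) else NA_real_,
               js_mean = if (length(js_vals)) mean(js_vals) else NA_real_,
               clf_linear_gap = if (!is.null(clf)) unname(clf$linear["gap"]) else NA_real_,
               clf_forest_gap = if (!is.null(clf)) unname(clf$forest["gap"]) else NA_real_)
  structure(list(per_feature = per_feature, classifier = clf,
                 summary = summary),
            class = "resemblance_report")
}
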