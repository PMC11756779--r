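# Reversible data generalization: quantile binning before synthesis, and a
# differentially private truncated-normal reversal after synthesis.

bin_labels_ <- function(edges) {
  n <- length(edges) - 1L
  lab <- sprintf("[%.15g,%.15g)", edges[-length(edges)], edges[-1L])
  lab[n] <- sprintf("[%.15g,%.15g]", edges[n], edges[n + 1L])
  lab
}

#' Bin specification for one continuous feature
#'
#' Edges `b_0 < b_1 < ... < b_N` define `N` half-open bins `[b_n, b_{n+1})`;
#' the top bin is closed on the right so the observed maximum is
#' representable.
#'
#' @param feature Feature name.
#' @param edges Strictly increasing numeric vector of length `N + 1`.
#' @param strategy `"quantile"` or `"explicit"`.
#' @return An object of class `bin_spec` with the generated bin labels.
#' @export
bin_spec <- function(feature, edges, strategy = c("explicit", "quantile")) {
  strategy <- match.arg(strategy)
  check_(is.numeric(edges) && length(edges) >= 2L && all(is.finite(edges)),
         "edges must be a finite numeric vector of length >= 2")
  check_(all(diff(edges) > 0), "edges must be strictly increasing")
  structure(list(feature = feature, edges = as.numeric(edges),
                 n_bins = length(edges) - 1L, labels = bin_labels_(edges),
                 strategy = strategy),
            class = "bin_spec")
}

#' Fit equal-frequency bins from empirical quantiles
#'
#' Edges sit at the `0, 1/N, ..., 1` empirical quantiles so each bin holds
#' roughly the same number of samples. Duplicate edges (too few distinct
#' values) are collapsed with a warning, reducing the bin count.
#'
#' @param values Numeric vector of observed feature values.
#' @param n_bins Requested number of bins (`N >= 1`).
#' @param feature Name recorded in the returned spec.
#' @return A [bin_spec()].
#' @export
fit_quantile_bins <- function(values, n_bins, feature = "x") {
  check_(is.numeric(values) && length(values) > 0L, "values must be non-empty")
  check_(is_count_(n_bins), "n_bins must be a positive integer")
  probs <- seq(0, 1, length.out = n_bins + 1L)
  edges <- unname(stats::quantile(values, probs = probs, type = 7))
  uedges <- unique(edges)
  if (length(uedges) < length(edges)) {
    warning(sprintf("feature '%s': duplicate quantile edges collapsed (%d -> %d bins)",
                    feature, n_bins, max(1L, length(uedges) - 1L)))
    edges <- uedges
  }
  if (length(edges) == 1L) edges <- c(edges, edges + max(1e-8, abs(edges) * 1e-8))
  bin_spec(feature, edges, strategy = "quantile")
}

bin_index_ <- function(x, spec) {
  e <- spec$edges
  out <- which(x < e[1L] | x > e[length(e)])
  if (length(out))
    abort_(sprintf("feature '%s': value %g in row %d outside [%g, %g]",
                   spec$feature, x[out[1L]], out[1L], e[1L], e[length(e)]),
           "synarm_validation_error")
  idx <- findInterval(x, e, rightmost.closed = TRUE)
  pmin(pmax(idx, 1L), spec$n_bins)
}

#' Generalize continuous features into ordered bins
#'
#' Each listed feature becomes a categorical column whose levels are the bin
#' interval labels; all other columns are untouched. The inverse operation is
#' [reverse_generalize()].
#'
#' @param d A `trial_dataset`.
#' @param specs A single [bin_spec()] or list of them (or a
#'   `generalization_map`, whose specs are used).
#' @return A `trial_dataset` with binned columns and an updated schema.
#' @export
generalize <- function(d, specs) {
  if (inherits(specs, "generalization_map")) specs <- specs$specs
  if (inherits(specs, "bin_spec")) specs <- list(specs)
  data <- d$data
  schema <- unclass(d$schema)
  for (sp in specs) {
    f <- sp$feature
    check_(f %in% names(schema), sprintf("unknown feature '%s'", f))
    check_(schema[[f]]$ftype == "continuous",
           sprintf("feature '%s' is not continuous", f))
    idx <- bin_index_(data[[f]], sp)
    data[[f]] <- factor(sp$labels[idx], levels = sp$labels)
    schema[[f]] <- schema_feature(f, ftype = "categorical",
                                  role = schema[[f]]$role,
                                  categories = sp$labels,
                                  binned_from = "continuous")
  }
  trial_dataset(data, structure(schema, class = "trial_schema"))
}

#' Privacy budget for the reversal parameters
#'
#' @param epsilon Total epsilon spent per generalized feature (> 0; `Inf`
#'   disables noise).
#' @param split Proportions allocated to mean vs. sd estimation; must sum
#'   to 1.
#' @return An object of class `privacy_budget`.
#' @export
privacy_budget <- function(epsilon, split = c(mean = 0.5, sd = 0.5)) {
  check_(is.numeric(epsilon) && length(epsilon) == 1L && epsilon > 0,
         "epsilon must be a positive real")
  check_(is.numeric(split) && length(split) == 2L && all(split > 0) &&
           abs(sum(split) - 1) < 1e-9, "split proportions must sum to 1")
  structure(list(epsilon = epsilon, split = unname(split)),
            class = "privacy_budget")
}

#' The Laplace mechanism
#'
#' Adds `Laplace(0, sensitivity / epsilon)` noise to a scalar statistic,
#' yielding epsilon-differential privacy for a statistic of the stated
#' sensitivity.
#'
#' @param value Scalar statistic.
#' @param sensitivity L1 sensitivity of the statistic (> 0).
#' @param epsilon Privacy budget (> 0; `Inf` returns `value` unchanged).
#' @param seed Optional integer seed.
#' @return `value` plus one Laplace draw.
#' @export
laplace_noise <- function(value, sensitivity, epsilon, seed = NULL) {
  check_(is.numeric(sensitivity) && length(sensitivity) == 1L && sensitivity > 0,
         "sensitivity must be positive")
  check_(is.numeric(epsilon) && length(epsilon) == 1L && epsilon > 0,
         "epsilon must be positive")
  if (is.infinite(epsilon)) return(value)
  value + with_seed_(seed, rlaplace_(length(value), sensitivity / epsilon))
}

sd_floor_ <- function(width) width * 1e-3

#' Differentially private truncated-normal parameters for one bin
#'
#' Estimates the in-bin mean and standard deviation, perturbing each with the
#' Laplace mechanism at sensitivity `w / m` (`w` = bin width, `m` = bin
#' count) and its share of the budget. The mean is clamped to the bin, the sd
#' to `[w * 1e-3, w]`. An empty bin gets the uniform fallback: midpoint mean,
#' `w / sqrt(12)` spread, `empty_flag = TRUE`.
#'
#' @param values_in_bin Numeric values falling in the bin (may be empty).
#' @param support Length-2 numeric `c(lo, hi)`, a bounded interval.
#' @param budget A [privacy_budget()].
#' @param seed Optional integer seed.
#' @return An object of class `bin_params`.
#' @export
estimate_bin_params_dp <- function(values_in_bin, support, budget, seed = NULL) {
  check_(is.numeric(support) && length(support) == 2L && all(is.finite(support)) &&
           support[2L] > support[1L], "support must be a bounded interval")
  check_(inherits(budget, "privacy_budget"), "budget must be a privacy_budget")
  w <- diff(support)
  m <- length(values_in_bin)
  if (m == 0L) {
    return(structure(list(mean = mean(support), sd = w / sqrt(12),
                          support = support, empty_flag = TRUE, m = 0L),
                     class = "bin_params"))
  }
  check_(all(values_in_bin >= support[1L] & values_in_bin <= support[2L]),
         "values must lie inside the support")
  eps_mean <- budget$epsilon * budget$split[1L]
  eps_sd <- budget$epsilon * budget$split[2L]
  sens <- w / m
  mu <- laplace_noise(mean(values_in_bin), sens, eps_mean,
                      seed = seed_child_(seed, 1L))
  s0 <- if (m > 1L) stats::sd(values_in_bin) else 0
  s <- laplace_noise(s0, sens, eps_sd, seed = seed_child_(seed, 2L))
  structure(list(mean = clamp_(mu, support[1L], support[2L]),
                 sd = clamp_(s, sd_floor_(w), w),
                 support = support, empty_flag = FALSE, m = m),
            class = "bin_params")
}

#' Fit the full reversible-generalization state for a dataset
#'
#' For each selected continuous feature: fit quantile bins, then estimate
#' per-bin truncated-normal parameters under the Laplace mechanism. Because
#' bins partition the patients, parallel composition applies: each feature
#' spends `budget$epsilon` once, not once per bin.
#'
#' @param d A `trial_dataset` (original, pre-synthesis values).
#' @param features Character vector of continuous features to generalize;
#'   default: every continuous feature (covariates and survival time).
#' @param n_bins Bins per feature (default 10).
#' @param budget A [privacy_budget()] per feature (default epsilon 1).
#' @param reversal `"truncnorm"` (DP-estimated parameters) or `"uniform"`
#'   (uniform within-bin reversal, no epsilon spent).
#' @param seed Optional integer seed for the Laplace draws.
#' @return An object of class `generalization_map` with elements `specs`,
#'   `params`, `budget`, `reversal`, `epsilon_per_feature`, `epsilon_total`,
#'   `seed`.
#' @export
fit_generalization_map <- function(d, features = NULL, n_bins = 10,
                                   budget = privacy_budget(1),
                                   reversal = c("truncnorm", "uniform"),
                                   seed = NULL) {
  reversal <- match.arg(reversal)
  if (is.null(features)) features <- continuous_names_(d$schema)
  check_(length(features) > 0L, "no continuous features to generalize")
  specs <- list(); params <- list()
  for (j in seq_along(features)) {
    f <- features[j]
    check_(f %in% names(d$schema) && d$schema[[f]]$ftype == "continuous",
           sprintf("feature '%s' is not a continuous column", f))
    x <- d$data[[f]]
    sp <- fit_quantile_bins(x, n_bins, feature = f)
    idx <- bin_index_(x, sp)
    pp <- vector("list", sp$n_bins)
    for (b in seq_len(sp$n_bins)) {
      supp <- c(sp$edges[b], sp$edges[b + 1L])
      if (reversal == "uniform") {
        pp[[b]] <- structure(list(mean = mean(supp), sd = diff(supp) / sqrt(12),
                                  support = supp, empty_flag = TRUE,
                                  m = sum(idx == b)),
                             class = "bin_params")
      } else {
        pp[[b]] <- estimate_bin_params_dp(x[idx == b], supp, budget,
                                          seed = seed_child_(seed, j * 1000L + b))
      }
    }
    names(pp) <- sp$labels
    specs[[f]] <- sp
    params[[f]] <- pp
  }
  eps_feature <- if (reversal == "uniform") 0 else budget$epsilon
  structure(list(specs = specs, params = params, budget = budget,
                 reversal = reversal,
                 epsilon_per_feature = eps_feature,
                 epsilon_total = eps_feature * length(features),
                 seed = seed),
            class = "generalization_map")
}

#' Reverse a generalization: restore continuous values inside each bin
#'
#' Every binned value is replaced by a draw from its bin's distribution:
#' truncated normal with the map's DP-estimated parameters, or uniform for
#' bins flagged empty (and for maps fitted with `reversal = "uniform"`).
#' Sampled values always lie inside their source bin, so re-generalizing
#' reproduces the bin labels exactly; survival times are additionally clamped
#' non-negative.
#'
#' @param d_binned A `trial_dataset` whose listed features carry bin labels.
#' @param map A [fit_generalization_map()] result.
#' @param seed Optional integer seed.
#' @return A `trial_dataset` with the features restored to continuous.
#' @export
reverse_generalize <- function(d_binned, map, seed = NULL) {
  data <- d_binned$data
  schema <- unclass(d_binned$schema)
  with_seed_(seed, {
    for (f in names(map$specs)) {
      sp <- map$specs[[f]]
      check_(f %in% names(schema), sprintf("unknown feature '%s'", f))
      lab <- as.character(data[[f]])
      unknown <- which(!(lab %in% sp$labels))
      if (length(unknown))
        abort_(sprintf("feature '%s': bin label '%s' absent from map",
                       f, lab[unknown[1L]]), "synarm_validation_error")
      out <- numeric(length(lab))
      for (b in seq_len(sp$n_bins)) {
        rows <- which(lab == sp$labels[b])
        if (!length(rows)) next
        p <- map$params[[f]][[b]]
        lo <- p$support[1L]; hi <- p$support[2L]
        out[rows] <- if (p$empty_flag) runif(length(rows), lo, hi)
        else rtruncnorm_(length(rows), p$mean, p$sd, lo, hi)
      }
      if (schema[[f]]$role == "survival_time") out <- pmax(out, 0)
      data[[f]] <- out
      schema[[f]] <- schema_feature(f, ftype = "continuous",
                                    role = schema[[f]]$role)
    }
  })
  trial_dataset(data, structure(schema, class = "trial_schema"))
}

#' Serialize / restore a generalization map
#'
#' Writes the edges, per-bin parameters and epsilon accounting as JSON for
#' audit and replay.
#'
#' @param map A `generalization_map`.
#' @param path Output file path.
#' @export
write_generalization_map <- function(map, path) {
  ser <- list(reversal = map$reversal,
              epsilon_per_feature = map$epsilon_per_feature,
              epsilon_total = map$epsilon_total,
              features = lapply(names(map$specs), function(f) {
                sp <- map$specs[[f]]
                list(feature = f, edges = sp$edges, strategy = sp$strategy,
                     bins = lapply(map$params[[f]], function(p)
                       list(mean = p$mean, sd = p$sd, support = p$support,
                            empty = p$empty_flag, m = p$m)))
              }))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
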