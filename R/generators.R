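# Generator contract: fit(spec, data, seed) -> fitted_generator;
# sample(fitted, n, seed) -> trial_dataset validating against the training
# schema. External (e.g. GAN-family) generators attach through the same
# contract via the "external" kind; their internals are out of scope here.

#' Describe a synthetic-data generator
#'
#' @param kind One of `"dummy"` (replicates the training data; upper quality
#'   bound), `"uniform"` (uniform marginal sampling; lower bound),
#'   `"independent"` (empirical marginal sampling), `"privbayes"`
#'   (differentially private Bayesian network), `"external"` (plugin).
#' @param ... Hyperparameters. For `privbayes`: `k` (max parents, default 2),
#'   `epsilon` (total budget, default 10), `structure_share` (fraction of
#'   epsilon spent on structure learning, default 0.5). For `external`:
#'   `entry_point`, a `function(d, seed)` returning a list with a
#'   `sample(n, seed)` function.
#' @param name Label used in reports; defaults to `kind`.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(kind = c("dummy", "uniform", "independent",
                                    "privbayes", "external"),
                           ..., name = NULL) {
  kind <- match.arg(kind)
  hp <- list(...)
  if (kind == "privbayes") {
    hp$k <- hp$k %||% 2L
    hp$epsilon <- hp$epsilon %||% 10
    hp$structure_share <- hp$structure_share %||% 0.5
    check_(is.numeric(hp$epsilon) && hp$epsilon > 0, "epsilon must be > 0")
    check_(is.numeric(hp$k) && hp$k >= 0, "k must be >= 0")
  }
  if (kind == "external")
    check_(is.function(hp$entry_point),
           "external generator needs an entry_point function(d, seed)")
  structure(list(kind = kind, hyperparameters = hp, name = name %||% kind),
            class = "generator_spec")
}

#' Fit a generator to a trial dataset
#'
#' @param spec A [generator_spec()].
#' @param d A validated `trial_dataset`. For `privbayes` every feature must be
#'   categorical; generalize continuous features first (see
#'   [fit_generalization_map()]).
#' @param seed Integer seed; fitting is deterministic under `(spec, d, seed)`.
#' @return An object of class `fitted_generator`.
#' @export
fit_generator <- function(spec, d, seed = NULL) {
  check_(inherits(spec, "generator_spec"), "spec must be a generator_spec")
  check_(inherits(d, "trial_dataset"), "d must be a trial_dataset")
  state <- switch(spec$kind,
    dummy = list(data = d$data),
    uniform = list(supports = lapply(names(d$schema), function(f) {
      col <- d$data[[f]]
      if (is.numeric(col)) range(col)
      else levels(col)[tabulate(col, nbins = nlevels(col)) > 0]
    }) |> setNames(names(d$schema))),
    independent = list(marginals = lapply(names(d$schema), function(f) {
      col <- d$data[[f]]
      if (is.numeric(col)) col else table(col) / length(col)
    }) |> setNames(names(d$schema))),
    privbayes = {
      cont <- continuous_names_(d$schema)
      if (length(cont))
        abort_(paste0("privbayes requires categorical features only; ",
                      "generalize continuous feature(s) first: ",
                      paste(cont, collapse = ", ")), "synarm_argument_error")
      hp <- spec$hyperparameters
      eps_s <- hp$epsilon * hp$structure_share
      eps_p <- hp$epsilon * (1 - hp$structure_share)
      model <- fit_privbayes_structure(d, k = hp$k, epsilon_structure = eps_s,
                                       seed = seed_child_(seed, 1L))
      model <- fit_privbayes_conditionals(d, model, epsilon_params = eps_p,
                                          seed = seed_child_(seed, 2L))
      list(model = model, epsilon_total = eps_s + eps_p)
    },
    external = list(plugin = spec$hyperparameters$entry_point(d, seed)),
    abort_(sprintf("unknown generator kind '%s'", spec$kind),
           "synarm_argument_error")
  )
  structure(list(spec = spec, schema = d$schema, state = state,
                 n_train = n_patients(d), fit_seed = seed),
            class = c(paste0("fitted_", spec$kind), "fitted_generator"))
}

#' Sample synthetic records from a fitted generator
#'
#' @param g A [fit_generator()] result.
#' @param n Number of records (>= 1).
#' @param seed Integer seed; sampling is reproducible under it.
#' @return A `trial_dataset` validating against the training schema.
#' @export
sample_generator <- function(g, n, seed = NULL) {
  check_(inherits(g, "fitted_generator"), "g must be a fitted_generator")
  check_(is_count_(n), "n must be a positive integer")
  UseMethod("sample_generator")
}

#' @export
sample_generator.fitted_dummy <- function(g, n, seed = NULL) {
  df <- if (n == g$n_train) g$state$data
  else g$state$data[with_seed_(seed, sample.int(g$n_train, n, replace = TRUE)),
                    , drop = FALSE]
  trial_dataset(df, g$schema)
}

#' @export
sample_generator.fitted_uniform <- function(g, n, seed = NULL) {
  df <- with_seed_(seed, {
    cols <- lapply(names(g$schema), function(f) {
      supp <- g$state$supports[[f]]
      if (is.numeric(supp)) runif(n, supp[1L], supp[2L])
      else sample(supp, n, replace = TRUE)
    })
    as.data.frame(setNames(cols, names(g$schema)), stringsAsFactors = FALSE)
  })
  trial_dataset(df, g$schema)
}

#' @export
sample_generator.fitted_independent <- function(g, n, seed = NULL) {
  df <- with_seed_(seed, {
    cols <- lapply(names(g$schema), function(f) {
      m <- g$state$marginals[[f]]
      if (is.numeric(m) && is.null(dimnames(m))) sample(m, n, replace = TRUE)
      else sample(names(m), n, replace = TRUE, prob = as.numeric(m))
    })
    as.data.frame(setNames(cols, names(g$schema)), stringsAsFactors = FALSE)
  })
  trial_dataset(df, g$schema)
}

#' @export
sample_generator.fitted_privbayes <- function(g, n, seed = NULL) {
  sample_bayesnet(g$state$model, n, seed = seed, schema = g$schema)
}

#' @export
sample_generator.fitted_external <- function(g, n, seed = NULL) {
  df <- g$state$plugin$sample(n, seed)
  if (inherits(df, "trial_dataset")) df <- df$data
  out <- trial_dataset(as.data.frame(df), g$schema)
  check_(n_patients(out) == n, "external generator returned wrong row count")
  out
}
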