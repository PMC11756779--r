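# Differentially private Bayesian network over categorical features, in the
# standard published form: greedy structure search where each (node, parent
# set) pair is drawn by the exponential mechanism with mutual-information
# quality, then Laplace-noised conditional tables, then ancestral sampling.

codes_ <- function(d) {
  # integer category codes, one column per feature
  vapply(d$data, as.integer, integer(n_patients(d)))
}

card_ <- function(schema) {
  vapply(schema, function(f) length(f$categories), integer(1L))
}

# Parent-configuration index in 1..prod(card[parents]) from code matrix.
config_index_ <- function(X, parents, card) {
  if (!length(parents)) return(rep(1L, nrow(X)))
  idx <- rep(1L, nrow(X)); stride <- 1L
  for (p in parents) {
    idx <- idx + (X[, p] - 1L) * stride
    stride <- stride * card[p]
  }
  idx
}

# Empirical mutual information I(X; parents) in bits (plug-in estimator).
mi_bits_ <- function(xi, a, cfg, b) {
  n <- length(xi)
  joint <- tabulate((cfg - 1L) * a + xi, nbins = a * b) / n
  px <- tabulate(xi, nbins = a) / n
  pc <- tabulate(cfg, nbins = b) / n
  pp <- outer(px, pc)
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / pp[nz]))
}

# Sensitivity of plug-in MI under one-record change (standard bound, bits).
mi_sensitivity_ <- function(n) {
  log2(n) / n + (n - 1) / n * log2(n / (n - 1))
}

# Exponential mechanism over candidate qualities.
exp_mech_ <- function(quality, epsilon, sensitivity) {
  if (is.infinite(epsilon)) return(which.max(quality))
  w <- epsilon * quality / (2 * sensitivity)
  w <- w - max(w)
  p <- exp(w); p <- p / sum(p)
  sample.int(length(quality), 1L, prob = p)
}

#' Learn a Bayesian-network structure under differential privacy
#'
#' Greedy ordering: the first node is drawn uniformly; at each later step the
#' (node, parent set) pair with parent sets of size at most `k` drawn from
#' already-placed nodes is selected by the exponential mechanism with
#' empirical mutual information as the quality function, spending
#' `epsilon_structure / (n_features - 1)` per step. `k = 0` forces the
#' independent-marginals structure.
#'
#' @param d A `trial_dataset` with categorical features only.
#' @param k Maximum parent-set size (>= 0).
#' @param epsilon_structure Structure budget (> 0; `Inf` makes the search
#'   greedy-deterministic).
#' @param seed Integer seed.
#' @return An object of class `bayesnet_model` (order, parent sets; tables
#'   are filled by [fit_privbayes_conditionals()]).
#' @export
fit_privbayes_structure <- function(d, k, epsilon_structure, seed = NULL) {
  check_(length(continuous_names_(d$schema)) == 0L,
         "all features must be categorical")
  check_(is.numeric(k) && length(k) == 1L && k >= 0, "k must be >= 0")
  check_(epsilon_structure > 0, "epsilon_structure must be > 0")
  nm <- names(d$schema)
  X <- codes_(d)
  card <- card_(d$schema)
  n <- n_patients(d)
  dsens <- mi_sensitivity_(n)
  nfeat <- length(nm)
  eps_step <- epsilon_structure / max(1L, nfeat - 1L)
  with_seed_(seed, {
    order <- sample.int(nfeat, 1L)
    parents <- setNames(vector("list", nfeat), nm)
    parents[[order[1L]]] <- character(0)
    while (length(order) < nfeat) {
      placed <- order
      todo <- setdiff(seq_len(nfeat), placed)
      cand_node <- integer(0); cand_par <- list(); q <- numeric(0)
      psets <- list(integer(0))
      for (s in seq_len(min(k, length(placed)))) {
        # combn(x, s) treats scalar x as 1:x; guard the single-node case
        new <- if (length(placed) == 1L) list(placed)
        else utils::combn(placed, s, simplify = FALSE)
        psets <- c(psets, new)
      }
      for (x in todo) {
        xi <- X[, x]
        for (ps in psets) {
          cfg <- config_index_(X, ps, card)
          b <- if (length(ps)) prod(card[ps]) else 1L
          cand_node <- c(cand_node, x)
          cand_par <- c(cand_par, list(ps))
          q <- c(q, mi_bits_(xi, card[x], cfg, b))
        }
      }
      pick <- exp_mech_(q, eps_step, dsens)
      node <- cand_node[pick]
      order <- c(order, node)
      parents[[node]] <- nm[cand_par[[pick]]]
    }
    structure(list(features = nm,
                   categories = lapply(d$schema, `[[`, "categories"),
                   card = card, order = order, parents = parents,
                   tables = NULL, n_train = n),
              class = "bayesnet_model")
  })
}

#' Estimate noisy conditional probability tables
#'
#' Counts over each (node, parent configuration) cell are perturbed with
#' Laplace noise at scale `n_features / epsilon_params` (each table gets an
#' equal epsilon share; count sensitivity 1), negatives are clipped to zero
#' and rows renormalized; an all-zero row falls back to the uniform
#' distribution.
#'
#' @param d The training `trial_dataset` (categorical features only).
#' @param model A [fit_privbayes_structure()] result.
#' @param epsilon_params Parameter budget (> 0; `Inf` disables noise).
#' @param seed Integer seed.
#' @return The model with `tables` filled.
#' @export
fit_privbayes_conditionals <- function(d, model, epsilon_params, seed = NULL) {
  check_(inherits(model, "bayesnet_model"), "model must be a bayesnet_model")
  check_(epsilon_params > 0, "epsilon_params must be > 0")
  X <- codes_(d)
  card <- model$card
  nfeat <- length(model$features)
  eps_table <- epsilon_params / nfeat
  tables <- with_seed_(seed, lapply(seq_len(nfeat), function(x) {
    ps <- match(model$parents[[x]], model$features)
    a <- card[x]
    b <- if (length(ps)) prod(card[ps]) else 1L
    cfg <- config_index_(X, ps, card)
    counts <- matrix(tabulate((cfg - 1L) * a + X[, x], nbins = a * b),
                     nrow = b, ncol = a, byrow = TRUE)
    if (is.finite(eps_table))
      counts <- counts + matrix(rlaplace_(a * b, 1 / eps_table), nrow = b)
    counts[counts < 0] <- 0
    rs <- rowSums(counts)
    probs <- counts / ifelse(rs > 0, rs, 1)
    probs[rs == 0, ] <- 1 / a
    list(parents = ps, probs = probs)
  }))
  model$tables <- setNames(tables, model$features)
  model$epsilon_params <- epsilon_params
  model
}

#' Ancestral sampling from a fitted Bayesian network
#'
#' @param model A complete `bayesnet_model` (structure and tables).
#' @param n Number of records.
#' @param seed Integer seed.
#' @param schema Optional `trial_schema` to validate against; when supplied a
#'   `trial_dataset` is returned, otherwise a plain data frame of factors.
#' @export
sample_bayesnet <- function(model, n, seed = NULL, schema = NULL) {
  check_(inherits(model, "bayesnet_model") && !is.null(model$tables),
         "model must carry fitted conditional tables")
  check_(is_count_(n), "n must be a positive integer")
  card <- model$card
  X <- matrix(0L, nrow = n, ncol = length(model$features))
  with_seed_(seed, {
    for (x in model$order) {
      tab <- model$tables[[x]]
      cfg <- config_index_(X, tab$parents, card)
      for (cf in unique(cfg)) {
        rows <- which(cfg == cf)
        X[rows, x] <- sample.int(card[x], length(rows), replace = TRUE,
                                 prob = tab$probs[cf, ])
      }
    }
  })
  cols <- lapply(seq_along(model$features), function(j)
    factor(model$categories[[j]][X[, j]], levels = model$categories[[j]]))
  df <- as.data.frame(setNames(cols, model$features))
  if (is.null(schema)) df else trial_dataset(df, schema)
}
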