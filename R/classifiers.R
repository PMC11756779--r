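# Minimal CART-style learners used by the resemblance and privacy metrics:
# a variance-reduction regression tree, a bagged forest, and a logistic
# gradient-boosting ensemble. Kept internal; they exist so the metric suite
# has a tree-ensemble and a boosted-tree classifier without heavyweight
# dependencies.

# Numeric design matrix from schema-typed columns: continuous as-is, binary
# as 0/1, wider categoricals treatment-coded against the first schema
# category (keeps the matrix full rank for the Cox fits). Column layout is
# fixed by the schema, so matrices from datasets sharing a schema align.
encode_features_ <- function(d, features) {
  cols <- list()
  for (f in features) {
    sch <- d$schema[[f]]
    v <- d$data[[f]]
    if (sch$ftype == "continuous") {
      cols[[f]] <- as.numeric(v)
    } else if (length(sch$categories) == 2L) {
      cols[[f]] <- as.numeric(v == sch$categories[2L])
    } else {
      for (lv in sch$categories[-1L])
        cols[[paste0(f, "=", lv)]] <- as.numeric(v == lv)
    }
  }
  do.call(cbind, cols)
}

# Best variance-reducing split of y along x; returns NULL or list(thr, gain).
best_split_ <- function(x, y, minbucket) {
  n <- length(y)
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  csum <- cumsum(ys)
  tot <- csum[n]
  i <- seq_len(n - 1L)
  valid <- i >= minbucket & i <= n - minbucket & xs[i] < xs[i + 1L]
  if (!any(valid)) return(NULL)
  i <- i[valid]
  score <- csum[i]^2 / i + (tot - csum[i])^2 / (n - i)
  best <- which.max(score)
  list(thr = (xs[i[best]] + xs[i[best] + 1L]) / 2,
       gain = score[best] - tot^2 / n)
}

tree_fit_ <- function(X, y, depth, minbucket, mtry = ncol(X)) {
  n <- length(y)
  if (depth == 0L || n < 2L * minbucket || length(unique(y)) == 1L)
    return(list(leaf = mean(y)))
  feats <- if (mtry < ncol(X)) sample.int(ncol(X), mtry) else seq_len(ncol(X))
  best <- NULL; bj <- NA_integer_
  for (j in feats) {
    sp <- best_split_(X[, j], y, minbucket)
    if (!is.null(sp) && (is.null(best) || sp$gain > best$gain)) {
      best <- sp; bj <- j
    }
  }
  if (is.null(best) || best$gain <= 1e-12) return(list(leaf = mean(y)))
  left <- X[, bj] <= best$thr
  list(var = bj, thr = best$thr,
       left = tree_fit_(X[left, , drop = FALSE], y[left],
                        depth - 1L, minbucket, mtry),
       right = tree_fit_(X[!left, , drop = FALSE], y[!left],
                         depth - 1L, minbucket, mtry))
}

tree_predict_ <- function(tree, X) {
  out <- numeric(nrow(X))
  rec <- function(node, rows) {
    if (!length(rows)) return(invisible(NULL))
    if (!is.null(node$leaf)) { out[rows] <<- node$leaf; return(invisible(NULL)) }
    left <- X[rows, node$var] <= node$thr
    rec(node$left, rows[left])
    rec(node$right, rows[!left])
  }
  rec(tree, seq_len(nrow(X)))
  out
}

# Bagged regression trees on a 0/1 response ~ random forest probability
# machine; predictions are averaged leaf means.
forest_fit_ <- function(X, y, ntree = 60L, depth = 5L, minbucket = 5L,
                        seed = NULL) {
  mtry <- max(1L, floor(sqrt(ncol(X))))
  with_seed_(seed, {
    trees <- lapply(seq_len(ntree), function(i) {
      idx <- sample.int(nrow(X), replace = TRUE)
      tree_fit_(X[idx, , drop = FALSE], y[idx], depth, minbucket, mtry)
    })
    structure(list(trees = trees), class = "synarm_forest")
  })
}

forest_predict_ <- function(fit, X) {
  rowMeans(vapply(fit$trees, function(tr) tree_predict_(tr, X),
                  numeric(nrow(X))))
}

# Logistic gradient boosting with shallow regression trees. Per-node column
# subsampling (a la colsample) lets the ensemble discover interaction-only
# signals that greedy gain search is otherwise blind to (e.g. planted
# feature equalities with no marginal effect).
boost_fit_ <- function(X, y, rounds = 100L, depth = 3L, lr = 0.2,
                       minbucket = 10L, mtry = NULL, seed = NULL) {
  mtry <- mtry %||% max(2L, floor(sqrt(ncol(X))))
  f0 <- log((mean(y) + 1e-6) / (1 - mean(y) + 1e-6))
  fx <- rep(f0, length(y))
  with_seed_(seed, {
    trees <- vector("list", rounds)
    for (m in seq_len(rounds)) {
      p <- 1 / (1 + exp(-fx))
      tr <- tree_fit_(X, y - p, depth, minbucket, mtry)
      trees[[m]] <- tr
      fx <- fx + lr * tree_predict_(tr, X)
    }
    structure(list(f0 = f0, lr = lr, trees = trees), class = "synarm_boost")
  })
}

boost_predict_ <- function(fit, X) {
  fx <- rep(fit$f0, nrow(X))
  for (tr in fit$trees) fx <- fx + fit$lr * tree_predict_(tr, X)
  1 / (1 + exp(-fx))
}

# Regularized logistic regression via iteratively reweighted least squares
# with a small ridge term, robust to separation and constant columns.
logistic_fit_ <- function(X, y, lambda = 1e-4, maxit = 50L) {
  Xd <- cbind(1, X)
  beta <- numeric(ncol(Xd))
  for (it in seq_len(maxit)) {
    eta <- drop(Xd %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- pmax(p * (1 - p), 1e-6)
    z <- eta + (y - p) / w
    A <- crossprod(Xd * w, Xd) + diag(lambda, ncol(Xd))
    beta_new <- drop(solve(A, crossprod(Xd * w, z)))
    if (max(abs(beta_new - beta)) < 1e-8) { beta <- beta_new; break }
    beta <- beta_new
  }
  beta
}

logistic_predict_ <- function(beta, X) {
  drop(1 / (1 + exp(-cbind(1, X) %*% beta)))
}
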