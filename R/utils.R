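# Internal helpers shared across modules.

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
# seed = NULL runs the code on the ambient stream.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seed; kept inside 32-bit signed range.
seed_child_ <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + 1000003 * as.double(k)) %% 2147483629) + 1L
}

abort_ <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "synarm_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

check_ <- function(cond, msg, class = "synarm_argument_error") {
  if (!isTRUE(cond)) abort_(msg, class)
  invisible(TRUE)
}

is_count_ <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == floor(x)

clamp_ <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Laplace(0, b) draws via inverse CDF.
rlaplace_ <- function(n, scale) {
  u <- runif(n, -0.5, 0.5)
  -scale * sign(u) * log1p(-2 * abs(u))
}

# Truncated-normal sampler on [lo, hi] via inverse-CDF; degenerate truncation
# (mass numerically zero inside the window) collapses to the clamped mean.
rtruncnorm_ <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(rep(clamp_(mean, lo, hi), n))
  pa <- pnorm(lo, mean, sd)
  pb <- pnorm(hi, mean, sd)
  if (!is.finite(pb - pa) || pb - pa < 1e-12)
    return(rep(clamp_(mean, lo, hi), n))
  x <- qnorm(pa + runif(n) * (pb - pa), mean, sd)
  clamp_(x, lo, hi)
}

# Area under the ROC curve from scores and 0/1 labels (rank statistic).
auroc_ <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  check_(n1 > 0 && n0 > 0, "AUROC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
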