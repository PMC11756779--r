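# Rank-score aggregation across the resemblance / utility / privacy measure
# categories: rank per measure, average ranks per category, min-max normalize
# to [0, 1] with lower = better.

#' Generators-by-measures score table
#'
#' @param values Numeric matrix (generators x measures) of run-averaged
#'   scores; no missing cells.
#' @param measures Data frame with columns `name`, `category` (one of
#'   `resemblance`, `utility`, `privacy`) and `orientation` (`lower_better`
#'   or `higher_better`), one row per column of `values`.
#' @param generators Generator names (rownames of `values` if omitted).
#' @return An object of class `metric_matrix`.
#' @export
metric_matrix <- function(values, measures, generators = rownames(values)) {
  values <- as.matrix(values)
  check_(!anyNA(values), "metric matrix must have no missing cells")
  check_(nrow(measures) == ncol(values),
         "one measures row per value column required")
  check_(all(measures$category %in% c("resemblance", "utility", "privacy")),
         "unknown measure category")
  check_(all(measures$orientation %in% c("lower_better", "higher_better")),
         "orientation must be declared for every measure")
  check_(length(generators) == nrow(values), "generator names missing")
  dimnames(values) <- list(generators, measures$name)
  structure(list(values = values, measures = measures,
                 generators = generators),
            class = "metric_matrix")
}

#' Rank generators on one measure
#'
#' Ranks 1..G with 1 = best under the declared orientation; ties receive the
#' average of their rank positions.
#'
#' @param values Numeric vector, one entry per generator (>= 2).
#' @param orientation `"lower_better"` or `"higher_better"`.
#' @return Numeric rank vector.
#' @export
rank_measure <- function(values, orientation = c("lower_better",
                                                 "higher_better")) {
  orientation <- match.arg(orientation)
  check_(length(values) >= 2L, "need at least 2 generators to rank")
  x <- if (orientation == "higher_better") -values else values
  rank(x, ties.method = "average")
}

minmax_ <- function(x) {
  r <- max(x) - min(x)
  if (r == 0) rep(0, length(x)) else (x - min(x)) / r
}

#' Aggregate ranks into per-category and overall scores
#'
#' Per category: each measure is ranked across generators, ranks are averaged
#' per generator, and the averages are min-max normalized to \[0, 1\] (all
#' zero when every generator ties). The overall score applies the same
#' procedure across all measures of all categories. Lower is better.
#'
#' @param m A [metric_matrix()].
#' @return An object of class `rank_report` with a tidy `scores` data frame
#'   (`generator`, `category`, `score`) where `category` includes
#'   `"overall"`, plus the `mean_ranks` underlying it.
#' @export
aggregate_ranks <- function(m) {
  check_(inherits(m, "metric_matrix"), "m must be a metric_matrix")
  ranks <- vapply(seq_len(ncol(m$values)), function(j)
    rank_measure(m$values[, j], m$measures$orientation[j]),
    numeric(nrow(m$values)))
  colnames(ranks) <- m$measures$name
  cats <- unique(m$measures$category)
  score_block <- function(cols) minmax_(rowMeans(ranks[, cols, drop = FALSE]))
  mean_rank_block <- function(cols) rowMeans(ranks[, cols, drop = FALSE])
  out <- list(); mr <- list()
  for (cat in cats) {
    cols <- which(m$measures$category == cat)
    check_(length(cols) > 0L, sprintf("empty category '%s'", cat))
    out[[cat]] <- score_block(cols)
    mr[[cat]] <- mean_rank_block(cols)
  }
  out[["overall"]] <- score_block(seq_len(ncol(ranks)))
  mr[["overall"]] <- mean_rank_block(seq_len(ncol(ranks)))
  scores <- do.call(rbind, lapply(names(out), function(cat)
    data.frame(generator = m$generators, category = cat,
               score = unname(out[[cat]]))))
  structure(list(scores = scores, mean_ranks = mr, ranks = ranks,
                 generators = m$generators),
            class = "rank_report")
}

#' @export
print.rank_report <- function(x, ...) {
  wide <- stats::reshape(x$scores, idvar = "generator", timevar = "category",
                         direction = "wide")
  names(wide) <- sub("^score\\.", "", names(wide))
  cat("<rank_report> normalized rank scores (lower = better)\n")
  print(wide, row.names = FALSE)
  invisible(x)
}

#' Score of one generator in one category
#' @param report A `rank_report`.
#' @param generator,category Labels to look up.
#' @export
rank_score <- function(report, generator, category) {
  s <- report$scores
  s$score[s$generator == generator & s$category == category]
}
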