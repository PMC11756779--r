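# Re-identification risk measures: attribute-inference (CAP), detection
# AUROC, and nearest-neighbour distances (DCR / NNDR) with a hold-out
# baseline calibrating what "safe" distances look like.

ranges_ <- function(d) {
  cont <- continuous_names_(d$schema)
  setNames(lapply(cont, function(f) range(d$data[[f]])), cont)
}

# Full cross-distance matrix (rows = records of a, cols = records of b),
# Gower-style mean of per-feature distances. Continuous features are
# range-normalized (ranges from the reference dataset), categorical features
# contribute a 0/1 mismatch.
gower_cross_ <- function(a, b, schema, ranges) {
  feats <- names(schema)
  acc <- matrix(0, nrow(a), nrow(b))
  for (f in feats) {
    if (schema[[f]]$ftype == "continuous") {
      r <- ranges[[f]]
      w <- max(r[2L] - r[1L], .Machine$double.eps)
      dist_f <- abs(outer(as.numeric(a[[f]]), as.numeric(b[[f]]), `-`)) / w
      dist_f <- pmin(dist_f, 1)
    } else {
      dist_f <- outer(as.character(a[[f]]), as.character(b[[f]]), `!=`) * 1
    }
    acc <- acc + dist_f
  }
  acc / length(feats)
}

#' Gower-style distance between two records
#'
#' Mean of per-feature distances: range-normalized absolute difference for
#' continuous features (capped at 1), 0/1 mismatch for categoricals. A metric
#' on records with range \[0, 1\].
#'
#' @param a,b Single records (one-row data frames or lists) under `schema`.
#' @param schema The shared `trial_schema`.
#' @param ranges Optional named list of `c(lo, hi)` normalization ranges for
#'   continuous features; defaults to the range spanned by the pair.
#' @return A value in \[0, 1\].
#' @export
mixed_distance <- function(a, b, schema, ranges = NULL) {
  a <- as.data.frame(a); b <- as.data.frame(b)
  check_(all(names(schema) %in% names(a)) && all(names(schema) %in% names(b)),
         "records must carry all schema features")
  total <- 0
  for (f in names(schema)) {
    if (schema[[f]]$ftype == "continuous") {
      va <- as.numeric(a[[f]]); vb <- as.numeric(b[[f]])
      r <- ranges[[f]] %||% range(c(va, vb))
      w <- r[2L] - r[1L]
      total <- total + if (w <= 0) 0 else min(abs(va - vb) / w, 1)
    } else {
      total <- total + as.numeric(as.character(a[[f]]) != as.character(b[[f]]))
    }
  }
  total / length(schema)
}

#' Correct Attribution Probability (categorical), safety orientation
#'
#' The attacker knows each original record's key attributes and predicts its
#' target attribute as the majority target value among synthetic records
#' matching on all keys (ties broken by schema category order; no key match
#' means the attacker fails). The returned score is `1 - attribution rate`,
#' so high values indicate safety.
#'
#' @param original,synthetic `trial_dataset`s sharing a schema.
#' @param key_features Categorical feature names the attacker holds.
#' @param target_feature Categorical feature the attacker infers.
#' @return A value in \[0, 1\].
#' @export
cap_categorical <- function(original, synthetic, key_features, target_feature) {
  sch <- original$schema
  check_(!(target_feature %in% key_features), "target must not be among keys")
  for (f in c(key_features, target_feature))
    check_(sch[[f]]$ftype != "continuous",
           sprintf("feature '%s' must be categorical", f))
  key_of <- function(d) do.call(paste, c(lapply(key_features, function(f)
    as.character(d$data[[f]])), sep = "\r"))
  ko <- key_of(original); ks <- key_of(synthetic)
  tgt_levels <- sch[[target_feature]]$categories
  ts <- as.integer(synthetic$data[[target_feature]])
  to <- as.integer(original$data[[target_feature]])
  # majority target per synthetic key group
  pred <- vapply(split(ts, ks), function(v) {
    tab <- tabulate(v, nbins = length(tgt_levels))
    which.max(tab)  # ties -> first (schema order)
  }, integer(1L))
  hit <- ko %in% names(pred)
  correct <- logical(length(ko))
  correct[hit] <- pred[ko[hit]] == to[hit]
  1 - mean(correct)
}

#' Detection score: can a boosted-tree classifier tell records apart?
#'
#' Labels original records 1 and synthetic records 0, fits a gradient-boosted
#' tree classifier under stratified 5-fold cross-validation, and returns the
#' mean out-of-fold AUROC. High values mean synthetic records are easy to
#' distinguish from originals, i.e. lower memorization risk.
#'
#' When the two datasets have equal size, fold assignment is paired (row i of
#' each class shares a fold): otherwise a synthetic record's exact duplicate
#' of an original (the Dummy generator's regime) lands in the training fold
#' with the opposite label and biases the AUROC below 0.5.
#'
#' @param original,synthetic `trial_dataset`s sharing a schema.
#' @param seed Integer seed.
#' @param rounds,depth Boosting rounds and tree depth.
#' @return A value in \[0, 1\].
#' @export
detection_score <- function(original, synthetic, seed = NULL,
                            rounds = 100L, depth = 3L) {
  n1 <- n_patients(original); n0 <- n_patients(synthetic)
  check_(n1 >= 10L && n0 >= 10L, "need at least 10 records per class")
  feats <- names(original$schema)
  X <- rbind(encode_features_(original, feats),
             encode_features_(synthetic, feats))
  y <- c(rep(1, n1), rep(0, n0))
  folds <- with_seed_(seed_child_(seed, 1L), {
    if (n1 == n0) {
      f1 <- sample(rep_len(1:5, n1))
      c(f1, f1)
    } else {
      f <- integer(length(y))
      f[y == 1] <- sample(rep_len(1:5, n1))
      f[y == 0] <- sample(rep_len(1:5, n0))
      f
    }
  })
  aucs <- vapply(1:5, function(k) {
    tr <- folds != k
    fit <- boost_fit_(X[tr, , drop = FALSE], y[tr], rounds = rounds,
                      depth = depth, seed = seed_child_(seed, 10L + k))
    auroc_(boost_predict_(fit, X[!tr, , drop = FALSE]), y[!tr])
  }, numeric(1L))
  mean(aucs)
}

#' Distance to Closest Record (DCR)
#'
#' Median over synthetic records of the minimum Gower distance to any
#' original training record. Low values indicate memorization.
#'
#' @param original_train,synthetic `trial_dataset`s sharing a schema.
#' @return A non-negative real.
#' @export
dcr <- function(original_train, synthetic) {
  check_(n_patients(original_train) > 0 && n_patients(synthetic) > 0,
         "datasets must be non-empty")
  D <- gower_cross_(synthetic$data, original_train$data,
                    original_train$schema, ranges_(original_train))
  median(apply(D, 1L, min))
}

#' Nearest Neighbour Distance Ratio (NNDR)
#'
#' Median over synthetic records of (distance to 1st nearest original) /
#' (distance to 5th nearest original); a ratio of 1 is reported when the 5th
#' distance is 0. Low values indicate proximity to sparsely populated regions
#' of the training data.
#'
#' @param original_train,synthetic `trial_dataset`s sharing a schema;
#'   `original_train` needs >= 5 records.
#' @return A value in \[0, 1\].
#' @export
nndr <- function(original_train, synthetic) {
  check_(n_patients(original_train) >= 5L, "need at least 5 original records")
  D <- gower_cross_(synthetic$data, original_train$data,
                    original_train$schema, ranges_(original_train))
  ratios <- apply(D, 1L, function(row) {
    s <- sort(row, method = "radix")[c(1L, 5L)]
    if (s[2L] == 0) 1 else s[1L] / s[2L]
  })
  median(ratios)
}

default_cap_config_ <- function(schema) {
  cats <- intersect(covariate_names(schema), categorical_names_(schema))
  check_(length(cats) >= 4L,
         "need at least 4 categorical covariates for default CAP keys/target")
  card <- vapply(cats, function(f) length(schema[[f]]$categories), integer(1L))
  ord <- cats[order(-card, cats)]
  list(keys = ord[1:3], target = ord[4L])
}

#' Full privacy report with hold-out baseline
#'
#' Computes CAP, detection AUROC, DCR and NNDR for the synthetic data, plus
#' the DCR/NNDR of an untouched hold-out split of the original data under the
#' same distance. A memorization-risk flag is raised when the synthetic DCR
#' falls below the hold-out DCR.
#'
#' @param original_train Training split the generator saw.
#' @param holdout Hold-out split of the original data (never shown to the
#'   generator).
#' @param synthetic Synthetic dataset under evaluation.
#' @param keys,target CAP key/target features; default: the three
#'   highest-cardinality categorical covariates as keys, the next as target.
#' @param seed Integer seed for the detection classifier.
#' @return An object of class `privacy_report`.
#' @export
privacy_report <- function(original_train, holdout, synthetic,
                           keys = NULL, target = NULL, seed = NULL) {
  if (is.null(keys) || is.null(target)) {
    cfg <- default_cap_config_(original_train$schema)
    keys <- keys %||% cfg$keys
    target <- target %||% cfg$target
  }
  cap <- cap_categorical(original_train, synthetic, keys, target)
  det <- detection_score(original_train, synthetic, seed = seed)
  d_syn <- dcr(original_train, synthetic)
  n_syn <- nndr(original_train, synthetic)
  d_hold <- dcr(original_train, holdout)
  n_hold <- nndr(original_train, holdout)
  structure(list(cap_score = cap, detection_score = det,
                 dcr = d_syn, nndr = n_syn,
                 holdout_dcr = d_hold, holdout_nndr = n_hold,
                 risk_flag = d_syn < d_hold,
                 keys = keys, target = target),
            class = "privacy_report")
}

#' @export
print.privacy_report <- function(x, ...) {
  cat(sprintf(paste0("<privacy_report> CAP %.3f | detection AUROC %.3f | ",
                     "DCR %.4f (holdout %.4f) | NNDR %.3f (holdout %.3f)%s\n"),
              x$cap_score, x$detection_score, x$dcr, x$holdout_dcr,
              x$nndr, x$holdout_nndr,
              if (x$risk_flag) " [MEMORIZATION RISK]" else ""))
  invisible(x)
}
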