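#' Declare a single trial-table column
#'
#' A feature schema records the column name, its measurement type, the
#' ordered category labels (for non-continuous columns) and its role in the
#' trial: ordinary covariate, survival time, event indicator, or arm label.
#'
#' @param name Column name.
#' @param ftype One of `"binary"`, `"categorical"`, `"continuous"`. Binary
#'   columns are stored as two-level categoricals; `"binary"` is an
#'   annotation, not a distinct storage type.
#' @param role One of `"covariate"`, `"survival_time"`, `"event_indicator"`,
#'   `"arm"`.
#' @param categories Ordered character vector of admissible labels; required
#'   unless `ftype = "continuous"`.
#' @param binned_from Internal marker set by [generalize()] when a continuous
#'   column has been mapped to interval labels; leave `NULL`.
#' @return An object of class `schema_feature`.
#' @export
schema_feature <- function(name,
                           ftype = c("binary", "categorical", "continuous"),
                           role = c("covariate", "survival_time",
                                    "event_indicator", "arm"),
                           categories = NULL,
                           binned_from = NULL) {
  ftype <- match.arg(ftype)
  role <- match.arg(role)
  check_(is.character(name) && length(name) == 1L && nzchar(name),
         "feature name must be a non-empty string")
  if (ftype == "continuous") {
    check_(is.null(categories), sprintf(
      "continuous feature '%s' must not declare categories", name))
  } else {
    check_(is.character(categories) && length(categories) >= 1L &&
             !anyDuplicated(categories), sprintf(
      "feature '%s': categories must be distinct labels", name))
    if (ftype == "binary")
      check_(length(categories) == 2L, sprintf(
        "binary feature '%s' needs exactly 2 categories", name))
  }
  structure(list(name = name, ftype = ftype, role = role,
                 categories = categories, binned_from = binned_from),
            class = "schema_feature")
}

#' Assemble and validate a trial schema
#'
#' Enforces the single-survival-time / single-event-indicator / single-arm
#' contract: the event indicator must be binary with categories `"0"`/`"1"`,
#' the arm column must have exactly two categories, and the survival time must
#' be continuous (or a binned continuous produced by [generalize()]).
#'
#' @param ... `schema_feature` objects, or a single list of them.
#' @return An object of class `trial_schema` (named list of features).
#' @export
trial_schema <- function(...) {
  feats <- list(...)
  if (length(feats) == 1L && !inherits(feats[[1L]], "schema_feature"))
    feats <- feats[[1L]]
  check_(length(feats) >= 3L && all(vapply(feats, inherits, TRUE,
                                           "schema_feature")),
         "trial_schema needs schema_feature objects")
  nm <- vapply(feats, `[[`, "", "name")
  check_(!anyDuplicated(nm), "duplicate feature names in schema")
  names(feats) <- nm
  roles <- vapply(feats, `[[`, "", "role")
  for (r in c("survival_time", "event_indicator", "arm"))
    check_(sum(roles == r) == 1L,
           sprintf("schema must contain exactly one %s column", r))
  ev <- feats[[which(roles == "event_indicator")]]
  check_(ev$ftype == "binary" && identical(ev$categories, c("0", "1")),
         "event indicator must be binary with categories '0','1'")
  arm <- feats[[which(roles == "arm")]]
  check_(arm$ftype != "continuous" && length(arm$categories) == 2L,
         "arm column must have exactly two categories")
  st <- feats[[which(roles == "survival_time")]]
  check_(st$ftype == "continuous" || identical(st$binned_from, "continuous"),
         "survival time must be continuous")
  structure(feats, class = "trial_schema")
}

schema_roles_ <- function(schema) vapply(schema, `[[`, "", "role")
schema_types_ <- function(schema) vapply(schema, `[[`, "", "ftype")

surv_col_ <- function(schema) names(schema)[schema_roles_(schema) == "survival_time"]
event_col_ <- function(schema) names(schema)[schema_roles_(schema) == "event_indicator"]
arm_col_ <- function(schema) names(schema)[schema_roles_(schema) == "arm"]

#' @rdname trial_schema
#' @param schema A `trial_schema`.
#' @export
covariate_names <- function(schema) {
  names(schema)[schema_roles_(schema) == "covariate"]
}

continuous_names_ <- function(schema) {
  names(schema)[schema_types_(schema) == "continuous"]
}
categorical_names_ <- function(schema) {
  names(schema)[schema_types_(schema) != "continuous"]
}

#' Construct a validated trial dataset
#'
#' Coerces a data frame to the schema types (categoricals become factors with
#' the schema's ordered levels) and enforces the invariants: no missing cells,
#' every categorical value among its declared categories, non-negative
#' survival times. Violations raise an error naming the offending row/column.
#'
#' @param data A data frame whose columns match the schema names.
#' @param schema A [trial_schema()].
#' @return An object of class `trial_dataset` with elements `data`, `schema`,
#'   `n_patients`.
#' @export
trial_dataset <- function(data, schema) {
  check_(inherits(schema, "trial_schema"), "schema must be a trial_schema")
  check_(is.data.frame(data), "data must be a data.frame")
  missing_cols <- setdiff(names(schema), names(data))
  check_(length(missing_cols) == 0L,
         paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  extra <- setdiff(names(data), names(schema))
  check_(length(extra) == 0L,
         paste0("unknown column(s): ", paste(extra, collapse = ", ")),
         class = "synarm_validation_error")
  data <- data[names(schema)]
  for (f in schema) {
    col <- data[[f$name]]
    if (f$ftype == "continuous") {
      suppressWarnings(v <- as.numeric(as.character(col)))
      bad <- which(is.na(v))
      if (length(bad))
        abort_(sprintf("column '%s': missing or non-numeric value in row %d",
                       f$name, bad[1L]), "synarm_validation_error")
      data[[f$name]] <- v
    } else {
      ch <- as.character(col)
      bad <- which(is.na(ch))
      if (length(bad))
        abort_(sprintf("column '%s': missing value in row %d",
                       f$name, bad[1L]), "synarm_validation_error")
      out <- which(!(ch %in% f$categories))
      if (length(out))
        abort_(sprintf("column '%s': value '%s' in row %d not among schema categories",
                       f$name, ch[out[1L]], out[1L]), "synarm_validation_error")
      data[[f$name]] <- factor(ch, levels = f$categories)
    }
  }
  st <- surv_col_(schema)
  if (schema[[st]]$ftype == "continuous") {
    neg <- which(data[[st]] < 0)
    if (length(neg))
      abort_(sprintf("column '%s': negative survival time in row %d",
                     st, neg[1L]), "synarm_validation_error")
  }
  rownames(data) <- NULL
  structure(list(data = data, schema = schema, n_patients = nrow(data)),
            class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf("<trial_dataset> %d patients, %d features (%s survival, arm '%s')\n",
              x$n_patients, length(x$schema), surv_col_(x$schema),
              arm_col_(x$schema)))
  invisible(x)
}

#' Number of patients in a trial dataset
#' @param d A `trial_dataset`.
#' @export
n_patients <- function(d) d$n_patients

subset_rows_ <- function(d, idx) {
  trial_dataset(d$data[idx, , drop = FALSE], d$schema)
}

#' Read / write a trial table as CSV
#'
#' Comma-delimited UTF-8 text with a header row; numeric columns are written
#' at full double precision so a read/write/read roundtrip reproduces the
#' value table exactly.
#'
#' @param path File path.
#' @param schema A [trial_schema()] describing the expected columns.
#' @return [read_trial_table()]: a validated `trial_dataset`.
#' @export
read_trial_table <- function(path, schema) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  trial_dataset(raw, schema)
}

#' @rdname read_trial_table
#' @param d A `trial_dataset` to write.
#' @export
write_trial_table <- function(d, path) {
  out <- d$data
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
    else out[[nm]] <- as.character(out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Split off an independent hold-out set
#'
#' Draws `round(fraction * n)` rows (without replacement) into a hold-out
#' partition, leaving the remainder as the training partition. The hold-out
#' calibrates the privacy distance baselines.
#'
#' @param d A `trial_dataset`.
#' @param fraction Hold-out proportion in (0, 1).
#' @param seed Integer seed; the split is reproducible under it.
#' @return `list(holdout =, train =)`, two disjoint `trial_dataset`s.
#' @export
split_holdout <- function(d, fraction, seed) {
  check_(is.numeric(fraction) && length(fraction) == 1L &&
           fraction > 0 && fraction < 1, "fraction must lie in (0, 1)")
  n <- n_patients(d)
  check_(n >= 2L, "need at least 2 patients to split")
  k <- round(fraction * n)
  k <- max(1L, min(n - 1L, k))
  idx <- with_seed_(seed, sample.int(n, k))
  list(holdout = subset_rows_(d, idx),
       train = subset_rows_(d, setdiff(seq_len(n), idx)))
}

#' Split a dataset by trial arm
#'
#' @param d A `trial_dataset`.
#' @return Named list with one `trial_dataset` per arm category (in schema
#'   category order).
#' @export
arm_split <- function(d) {
  ac <- arm_col_(d$schema)
  lv <- d$schema[[ac]]$categories
  out <- lapply(lv, function(l) subset_rows_(d, which(d$data[[ac]] == l)))
  names(out) <- lv
  out
}
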