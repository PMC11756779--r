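# Programmatic fixtures shared across the suite. Everything is generated in
# code; no data files.

basic_schema <- function() {
  trial_schema(
    schema_feature("bin01", "binary", categories = c("0", "1")),
    schema_feature("bin02", "binary", categories = c("0", "1")),
    schema_feature("bin03", "binary", categories = c("0", "1")),
    schema_feature("bin04", "binary", categories = c("0", "1")),
    schema_feature("age", "continuous"),
    schema_feature("os", "continuous", role = "survival_time"),
    schema_feature("ev", "binary", role = "event_indicator",
                   categories = c("0", "1")),
    schema_feature("arm", "categorical", role = "arm",
                   categories = c("ctl", "act"))
  )
}

basic_dataset <- function(n = 60, seed = 1, event_rate = 0.7) {
  set.seed(seed)
  df <- data.frame(
    bin01 = sample(c("0", "1"), n, TRUE),
    bin02 = sample(c("0", "1"), n, TRUE),
    bin03 = sample(c("0", "1"), n, TRUE),
    bin04 = sample(c("0", "1"), n, TRUE),
    age = runif(n, 40, 90),
    os = rexp(n, rate = 1 / 12),
    ev = sample(c("0", "1"), n, TRUE, prob = c(1 - event_rate, event_rate)),
    arm = "ctl",
    stringsAsFactors = FALSE
  )
  trial_dataset(df, basic_schema())
}

# Survival dataset with one binary group covariate and exponential times:
# group effect log_hr, baseline rate `rate`, optional uniform censoring.
exp_surv_dataset <- function(n, log_hr = 0, rate = 0.1, seed = 1,
                             censor_max = Inf, group = NULL) {
  set.seed(seed)
  grp <- group %||% sample(c("0", "1"), n, TRUE)
  tt <- rexp(n, rate = rate * exp(log_hr * (grp == "1")))
  cc <- if (is.finite(censor_max)) runif(n, 0, censor_max) else rep(Inf, n)
  sch <- trial_schema(
    schema_feature("grp", "binary", categories = c("0", "1")),
    schema_feature("os", "continuous", role = "survival_time"),
    schema_feature("ev", "binary", role = "event_indicator",
                   categories = c("0", "1")),
    schema_feature("arm", "categorical", role = "arm",
                   categories = c("ctl", "act"))
  )
  trial_dataset(data.frame(grp = grp, os = pmin(tt, cc),
                           ev = as.character(as.integer(tt <= cc)),
                           arm = "ctl", stringsAsFactors = FALSE), sch)
}

# Control arm with planted deterministic structure (five duplicated binary
# covariates) for the detection lower-bound check.
planted_structure_control <- function(seed = 5) {
  d <- simulate_cohort(cohort_config(age_sd = 6, seed = seed))
  ctrl <- arm_split(d)[[1L]]
  df <- ctrl$data
  for (j in 1:5) df[[sprintf("bin%02d", j + 5)]] <- df[[sprintf("bin%02d", j)]]
  trial_dataset(df, ctrl$schema)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
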