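# Simulated two-arm advanced-NSCLC-like cohort. A structural stand-in for
# the registry extract every other module is exercised against: mostly
# binary covariates with balanced outcomes, a continuous age, right-censored
# overall survival with uniform accrual and an administrative cutoff. It is
# never a claim about the real registry distributions.

#' Configure the simulated trial cohort
#'
#' @param n_control,n_active Arm sizes (defaults mirror 397 chemotherapy
#'   controls and 248 active-arm patients, 645 total).
#' @param n_binary Number of balanced binary covariates (default 10).
#' @param n_categorical Number of 3-level categorical covariates (default 1).
#' @param log_hr_active True log hazard ratio of the active arm vs control
#'   (default `log(0.65)`, an active-arm survival benefit).
#' @param weibull_shape,weibull_scale Baseline Weibull hazard parameters
#'   (months); defaults shape 1.2, scale 16 put the control-arm median near
#'   12 months.
#' @param accrual_months Uniform accrual window (default 57, mirroring a
#'   Jan 2017 - Sep 2021 accrual).
#' @param followup_extra_months Administrative follow-up beyond accrual end
#'   (default 3, mirroring a Dec 2021 cutoff).
#' @param covariate_effect Scale of the per-covariate log hazard effects;
#'   effects alternate in sign and are bounded by this value (default 0.3).
#' @param binary_correlation Equicorrelation of the latent Gaussian behind
#'   the binary covariates (default 0.2, giving the generators dependence
#'   structure to capture).
#' @param age_mean,age_sd,age_range Age distribution (truncated normal).
#' @param arm_labels Two arm category labels, control first.
#' @param seed Integer seed stored in the config.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_control = 397L, n_active = 248L,
                          n_binary = 10L, n_categorical = 1L,
                          log_hr_active = log(0.65),
                          weibull_shape = 1.2, weibull_scale = 16,
                          accrual_months = 57, followup_extra_months = 3,
                          covariate_effect = 0.3,
                          binary_correlation = 0.2,
                          age_mean = 68, age_sd = 9, age_range = c(40, 90),
                          arm_labels = c("chemo", "pembro"),
                          seed = 1L) {
  check_(is_count_(n_control) && is_count_(n_active), "arm sizes must be >= 1")
  check_(n_binary >= 1L && n_categorical >= 0L, "need at least one binary covariate")
  check_(weibull_shape > 0 && weibull_scale > 0, "hazard parameters must be > 0")
  check_(accrual_months > 0 && followup_extra_months >= 0,
         "accrual/follow-up must be non-negative")
  check_(binary_correlation >= 0 && binary_correlation < 1,
         "binary_correlation must lie in [0, 1)")
  check_(length(arm_labels) == 2L, "exactly two arm labels required")
  structure(as.list(environment()), class = "cohort_config")
}

#' Paper-scale default cohort configuration
#'
#' 397 control + 248 active patients with 10 binary, 1 three-level
#' categorical and 1 continuous covariate (>= 75% of covariates binary), a
#' 57-month accrual window, administrative censoring 3 months after accrual
#' end, and an active-arm survival benefit.
#'
#' @param seed Integer seed.
#' @return A [cohort_config()].
#' @export
default_nsclc_config <- function(seed = 1L) cohort_config(seed = seed)

fixture_schema_ <- function(cfg) {
  feats <- list()
  for (i in seq_len(cfg$n_binary))
    feats[[length(feats) + 1L]] <- schema_feature(sprintf("bin%02d", i),
                                                  "binary",
                                                  categories = c("0", "1"))
  for (i in seq_len(cfg$n_categorical))
    feats[[length(feats) + 1L]] <- schema_feature(sprintf("cat%02d", i),
                                                  "categorical",
                                                  categories = c("a", "b", "c"))
  feats[[length(feats) + 1L]] <- schema_feature("age", "continuous")
  feats[[length(feats) + 1L]] <- schema_feature("os_months", "continuous",
                                                role = "survival_time")
  feats[[length(feats) + 1L]] <- schema_feature("os_event", "binary",
                                                role = "event_indicator",
                                                categories = c("0", "1"))
  feats[[length(feats) + 1L]] <- schema_feature("arm", "categorical",
                                                role = "arm",
                                                categories = cfg$arm_labels)
  trial_schema(feats)
}

#' Simulate the trial cohort
#'
#' Binary covariates are thresholded equicorrelated Gaussians with success
#' probabilities jittered around 0.5; age is truncated normal; event times
#' follow a Weibull proportional-hazards model whose linear predictor is the
#' arm effect plus small alternating covariate effects; censoring is uniform
#' accrual plus an administrative cutoff. Reproducible under the config seed.
#'
#' @param cfg A [cohort_config()].
#' @return A validated `trial_dataset`.
#' @export
simulate_cohort <- function(cfg) {
  check_(inherits(cfg, "cohort_config"), "cfg must be a cohort_config")
  check_(cfg$followup_extra_months + cfg$accrual_months > 0,
         "administrative cutoff precedes accrual start")
  n <- cfg$n_control + cfg$n_active
  schema <- fixture_schema_(cfg)
  with_seed_(cfg$seed, {
    arm <- c(rep(cfg$arm_labels[1L], cfg$n_control),
             rep(cfg$arm_labels[2L], cfg$n_active))
    # equicorrelated latent Gaussians -> jittered-balanced binaries
    p <- runif(cfg$n_binary, 0.45, 0.55)
    z0 <- rnorm(n)
    rho <- cfg$binary_correlation
    B <- vapply(seq_len(cfg$n_binary), function(j) {
      z <- sqrt(rho) * z0 + sqrt(1 - rho) * rnorm(n)
      as.integer(z < qnorm(p[j]))
    }, integer(n))
    C <- if (cfg$n_categorical > 0L)
      vapply(seq_len(cfg$n_categorical), function(j)
        sample(c("a", "b", "c"), n, replace = TRUE,
               prob = c(0.5, 0.3, 0.2)), character(n))
    else NULL
    age <- rtruncnorm_(n, cfg$age_mean, cfg$age_sd,
                       cfg$age_range[1L], cfg$age_range[2L])
    # linear predictor: arm effect + small alternating covariate effects
    beta_bin <- cfg$covariate_effect * (-1)^(seq_len(cfg$n_binary)) *
      seq_len(cfg$n_binary) / cfg$n_binary
    lp <- drop((B - 0.5) %*% beta_bin) +
      0.5 * cfg$covariate_effect * (age - cfg$age_mean) / cfg$age_sd +
      cfg$log_hr_active * (arm == cfg$arm_labels[2L])
    if (!is.null(C))
      lp <- lp + 0.3 * cfg$covariate_effect * (C[, 1L] == "c")
    T_event <- cfg$weibull_scale *
      (-log(runif(n)) / exp(lp))^(1 / cfg$weibull_shape)
    entry <- runif(n, 0, cfg$accrual_months)
    cutoff <- cfg$accrual_months + cfg$followup_extra_months
    C_admin <- cutoff - entry
    os <- pmin(T_event, C_admin)
    ev <- as.integer(T_event <= C_admin)
    df <- as.data.frame(B)
    names(df) <- sprintf("bin%02d", seq_len(cfg$n_binary))
    df[] <- lapply(df, as.character)
    if (!is.null(C))
      for (j in seq_len(cfg$n_categorical))
        df[[sprintf("cat%02d", j)]] <- C[, j]
    df$age <- age
    df$os_months <- pmax(os, 1e-6)
    df$os_event <- as.character(ev)
    df$arm <- arm
    trial_dataset(df, schema)
  })
}

#' Binary share of the covariate schema
#' @param schema A `trial_schema`.
#' @export
binary_covariate_share <- function(schema) {
  covs <- covariate_names(schema)
  mean(vapply(covs, function(f) schema[[f]]$ftype == "binary", logical(1L)))
}
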