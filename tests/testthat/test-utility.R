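test_that("Kaplan-Meier matches hand product-limit computations", {
  c1 <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(c1$survival, c(2 / 3, 1 / 3, 0))
  # censoring at t = 2: S(1) = 2/3, then the last subject's event empties
  # the risk set -> S(3) = 0
  c2 <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(c2$times, c(1, 3))
  expect_equal(c2$survival, c(2 / 3, 0))
  # all censored: S identically 1, median undefined
  c3 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_identical(surv_at(c3, c(0, 5)), c(1, 1))
  expect_error(km_median(c3), class = "synarm_undefined_median")
  expect_error(km_estimate(1:3, c(1, 1)), "length")
})

test_that("Kaplan-Meier agrees with the survival package on random data", {
  set.seed(21)
  for (i in 1:5) {
    tt <- round(rexp(60, 0.1), 1)
    ev <- rbinom(60, 1, 0.7)
    mine <- km_estimate(tt, ev)
    ref <- survival::survfit(survival::Surv(tt, ev) ~ 1)
    ref_s <- summary(ref, times = mine$times)
    expect_equal(mine$survival, ref_s$surv, tolerance = 1e-12)
  }
})

test_that("Cox fit recovers simulated effects", {
  # large-sample oracle: two-group exponential, true log-HR = log 2
  d <- exp_surv_dataset(2000, log_hr = log(2), seed = 31)
  f <- fit_cox(d, "grp")
  expect_true(f$converged)
  expect_lt(abs(f$coefficients[["grp"]] - log(2)), 3 * f$se[["grp"]])
  # null covariate stays within 3 SE of zero
  d0 <- exp_surv_dataset(2000, log_hr = 0, seed = 32)
  f0 <- fit_cox(d0, "grp")
  expect_lt(abs(f0$coefficients[["grp"]]), 3 * f0$se[["grp"]])
  # zero events: undefined partial likelihood
  dz <- exp_surv_dataset(50, seed = 33)
  df <- dz$data; df$ev <- "0"
  expect_error(fit_cox(trial_dataset(df, dz$schema), "grp"),
               class = "synarm_convergence_error")
})

test_that("Cox beta distance: identity, sign flip, symmetry", {
  d <- exp_surv_dataset(400, log_hr = log(2), seed = 41)
  expect_lt(cox_beta_distance(d, d, "grp"), 1e-6)
  # relabeling the group flips the coefficient sign; refit oracle says the
  # distance equals |beta1 - beta2| of the two actual fits
  df <- d$data
  df$grp <- factor(ifelse(df$grp == "1", "0", "1"), levels = c("0", "1"))
  d_flip <- trial_dataset(df, d$schema)
  b1 <- fit_cox(d, "grp")$coefficients[["grp"]]
  b2 <- fit_cox(d_flip, "grp")$coefficients[["grp"]]
  expect_equal(cox_beta_distance(d, d_flip, "grp"), abs(b1 - b2))
  expect_equal(cox_beta_distance(d, d_flip, "grp"), 2 * abs(b1),
               tolerance = 1e-4)
  expect_equal(cox_beta_distance(d_flip, d, "grp"),
               cox_beta_distance(d, d_flip, "grp"))
})

test_that("median survival distance follows the exponential oracle", {
  d1 <- exp_surv_dataset(4000, rate = 0.1, seed = 51)
  d2 <- exp_surv_dataset(4000, rate = 0.2, seed = 52)
  expect_identical(median_survival_distance(d1, d1), 0)
  # closed form: ln2/lambda - ln2/(2 lambda)
  truth <- log(2) / 0.1 - log(2) / 0.2
  expect_lt(abs(median_survival_distance(d1, d2) - truth), 0.6)
  # all-censored synthetic arm: undefined median policy
  df <- d2$data; df$ev <- "0"
  d_cens <- trial_dataset(df, d2$schema)
  expect_error(median_survival_distance(d1, d_cens),
               class = "synarm_undefined_median")
  expect_warning(median_survival_distance(d1, d_cens, fallback = "rmst"),
                 "restricted-mean")
})

test_that("survival curve distance integrates the merged step grid", {
  d <- exp_surv_dataset(100, seed = 61)
  expect_identical(survival_curve_distance(d, d), 0)
  # hand oracle: d1 events at 1, 2 -> S = 0.5 on [1,2), 0 after; d2 all
  # censored at 1, 2 -> S = 1; T = 2; area = |1-1|*1 + |1-0.5|*1 = 0.5
  mk <- function(ev) {
    df <- d$data[1:2, ]
    df$os <- c(1, 2); df$ev <- ev
    trial_dataset(df, d$schema)
  }
  expect_equal(survival_curve_distance(mk(c("1", "1")), mk(c("0", "0"))), 0.5)
  # order independence
  d2 <- exp_surv_dataset(80, rate = 0.2, seed = 62)
  expect_equal(survival_curve_distance(d, d2), survival_curve_distance(d2, d))
})

test_that("predicted survival distance is bounded and discriminates", {
  d <- simulate_cohort(cohort_config(n_control = 250L, n_active = 40L,
                                     seed = 71))
  ctrl <- arm_split(d)[[1L]]
  covs <- covariate_names(ctrl$schema)
  expect_lt(predicted_survival_distance(ctrl, ctrl, covs), 1e-3)
  df <- ctrl$data
  df$os_months <- df$os_months * 2
  d_shift <- trial_dataset(df, ctrl$schema)
  dist_shift <- predicted_survival_distance(ctrl, d_shift, covs)
  expect_gt(dist_shift, predicted_survival_distance(ctrl, ctrl, covs))
  expect_gte(dist_shift, 0)
  expect_lte(dist_shift, 1)
})

test_that("all four distances vanish for dummy at full sample size", {
  d <- simulate_cohort(cohort_config(n_control = 300L, n_active = 40L,
                                     seed = 81))
  ctrl <- arm_split(d)[[1L]]
  g <- fit_generator(generator_spec("dummy"), ctrl, seed = 1)
  syn <- sample_generator(g, n_patients(ctrl), seed = 2)
  covs <- covariate_names(ctrl$schema)
  expect_lt(cox_beta_distance(ctrl, syn, covs), 1e-3)
  expect_lt(median_survival_distance(ctrl, syn), 1e-3)
  expect_lt(survival_curve_distance(ctrl, syn), 1e-3)
  expect_lt(predicted_survival_distance(ctrl, syn, covs), 1e-3)
})
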