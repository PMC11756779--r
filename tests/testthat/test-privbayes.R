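# Fixture: all-categorical dataset with a controllable dependence between
# bin01 and bin02 (copy = perfectly correlated), bin03 independent.
pb_dataset <- function(n = 200, seed = 1, copy = TRUE) {
  set.seed(seed)
  b1 <- sample(c("0", "1"), n, TRUE)
  b2 <- if (copy) b1 else sample(c("0", "1"), n, TRUE)
  df <- data.frame(
    bin01 = b1, bin02 = b2, bin03 = sample(c("0", "1"), n, TRUE),
    bin04 = sample(c("0", "1"), n, TRUE),
    os = sample(c("lo", "mid", "hi"), n, TRUE, prob = c(0.5, 0.3, 0.2)),
    ev = sample(c("0", "1"), n, TRUE),
    arm = "ctl", stringsAsFactors = FALSE)
  sch <- trial_schema(
    schema_feature("bin01", "binary", categories = c("0", "1")),
    schema_feature("bin02", "binary", categories = c("0", "1")),
    schema_feature("bin03", "binary", categories = c("0", "1")),
    schema_feature("bin04", "binary", categories = c("0", "1")),
    schema_feature("os", "categorical", categories = c("lo", "mid", "hi"),
                   role = "survival_time", binned_from = "continuous"),
    schema_feature("ev", "binary", role = "event_indicator",
                   categories = c("0", "1")),
    schema_feature("arm", "categorical", role = "arm",
                   categories = c("ctl", "act")))
  trial_dataset(df, sch)
}

test_that("k = 0 forces the independent-marginals structure", {
  d <- pb_dataset(100, seed = 2)
  m <- fit_privbayes_structure(d, k = 0, epsilon_structure = 1, seed = 1)
  expect_true(all(lengths(m$parents) == 0L))
})

test_that("a perfectly correlated pair is linked at high epsilon", {
  # exact-MI oracle on the 2x2 table: I(bin01; bin02) = H(bin01) ~ 1 bit,
  # the largest MI in the dataset, so the exponential mechanism at eps 1e6
  # must link the pair (as parent or child) whichever is placed later.
  d <- pb_dataset(300, seed = 3, copy = TRUE)
  for (s in 1:3) {
    m <- fit_privbayes_structure(d, k = 1, epsilon_structure = 1e6, seed = s)
    linked <- "bin01" %in% m$parents[["bin02"]] ||
      "bin02" %in% m$parents[["bin01"]]
    expect_true(linked)
  }
})

test_that("eps -> 0 makes the first parent choice uniform", {
  # 3 features; after placing the first node, candidates for the exponential
  # mechanism are (node, parent set) pairs; with eps ~ 0 the pick must be
  # uniform. Chi-square over 200 seeded runs at alpha = 0.01.
  set.seed(4)
  df <- data.frame(a = sample(c("0", "1"), 60, TRUE),
                   t = sample(c("0", "1"), 60, TRUE),
                   e = sample(c("0", "1"), 60, TRUE),
                   arm = "x", stringsAsFactors = FALSE)
  sch <- trial_schema(
    schema_feature("a", "binary", categories = c("0", "1")),
    schema_feature("t", "categorical", categories = c("0", "1"),
                   role = "survival_time", binned_from = "continuous"),
    schema_feature("e", "binary", role = "event_indicator",
                   categories = c("0", "1")),
    schema_feature("arm", "categorical", role = "arm",
                   categories = c("x", "y")))
  d <- trial_dataset(df, sch)
  picks <- vapply(1:200, function(s) {
    m <- fit_privbayes_structure(d, k = 1, epsilon_structure = 1e-9, seed = s)
    m$order[2L]  # first exponential-mechanism pick; uniform by symmetry
  }, integer(1L))
  tab <- tabulate(picks, nbins = 4)
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})

test_that("noisy conditionals renormalize and fall back to uniform", {
  d <- pb_dataset(2000, seed = 5, copy = FALSE)
  m <- fit_privbayes_structure(d, k = 1, epsilon_structure = 1e6, seed = 1)
  m <- fit_privbayes_conditionals(d, m, epsilon_params = 1e6, seed = 2)
  # plug-in frequency oracle at eps = 1e6: tables match empirical conditionals
  X <- vapply(d$data, as.integer, integer(2000))
  for (f in names(m$tables)) {
    tab <- m$tables[[f]]
    j <- match(f, m$features)
    emp_cfg <- synarm:::config_index_(X, tab$parents, m$card)
    for (cf in unique(emp_cfg)) {
      emp <- tabulate(X[emp_cfg == cf, j], nbins = m$card[j])
      expect_lt(max(abs(tab$probs[cf, ] - emp / sum(emp))), 0.01)
    }
    expect_equal(unname(rowSums(tab$probs)), rep(1, nrow(tab$probs)))
  }
  # heavy noise: all rows still sum to 1
  m2 <- fit_privbayes_conditionals(d, m, epsilon_params = 0.01, seed = 3)
  for (f in names(m2$tables))
    expect_equal(unname(rowSums(m2$tables[[f]]$probs)),
                 rep(1, nrow(m2$tables[[f]]$probs)))
})

test_that("ancestral sampling respects the fitted law", {
  # deterministic chain: bin02 copies bin01 with point-mass tables
  d <- pb_dataset(400, seed = 6, copy = TRUE)
  m <- fit_privbayes_structure(d, k = 1, epsilon_structure = 1e6, seed = 1)
  m <- fit_privbayes_conditionals(d, m, epsilon_params = 1e6, seed = 2)
  s <- sample_bayesnet(m, 500, seed = 3)
  expect_gt(mean(as.character(s$bin01) == as.character(s$bin02)), 0.98)

  # binomial oracle on a single node's marginal
  d2 <- pb_dataset(5000, seed = 7, copy = FALSE)
  m2 <- fit_privbayes_structure(d2, k = 0, epsilon_structure = 1e6, seed = 1)
  m2 <- fit_privbayes_conditionals(d2, m2, epsilon_params = 1e6, seed = 2)
  s2 <- sample_bayesnet(m2, 1e4, seed = 4)
  p_emp <- mean(d2$data$os == "lo")
  expect_lt(abs(mean(s2$os == "lo") - p_emp), 0.015)

  # independent structure: pairwise MI of samples stays near zero
  X <- cbind(as.integer(s2$bin01), as.integer(s2$bin03))
  mi <- synarm:::mi_bits_(X[, 1], 2L, X[, 2], 2L)
  expect_lt(mi, 0.01)
})

test_that("privbayes epsilon accounting composes sequentially", {
  d <- pb_dataset(150, seed = 8)
  g <- fit_generator(generator_spec("privbayes", epsilon = 10,
                                    structure_share = 0.3), d, seed = 1)
  expect_equal(g$state$epsilon_total, 10)
  expect_equal(g$state$model$epsilon_params, 7)
  syn <- sample_generator(g, 150, seed = 2)
  expect_identical(n_patients(syn), 150L)
})
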