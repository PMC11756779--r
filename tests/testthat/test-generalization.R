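test_that("quantile bins equalize counts and handle degenerate inputs", {
  sp <- fit_quantile_bins(c(1, 2, 3, 4), 2)
  # brute-force oracle: each bin should hold exactly half the sorted vector
  idx <- findInterval(c(1, 2, 3, 4), sp$edges, rightmost.closed = TRUE)
  expect_identical(tabulate(idx, nbins = 2), c(2L, 2L))

  sp1 <- fit_quantile_bins(rnorm(50), 1)
  expect_identical(sp1$n_bins, 1L)

  expect_warning(sp3 <- fit_quantile_bins(rep(2, 10), 3), "collapsed")
  expect_identical(sp3$n_bins, 1L)
  expect_error(fit_quantile_bins(numeric(0), 2), "non-empty")
})

test_that("generalize maps values to half-open bins with closed top", {
  d <- basic_dataset(4, seed = 1)
  d$data$age <- c(63, 50, 60, 70)
  d <- trial_dataset(d$data, d$schema)
  sp <- bin_spec("age", c(50, 60, 70))
  g <- generalize(d, sp)
  expect_identical(as.character(g$data$age),
                   c("[60,70]", "[50,60)", "[60,70]", "[60,70]"))
  d$data$age[1] <- 71
  expect_error(generalize(trial_dataset(d$data, d$schema), sp), "row 1")
})

test_that("laplace mechanism is calibrated", {
  expect_identical(laplace_noise(5, 1, Inf), 5)
  x <- laplace_noise(rep(5, 2e4), sensitivity = 1, epsilon = 1, seed = 11)
  expect_lt(abs(mean(x) - 5), 3 * sqrt(2) / sqrt(2e4))
  expect_lt(abs(var(x) / 2 - 1), 0.10)
  expect_error(laplace_noise(1, 0, 1), "sensitivity")
  expect_error(laplace_noise(1, 1, -2), "epsilon")
})

test_that("DP bin parameters: clamping, floors and empty-bin fallback", {
  b <- privacy_budget(Inf)
  p <- estimate_bin_params_dp(rep(3, 20), c(0, 10), b)
  expect_identical(p$mean, 3)
  expect_identical(p$sd, 10 * 1e-3)  # sd floor

  p0 <- estimate_bin_params_dp(numeric(0), c(2, 4), privacy_budget(1))
  expect_true(p0$empty_flag)
  expect_identical(p0$mean, 3)
  expect_equal(p0$sd, 2 / sqrt(12))

  set.seed(8)
  v <- pmin(pmax(rnorm(1000), -1), 1)
  p1 <- estimate_bin_params_dp(v, c(-1, 1), privacy_budget(1e6), seed = 3)
  expect_lt(abs(p1$mean - mean(v)), 0.01)
  expect_lt(abs(p1$sd - sd(v)), 0.01)
  expect_error(estimate_bin_params_dp(1:3, c(0, Inf), b), "bounded")
})

test_that("reversal stays inside bins and roundtrips bin labels", {
  d <- basic_dataset(200, seed = 6)
  map <- fit_generalization_map(d, n_bins = 5, budget = privacy_budget(1),
                                seed = 2)
  db <- generalize(d, map)
  dr <- reverse_generalize(db, map, seed = 3)
  for (f in c("age", "os")) {
    sp <- map$specs[[f]]
    idx <- findInterval(dr$data[[f]], sp$edges, rightmost.closed = TRUE)
    expect_identical(as.character(db$data[[f]]), sp$labels[idx])
  }
  # regeneralizing reproduces the labels exactly
  expect_identical(generalize(dr, map)$data$age, db$data$age)
  # reproducible under seed
  dr2 <- reverse_generalize(db, map, seed = 3)
  expect_identical(dr$data, dr2$data)
  expect_true(all(dr$data$os >= 0))
})

test_that("unknown bin label in reversal is reported", {
  d <- basic_dataset(30, seed = 2)
  map <- fit_generalization_map(d, n_bins = 4, seed = 1)
  db <- generalize(d, map)
  map2 <- fit_generalization_map(d, n_bins = 3, seed = 1)
  expect_error(reverse_generalize(db, map2), "absent from map")
})

test_that("epsilon accounting uses parallel composition across bins", {
  d <- basic_dataset(80, seed = 3)
  map <- fit_generalization_map(d, n_bins = 8, budget = privacy_budget(2),
                                seed = 1)
  expect_identical(map$epsilon_per_feature, 2)     # not 2 * n_bins
  expect_identical(map$epsilon_total, 2 * 2)       # two features, sequential
  mapu <- fit_generalization_map(d, n_bins = 8, reversal = "uniform")
  expect_identical(mapu$epsilon_total, 0)
})

test_that("with eps -> Inf reversed per-bin means converge to originals", {
  d <- basic_dataset(2000, seed = 12)
  map <- fit_generalization_map(d, features = "age", n_bins = 4,
                                budget = privacy_budget(Inf), seed = 2)
  db <- generalize(d, map)
  dr <- reverse_generalize(db, map, seed = 5)
  sp <- map$specs$age
  idx <- findInterval(d$data$age, sp$edges, rightmost.closed = TRUE)
  for (b in seq_len(sp$n_bins)) {
    orig <- d$data$age[idx == b]
    rev <- dr$data$age[idx == b]
    expect_lt(abs(mean(rev) - mean(orig)), 3 * sd(orig) / sqrt(length(orig)))
  }
})

test_that("generalization map serializes to JSON", {
  d <- basic_dataset(50, seed = 2)
  map <- fit_generalization_map(d, n_bins = 3, seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_generalization_map(map, path)
  ser <- jsonlite::read_json(path)
  expect_identical(length(ser$features), 2L)
  expect_identical(ser$features[[1]]$feature, "age")
})
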