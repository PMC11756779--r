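test_that("mixed distance matches hand Gower computations", {
  d <- basic_dataset(5, seed = 1)
  sch <- d$schema
  a <- d$data[1, ]
  expect_identical(mixed_distance(a, a, sch), 0)
  # one continuous feature at its range endpoints, everything else equal:
  # contribution 1 for that feature, 0 elsewhere -> 1/p
  b <- a
  rng <- list(age = c(40, 90), os = c(0, 50))
  a$age <- 40; b$age <- 90
  expect_equal(mixed_distance(a, b, sch, rng), 1 / length(sch))
  # all categoricals differ and continuous at endpoints -> 1
  b2 <- a
  b2$bin01 <- "1"; a$bin01 <- "0"
  for (f in c("bin02", "bin03", "bin04", "ev")) {
    a[[f]] <- "0"; b2[[f]] <- "1"
  }
  a$arm <- "ctl"; b2$arm <- "act"
  a$age <- 40; b2$age <- 90; a$os <- 0; b2$os <- 50
  expect_equal(mixed_distance(a, b2, sch, rng), 1)
})

test_that("mixed distance is a metric on random record triples", {
  d <- basic_dataset(30, seed = 3)
  sch <- d$schema
  rng <- list(age = range(d$data$age), os = range(d$data$os))
  set.seed(4)
  for (i in 1:20) {
    idx <- sample.int(30, 3)
    a <- d$data[idx[1], ]; b <- d$data[idx[2], ]; c <- d$data[idx[3], ]
    dab <- mixed_distance(a, b, sch, rng)
    expect_identical(dab, mixed_distance(b, a, sch, rng))
    expect_lte(dab, mixed_distance(a, c, sch, rng) +
                 mixed_distance(c, b, sch, rng) + 1e-12)
  }
})

test_that("CAP covers worst case, chance level and no-overlap", {
  # unique key combinations + identical synthetic -> perfect attribution
  grid <- expand.grid(bin01 = c("0", "1"), bin02 = c("0", "1"),
                      bin03 = c("0", "1"), bin04 = c("0", "1"),
                      stringsAsFactors = FALSE)
  df <- data.frame(grid, age = 50, os = 10,
                   ev = rep(c("0", "1"), 8), arm = "ctl",
                   stringsAsFactors = FALSE)
  d <- trial_dataset(df, basic_schema())
  expect_identical(
    cap_categorical(d, d, c("bin01", "bin02", "bin03", "bin04"), "ev"), 0)
  # no key overlap: attacker never attributes -> full safety
  df2 <- df
  df2$bin01 <- "1"; df2$bin02 <- "1"; df2$bin03 <- "1"
  df_orig <- df
  df_orig$bin01 <- "0"; df_orig$bin02 <- "0"; df_orig$bin03 <- "0"
  expect_identical(
    cap_categorical(trial_dataset(df_orig, basic_schema()),
                    trial_dataset(df2, basic_schema()),
                    c("bin01", "bin02", "bin03"), "bin04"), 1)
  # Monte-Carlo oracle: synthetic target independent of keys, balanced
  # binary target -> attribution ~ 0.5
  d_big <- basic_dataset(4000, seed = 5)
  df_s <- d_big$data
  set.seed(6)
  df_s$bin04 <- sample(df_s$bin04)
  d_shuf <- trial_dataset(df_s, d_big$schema)
  cap <- cap_categorical(d_big, d_shuf, c("bin01", "bin02", "bin03"), "bin04")
  expect_lt(abs(cap - 0.5), 0.05)
  expect_error(cap_categorical(d_big, d_big, c("bin01"), "bin01"), "keys")
})

test_that("DCR matches the brute-force all-pairs oracle", {
  d <- basic_dataset(10, seed = 7)
  expect_identical(dcr(d, d), 0)
  # hand-set 2x2 case on a single varying continuous feature
  df_o <- d$data[1:2, ]
  df_o$age <- c(50, 70); df_o[, c("bin01", "bin02", "bin03", "bin04")] <- "0"
  df_o$os <- 10; df_o$ev <- "1"; df_o$arm <- "ctl"
  df_s <- df_o
  df_s$age <- c(55, 90)
  o <- trial_dataset(df_o, d$schema); s <- trial_dataset(df_s, d$schema)
  # ranges from original: age range 20 -> d(55,.) = min(5,15)/20 / 8 features
  p <- length(d$schema)
  expected <- median(c((5 / 20) / p, (20 / 20) / p))
  expect_equal(dcr(o, s), expected)
})

test_that("NNDR follows the sorted-distance oracle and its conventions", {
  d <- basic_dataset(6, seed = 8)
  df <- d$data
  df[, c("bin01", "bin02", "bin03", "bin04")] <- "0"
  df$os <- 10; df$ev <- "1"; df$arm <- "ctl"
  df$age <- c(0, 1, 2, 3, 4, 10) + 50
  o <- trial_dataset(df, d$schema)
  q <- function(x) {
    df2 <- df[1, , drop = FALSE]
    df2$age <- x + 50
    trial_dataset(df2, d$schema)
  }
  # from 0: d1 = 0 -> ratio 0; from 2.5: 0.5/2.5 = 0.2 (range cancels)
  expect_identical(nndr(o, q(0)), 0)
  expect_equal(nndr(o, q(2.5)), 0.2)
  # coincident 5th neighbour distance 0 -> ratio 1
  df_same <- df
  df_same$age <- 50
  o_same <- trial_dataset(df_same, d$schema)
  expect_identical(nndr(o_same, q(0)), 1)
  expect_error(nndr(trial_dataset(df[1:4, ], d$schema), q(1)), "at least 5")
})

test_that("NNDR is invariant under affine rescaling of continuous features", {
  d <- basic_dataset(40, seed = 9)
  s <- basic_dataset(15, seed = 10)
  v1 <- nndr(d, s)
  scale_ <- function(x, f) {
    df <- x$data
    df$age <- df$age * 3 + 100
    trial_dataset(df, x$schema)
  }
  expect_equal(nndr(scale_(d), scale_(s)), v1, tolerance = 1e-12)
})

test_that("detection score is bounded and validates inputs", {
  d <- basic_dataset(40, seed = 11)
  s <- basic_dataset(40, seed = 12)
  a <- detection_score(d, s, seed = 1, rounds = 10L)
  expect_gte(a, 0); expect_lte(a, 1)
  expect_error(detection_score(basic_dataset(5, seed = 1), s), "at least 10")
})

test_that("privacy report assembles scores and flags memorization", {
  d <- basic_dataset(120, seed = 13)
  sp <- split_holdout(d, 0.25, seed = 2)
  g <- fit_generator(generator_spec("dummy"), sp$train, seed = 1)
  syn <- sample_generator(g, n_patients(sp$train), seed = 2)
  rep <- privacy_report(sp$train, sp$holdout, syn, seed = 3)
  expect_true(rep$risk_flag)   # dummy: dcr = 0 <= any holdout dcr
  expect_identical(rep$dcr, 0)
  # substitution identity: synthetic = holdout -> dcr equals holdout_dcr
  rep2 <- privacy_report(sp$train, sp$holdout, sp$holdout, seed = 3)
  expect_identical(rep2$dcr, rep2$holdout_dcr)
  expect_identical(rep2$nndr, rep2$holdout_nndr)
  # ranges on a random fixture
  for (v in c(rep$cap_score, rep$detection_score, rep$nndr,
              rep$holdout_nndr)) {
    expect_gte(v, 0); expect_lte(v, 1)
  }
  expect_gte(rep$dcr, 0)
})
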