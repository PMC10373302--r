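test_that("mode imputation fills the most frequent value, ties to smaller", {
  expect_equal(impute_mode(c(1, 1, 0, NA)), c(1, 1, 0, 1))
  expect_equal(impute_mode(c(0, 1, NA)), c(0, 1, 0))
  expect_equal(impute_mode(c(1, 0, 1)), c(1, 0, 1))
})

test_that("mean imputation uses the observed arithmetic mean", {
  expect_equal(impute_mean(c(2, 4, NA)), c(2, 4, 3))
  expect_equal(impute_mean(c(5, NA, NA)), c(5, 5, 5))
  expect_equal(impute_mean(c(7, 7, NA)), c(7, 7, 7))
})

test_that("nan-replace writes the fill value into every missing cell", {
  expect_equal(impute_nan_replace(c(1, NA, 0)), c(1, 0, 0))
  expect_equal(impute_nan_replace(c(1, NA, 0), fill_value = -1), c(1, -1, 0))
  expect_equal(impute_nan_replace(c(1, 0)), c(1, 0))
})

test_that("random imputation samples the empirical observed distribution", {
  # degenerate: all observed ones
  set.seed(1)
  expect_equal(impute_random(c(1, 1, NA, NA)), c(1, 1, 1, 1))
  # determinism given seed
  x <- c(rep(c(0, 1, 1, 1), 5), rep(NA, 10))
  a <- negdrop:::with_rng_seed(99L, impute_random(x))
  b <- negdrop:::with_rng_seed(99L, impute_random(x))
  expect_identical(a, b)
  # frequency matches the empirical rate within 3 binomial sigmas
  x <- c(rep(1, 75), rep(0, 25), rep(NA, 10000))
  set.seed(4)
  filled <- impute_random(x)[101:10100]
  se <- sqrt(0.75 * 0.25 / 10000)
  expect_lt(abs(mean(filled) - 0.75), 3 * se)
})

test_that("Bayesian imputation draws from the Beta-Bernoulli posterior predictive", {
  # observed [1,1,1,0]: P(1) = (3+1)/(4+2) = 2/3
  x <- c(1, 1, 1, 0, rep(NA, 30000))
  set.seed(8)
  filled <- impute_bayes(x)[5:30004]
  p <- 2 / 3
  expect_lt(abs(mean(filled) - p), 3 * sqrt(p * (1 - p) / 30000))
  # balanced observed: predictive 1/2
  x <- c(0, 1, 0, 1, rep(NA, 30000))
  set.seed(9)
  filled <- impute_bayes(x)[5:30004]
  expect_lt(abs(mean(filled) - 0.5), 3 * sqrt(0.25 / 30000))
  # determinism given seed; boolean-only contract
  a <- negdrop:::with_rng_seed(7L, impute_bayes(c(1, 0, NA)))
  b <- negdrop:::with_rng_seed(7L, impute_bayes(c(1, 0, NA)))
  expect_identical(a, b)
  expect_error(impute_bayes(c(0.5, NA)), "boolean")
})

test_that("all-missing columns raise errors naming the operation", {
  expect_error(impute_mode(c(NA_real_, NA_real_)), "entirely missing")
  expect_error(impute_mean(c(NA_real_, NA_real_)), "entirely missing")
  sch <- toy_schema(n_bool = 2L, n_cont = 0L)
  vals <- matrix(c(1, 0, NA, NA), 2, 2)
  tab <- clinical_table(vals, c("k1", "k2"), sch)
  expect_error(impute_table(tab, imputation_policy("mode")), "b2")
})

test_that("table imputation clears the mask, routes by type and never touches observed cells", {
  sch <- toy_schema(n_bool = 3L, n_cont = 2L)
  tab <- toy_table(30L, sch, seed = 3L)
  set.seed(42)
  mask <- matrix(FALSE, 30L, 5L)
  mask[cbind(sample.int(30L, 8L), sample(1:3, 8L, replace = TRUE))] <- TRUE
  mask[cbind(c(2L, 17L), c(4L, 5L))] <- TRUE
  vals <- tab$values; vals[mask] <- NA
  tab <- clinical_table(vals, tab$labels, sch, mask)
  for (strat in c("mode", "random", "bayesian", "nan_replace")) {
    pol <- imputation_policy(strat, seed = 5L)
    out <- impute_table(tab, pol)
    expect_false(any(out$missing_mask))
    expect_identical(out$values[!mask], tab$values[!mask])
    expect_true(all(out$values[, 1:3] %in% c(0, 1)))
    # continuous missing filled by the column mean regardless of strategy
    expect_equal(unname(out$values[2, 4]), mean(tab$values[-2, 4]))
  }
})

test_that("imputation is the identity on complete tables for every strategy", {
  tab <- toy_table(15L, seed = 12L)
  for (strat in c("mode", "random", "bayesian", "nan_replace")) {
    out <- impute_table(tab, imputation_policy(strat, seed = 1L))
    expect_equal(out$values, tab$values)
  }
})

test_that("stochastic strategies are reproducible given the policy seed", {
  sch <- toy_schema(n_bool = 4L, n_cont = 0L)
  set.seed(21)
  vals <- matrix(rbinom(80, 1L, 0.6), 20, 4)
  vals[sample.int(80, 15)] <- NA
  tab <- clinical_table(vals, rep(c("k1", "k2"), 10), sch)
  for (strat in c("random", "bayesian")) {
    a <- impute_table(tab, imputation_policy(strat, seed = 33L))
    b <- impute_table(tab, imputation_policy(strat, seed = 33L))
    d <- impute_table(tab, imputation_policy(strat, seed = 34L))
    expect_identical(a$values, b$values)
    expect_false(identical(a$values, d$values))
  }
})

test_that("policy validation enforces seeds for stochastic strategies", {
  expect_error(imputation_policy("random"), "seed")
  expect_error(imputation_policy("bayesian"), "seed")
  expect_s3_class(imputation_policy("mode"), "imputation_policy")
})

test_that("train-only statistics use only the designated rows", {
  sch <- toy_schema(n_bool = 1L, n_cont = 1L)
  vals <- matrix(c(1, 1, 0, NA,
                   2, 4, 100, NA), 4, 2)
  tab <- clinical_table(vals, rep(c("k1", "k2"), 2), sch)
  pol <- imputation_policy("mode", statistics = "train")
  out <- impute_table(tab, pol, stat_rows = 1:2)
  expect_equal(unname(out$values[4, 1]), 1)       # mode of rows 1:2
  expect_equal(unname(out$values[4, 2]), 3)       # mean of rows 1:2
})
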