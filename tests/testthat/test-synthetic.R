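test_that("the built-in clinical profile meets its dataset contract", {
  spec <- clinical_profile()
  tab <- generate_clinical_dataset(spec)
  expect_equal(dim(tab$values), c(1920L, 24L))
  expect_equal(length(tab$schema$class_labels), 7L)
  expect_equal(sum(tab$schema$feature_types == "boolean"), 22L)
  expect_equal(sum(tab$missing_mask), 275L)
  # continuous columns never missing
  ci <- which(tab$schema$feature_types == "continuous")
  expect_true(all(!tab$missing_mask[, ci]))
})

test_that("generation is bit-identical under a fixed seed", {
  spec <- clinical_profile(seed = 77L)
  a <- generate_clinical_dataset(spec)
  b <- generate_clinical_dataset(spec)
  d <- generate_clinical_dataset(spec, seed = 78L)
  expect_identical(a$values, b$values)
  expect_identical(a$missing_mask, b$missing_mask)
  expect_false(identical(a$values, d$values))
})

test_that("missing cells are uniform over boolean cells across seeds", {
  # chi-square over column totals of injected missingness
  spec <- clinical_profile(missing_count = 200L)
  counts <- numeric(22)
  for (s in 1:15) {
    tab <- generate_clinical_dataset(spec, seed = s)
    counts <- counts + colSums(tab$missing_mask[, 1:22])
  }
  expect_equal(sum(counts), 15 * 200)
  chi <- sum((counts - mean(counts))^2 / mean(counts))
  expect_lt(chi, qchisq(0.999, df = 21))
})

test_that("exact missing counts and the rate-based alternative both work", {
  spec <- clinical_profile(missing_count = 0L)
  expect_equal(sum(generate_clinical_dataset(spec)$missing_mask), 0L)
  spec$missing_count <- NULL
  spec$missing_rate <- 0.05
  tab <- generate_clinical_dataset(spec, seed = 3L)
  frac <- sum(tab$missing_mask) / (1920 * 22)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / (1920 * 22)))
  expect_error(clinical_profile(missing_count = 1920L * 22L + 1L),
               "exceeds")
})

test_that("separation 0 collapses the classes to chance level", {
  spec <- clinical_profile(separation = 0, missing_count = 0L)
  bo <- bayes_optimal_accuracy(spec, n_mc = 8000L, seed = 2L)
  expect_lt(abs(bo$accuracy - 1 / 7), 0.02)
})

test_that("a deterministic feature per class makes the oracle perfect", {
  bern <- diag(3)            # class c always shows symptom c, never others
  spec <- generator_spec(n_rows = 100L, n_boolean = 3L, n_continuous = 0L,
                         n_classes = 3L, bernoulli = bern,
                         cont_means = matrix(0, 3, 0),
                         cont_sds = matrix(0, 3, 0),
                         cont_ranges = list(), seed = 4L)
  bo <- bayes_optimal_accuracy(spec, n_mc = 2000L, seed = 1L)
  expect_equal(bo$accuracy, 1.0)
})

test_that("the benchmark oracle exceeds 0.95 and reports its standard error", {
  bo <- bayes_optimal_accuracy(clinical_profile(), n_mc = 20000L, seed = 1L)
  expect_gt(bo$accuracy, 0.95)
  expect_true(bo$se > 0 && bo$se < 0.01)
})

test_that("generated tables satisfy container invariants and survive CSV round-trips", {
  spec <- clinical_profile()
  tab <- generate_clinical_dataset(spec, seed = 5L)
  bi <- which(tab$schema$feature_types == "boolean")
  obs <- !tab$missing_mask[, bi]
  expect_true(all(tab$values[, bi][obs] %in% c(0, 1)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_clinical_csv(tab, path)
  back <- read_clinical_csv(path, tab$schema)
  expect_equal(back$values, tab$values)
  expect_identical(back$missing_mask, tab$missing_mask)
  expect_identical(back$labels, tab$labels)
})

test_that("MAR hook tilts missingness with the driving feature", {
  spec <- clinical_profile(missing_count = 2000L)
  spec$mar_feature <- 1L
  spec$mar_slope <- 2
  tab <- generate_clinical_dataset(spec, seed = 6L)
  drv <- tab$values[, 23]
  nmiss <- rowSums(tab$missing_mask)
  expect_gt(cor(drv, nmiss), 0.1)
})
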