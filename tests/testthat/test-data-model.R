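test_that("CSV round-trip preserves values, mask and labels", {
  sch <- toy_schema(n_bool = 3L, n_cont = 2L)
  tab <- toy_table(10L, sch, seed = 7L)
  # knock out a few boolean cells
  tab$missing_mask[cbind(c(1, 4, 9), c(1, 2, 3))] <- TRUE
  tab <- clinical_table(tab$values, tab$labels, sch, tab$missing_mask)
  path <- withr::local_tempfile(fileext = ".csv")
  write_clinical_csv(tab, path)
  back <- read_clinical_csv(path, sch)
  expect_identical(back$missing_mask, tab$missing_mask)
  expect_equal(back$values, tab$values)
  expect_identical(back$labels, tab$labels)
})

test_that("missing markers are detected and counted", {
  sch <- toy_schema(n_bool = 2L, n_cont = 0L)
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("b1,b2,label", "1,,k1", "0,1,k2", "NA,1,k1"), path)
  tab <- read_clinical_csv(path, sch)
  expect_equal(sum(tab$missing_mask), 2L)
  expect_true(tab$missing_mask[1, 2])
  expect_true(tab$missing_mask[3, 1])
})

test_that("invalid CSV content raises informative errors", {
  sch <- toy_schema(n_bool = 2L, n_cont = 0L)
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("b1,b2,label", "1,2,k1"), path)
  expect_error(read_clinical_csv(path, sch), "boolean.*b2.*row 2")
  writeLines(c("b1,b2,extra,label", "1,0,5,k1"), path)
  expect_error(read_clinical_csv(path, sch), "unknown column")
  writeLines(c("b1,label", "1,k1"), path)
  expect_error(read_clinical_csv(path, sch), "missing column")
})

test_that("empty table writes a header-only CSV", {
  sch <- toy_schema(n_bool = 2L, n_cont = 0L)
  tab <- clinical_table(matrix(numeric(0), 0, 2), character(0), sch)
  path <- withr::local_tempfile(fileext = ".csv")
  write_clinical_csv(tab, path)
  expect_length(readLines(path), 1L)
})

test_that("missingness filter keeps the boundary row and preserves order", {
  sch <- toy_schema(n_bool = 5L, n_cont = 0L)
  vals <- matrix(1, 4, 5)
  mask <- matrix(FALSE, 4, 5)
  mask[2, 1:4] <- TRUE   # 4 missing -> dropped
  mask[3, 1:3] <- TRUE   # exactly 3 -> kept
  vals[mask] <- NA
  tab <- clinical_table(vals, rep(c("k1", "k2"), 2), sch, mask)
  out <- filter_rows_by_missingness(tab, 3L)
  expect_equal(nrow(out$values), 3L)
  expect_equal(out$labels, tab$labels[c(1, 3, 4)])
  # vacuous filter
  expect_equal(nrow(filter_rows_by_missingness(tab, 5L)$values), 4L)
})

test_that("stratified split reproduces the canonical 70/30 counts", {
  for (case in list(c(683L, 478L), c(768L, 537L), c(1920L, 1344L))) {
    n <- case[1]
    sch <- toy_schema(n_bool = 2L, n_cont = 0L)
    set.seed(3)
    vals <- matrix(rbinom(n * 2L, 1L, 0.5), n, 2L)
    labs <- sch$class_labels[rep_len(1:2, n)]
    tab <- clinical_table(vals, labs, sch)
    sp <- stratified_split(tab, 0.7, seed = 11L)
    expect_equal(length(sp$train_indices), case[2])
    expect_equal(length(sp$test_indices), n - case[2])
  }
})

test_that("split is seed-reproducible, disjoint and count-stable across seeds", {
  tab <- toy_table(101L, toy_schema(n_classes = 3L), seed = 5L)
  a <- stratified_split(tab, 0.7, seed = 42L)
  b <- stratified_split(tab, 0.7, seed = 42L)
  c <- stratified_split(tab, 0.7, seed = 43L)
  expect_identical(a, b)
  expect_false(identical(a$train_indices, c$train_indices))
  expect_equal(length(c$train_indices), length(a$train_indices))
  expect_length(intersect(a$train_indices, a$test_indices), 0L)
  expect_setequal(c(a$train_indices, a$test_indices), seq_len(101L))
})

test_that("train size equals floor(fraction * n) over a sweep of n", {
  sch <- toy_schema(n_bool = 1L, n_cont = 0L)
  for (n in seq(2L, 500L, by = 7L)) {
    vals <- matrix(rep_len(c(0, 1), n), n, 1L)
    labs <- sch$class_labels[rep_len(1:2, n)]
    tab <- clinical_table(vals, labs, sch)
    sp <- stratified_split(tab, 0.7, seed = n)
    expect_equal(length(sp$train_indices), floor(0.7 * n))
  }
})

test_that("per-class allocation is stratified", {
  sch <- toy_schema(n_bool = 1L, n_cont = 0L, n_classes = 3L)
  n_per <- c(50L, 30L, 20L)
  labs <- rep(sch$class_labels, n_per)
  vals <- matrix(rep_len(c(0, 1), 100L), 100L, 1L)
  tab <- clinical_table(vals, labs, sch)
  sp <- stratified_split(tab, 0.7, seed = 1L)
  y <- class_index(tab)
  per_class_train <- table(y[sp$train_indices])
  expect_equal(as.integer(per_class_train), c(35L, 21L, 14L))
})

test_that("table validation rejects malformed inputs", {
  sch <- toy_schema(n_bool = 2L, n_cont = 0L)
  expect_error(clinical_table(matrix(c(1, 2, 0, 1), 2, 2), c("k1", "k2"), sch),
               "non-binary")
  expect_error(clinical_table(matrix(0, 2, 2), c("k1", "zz"), sch),
               "labels not in schema")
  expect_error(feature_schema(c("a", "a"), c("boolean", "boolean"),
                              c("k1", "k2")), "unique")
})
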