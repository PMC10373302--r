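tiny_backbone <- function(tab, dropout, seed = 1L) {
  build_backbone(backbone_config(ncol(tab$values),
                                 length(tab$schema$class_labels),
                                 hidden_size = 8L, depth = 2L,
                                 dropout_rate = dropout), seed = seed)
}

test_that("alpha = 0 training equals an independent dual-pass CE loop", {
  tab <- bool_table(40L)
  cfg <- train_config(alpha = 0, dropout_rate = 0.3, batch_size = 16L,
                      epochs = 3L, base_seed = 5L)
  fit <- train_model(tiny_backbone(tab, 0.3, 5L), tab, NULL, cfg)
  ref <- reference_train(tiny_backbone(tab, 0.3, 5L), tab, cfg, "dual_ce")
  expect_lt(max_param_diff(fit$model$params, ref$params), 1e-10)
})

test_that("dropping the negative term equals an independent R-Drop loop", {
  tab <- bool_table(40L)
  cfg <- train_config(alpha = 1.5, dropout_rate = 0.3, batch_size = 16L,
                      epochs = 3L, base_seed = 6L, use_negative = FALSE)
  fit <- train_model(tiny_backbone(tab, 0.3, 6L), tab, NULL, cfg)
  ref <- reference_train(tiny_backbone(tab, 0.3, 6L), tab, cfg, "rdrop")
  expect_lt(max_param_diff(fit$model$params, ref$params), 1e-10)
})

test_that("dropout 0 and alpha 0 equal an independent plain-CE loop", {
  tab <- bool_table(40L)
  cfg <- train_config(alpha = 0, dropout_rate = 0, batch_size = 16L,
                      epochs = 3L, base_seed = 7L)
  fit <- train_model(tiny_backbone(tab, 0, 7L), tab, NULL, cfg)
  ref <- reference_train(tiny_backbone(tab, 0, 7L), tab, cfg, "plain_ce")
  expect_lt(max_param_diff(fit$model$params, ref$params), 1e-10)
})

test_that("zero epochs leave the model untouched and the history empty", {
  tab <- bool_table(20L)
  m <- tiny_backbone(tab, 0.2)
  fit <- train_model(m, tab, tab, train_config(epochs = 0L))
  expect_identical(fit$model$params, m$params)
  expect_equal(nrow(fit$history$steps), 0L)
  expect_equal(nrow(fit$history$epochs), 0L)
})

test_that("training history is reproducible under a fixed base seed", {
  tab <- bool_table(30L)
  cfg <- train_config(epochs = 2L, batch_size = 10L, base_seed = 9L)
  f1 <- train_model(tiny_backbone(tab, 0.3, 9L), tab, tab, cfg)
  f2 <- train_model(tiny_backbone(tab, 0.3, 9L), tab, tab, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("losses stay finite across fuzzed training batches", {
  set.seed(40)
  tab <- bool_table(24L, n_bool = 8L, n_classes = 4L)
  m <- tiny_backbone(tab, 0.4)
  opt <- negdrop:::adam_init(m$params)
  cfg <- train_config(alpha = 2, dropout_rate = 0.4)
  for (i in 1:100) {
    x <- matrix(rbinom(10 * 8, 1L, runif(1, 0.05, 0.95)), 10, 8)
    y <- sample.int(4L, 10, replace = TRUE)
    res <- negdrop:::train_step(m, x, y, cfg, step_seed = i, opt_state = opt)
    m <- res$model; opt <- res$opt_state
    expect_true(all(is.finite(unlist(res$breakdown))))
  }
})

test_that("mean epoch loss decreases on a separable two-blob toy", {
  set.seed(41)
  n <- 120L
  sch <- feature_schema(c("f1", "f2"), c("continuous", "continuous"),
                       c("k1", "k2"),
                       continuous_ranges = list(f1 = c(-10, 10),
                                                f2 = c(-10, 10)))
  y <- rep(1:2, each = n / 2)
  vals <- cbind(rnorm(n, ifelse(y == 1, -2, 2), 1),
                rnorm(n, ifelse(y == 1, 2, -2), 1))
  vals <- pmin(pmax(vals, -10), 10)
  tab <- clinical_table(vals, sch$class_labels[y], sch)
  cfg <- train_config(alpha = 1, dropout_rate = 0.1, batch_size = 30L,
                      epochs = 20L, base_seed = 3L)
  fit <- train_model(tiny_backbone(tab, 0.1, 3L), tab, NULL, cfg)
  per_epoch <- tapply(fit$history$steps$total, fit$history$steps$epoch, mean)
  # robust monotone trend: late epochs clearly below early ones
  expect_lt(mean(per_epoch[16:20]), mean(per_epoch[1:5]))
  expect_lt(per_epoch[20], per_epoch[1])
})

test_that("run_trials: degenerate and aggregate behaviour", {
  tab <- bool_table(60L, n_bool = 5L, n_classes = 2L, seed = 8L)
  sp <- stratified_split(tab, 0.7, 1L)
  cfg1 <- train_config(epochs = 2L, n_trials = 1L, batch_size = 16L)
  r1 <- run_trials(tab[sp$train_indices], tab[sp$test_indices], cfg1,
                   backbone_config(5L, 2L, hidden_size = 8L, depth = 2L))
  expect_equal(unname(r1$summary["accuracy_sd"]), 0)
  expect_equal(unname(r1$summary["accuracy_mean"]), r1$trials$accuracy[1])
  cfg3 <- train_config(epochs = 2L, n_trials = 3L, batch_size = 16L)
  r3 <- run_trials(tab[sp$train_indices], tab[sp$test_indices], cfg3,
                   backbone_config(5L, 2L, hidden_size = 8L, depth = 2L))
  expect_equal(nrow(r3$trials), 3L)
  expect_equal(unname(r3$summary["accuracy_mean"]), mean(r3$trials$accuracy))
})

test_that("ablation harness produces one summary row per grid point", {
  tab <- bool_table(40L, n_bool = 4L, n_classes = 2L, seed = 10L)
  sp <- stratified_split(tab, 0.7, 1L)
  cfg <- train_config(epochs = 1L, n_trials = 1L, batch_size = 16L)
  bb <- backbone_config(4L, 2L, hidden_size = 6L, depth = 1L)
  abl <- run_ablation("dropout_rate", tab[sp$train_indices],
                      tab[sp$test_indices], cfg, bb, values = c(0.1, 0.5))
  expect_equal(nrow(abl), 2L)
  expect_equal(abl$value, c("0.1", "0.5"))
  abl2 <- run_ablation("negative_strategy", tab[sp$train_indices],
                       tab[sp$test_indices], cfg, bb,
                       values = c("max_minus", "in_batch"))
  expect_equal(nrow(abl2), 2L)
  expect_error(run_ablation("nope", tab, tab, cfg, bb), "unknown ablation axis")
})

test_that("training refuses incomplete tables and empty training sets", {
  sch <- toy_schema(n_bool = 2L, n_cont = 0L)
  vals <- matrix(c(1, NA, 0, 1), 2, 2)
  tab <- clinical_table(vals, c("k1", "k2"), sch)
  m <- build_backbone(backbone_config(2L, 2L, hidden_size = 4L, depth = 1L))
  expect_error(train_model(m, tab, NULL, train_config(epochs = 1L)),
               "impute")
  empty <- clinical_table(matrix(numeric(0), 0, 2), character(0), sch)
  expect_error(train_model(m, empty, NULL, train_config(epochs = 1L)),
               "empty")
})
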