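#' Training configuration
#'
#' Hyperparameters for the negative-regularized dropout training loop.
#' Defaults: Adam at learning rate 1e-3, batch size 64, 30 epochs,
#' `alpha = 2`, dropout rate 0.3, max-minus negatives with the MSE
#' negative loss, 5 trials.
#'
#' @param alpha Non-negative weight of the consistency-minus-negative
#'   regularizer (ablation grid: 0.001, 0.01, 0.1, 1, 2, 4).
#' @param dropout_rate Dropout probability (ablation grid: 0.1-0.5).
#' @param batch_size Mini-batch size.
#' @param epochs Number of passes over the training data.
#' @param learning_rate Optimizer step size.
#' @param optimizer `"adam"` or `"sgd"`.
#' @param n_trials Number of seeded trials for [run_trials()].
#' @param base_seed Root seed; every stochastic stage derives its own
#'   stream from it.
#' @param negative_strategy `"max_minus"`, `"in_batch"` or
#'   `"random_generation"`.
#' @param negative_loss `"mse"` (default) or `"kl"` separation loss.
#' @param use_kl Keep the consistency term (`FALSE` only for degenerate
#'   baselines).
#' @param use_negative Keep the negative term; `FALSE` gives the plain
#'   dropout-consistency (R-Drop) objective.
#' @param shuffle Shuffle training rows each epoch.
#' @return A `train_config`.
#' @export
train_config <- function(alpha = 2, dropout_rate = 0.3, batch_size = 64L,
                         epochs = 30L, learning_rate = 1e-3,
                         optimizer = c("adam", "sgd"), n_trials = 5L,
                         base_seed = 1L,
                         negative_strategy = c("max_minus", "in_batch",
                                               "random_generation"),
                         negative_loss = c("mse", "kl"),
                         use_kl = TRUE, use_negative = TRUE, shuffle = TRUE) {
  optimizer <- match.arg(optimizer)
  negative_strategy <- match.arg(negative_strategy)
  negative_loss <- match.arg(negative_loss)
  if (alpha < 0) stop_negdrop("alpha must be non-negative")
  if (!is_count(n_trials) || n_trials < 1) stop_negdrop("n_trials must be >= 1")
  if (!is_count(epochs)) stop_negdrop("epochs must be a non-negative integer")
  if (!is_count(batch_size) || batch_size < 1) stop_negdrop("batch_size must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1) stop_negdrop("dropout_rate must lie in [0, 1)")
  structure(list(alpha = alpha, dropout_rate = dropout_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, optimizer = optimizer,
                 n_trials = as.integer(n_trials),
                 base_seed = as.integer(base_seed),
                 negative_strategy = negative_strategy,
                 negative_loss = negative_loss,
                 use_kl = isTRUE(use_kl), use_negative = isTRUE(use_negative),
                 shuffle = isTRUE(shuffle)),
            class = "train_config")
}

# One optimization step: three dropout forward passes (two on the batch,
# one on its negatives), combined-loss gradients through all passes, one
# optimizer update. `step_seed` fans out into the per-pass mask streams and
# the negative-sampling stream so that disabling one pass never perturbs
# the others (this is what makes the reduction properties exact).
train_step <- function(model, x, y, config, step_seed, opt_state,
                       schema = NULL, data = NULL) {
  n <- nrow(x)
  masks1 <- with_rng_seed(derive_seed(step_seed, "pass1"),
                          draw_dropout_masks(model, n))
  masks2 <- with_rng_seed(derive_seed(step_seed, "pass2"),
                          draw_dropout_masks(model, n))
  f1 <- backbone_forward(model, x, masks1)
  f2 <- backbone_forward(model, x, masks2)
  fng <- NULL
  if (config$use_negative) {
    xng <- make_negatives(config$negative_strategy, x, y,
                          derive_seed(step_seed, "negatives"),
                          schema = schema, data = data)
    # random-generation negatives are drawn in raw feature units; put them
    # on the model's (standardized) scale like the anchor batch
    if (config$negative_strategy == "random_generation") {
      xng <- scale_apply(model, xng)
    }
    masksng <- with_rng_seed(derive_seed(step_seed, "passng"),
                             draw_dropout_masks(model, n))
    fng <- backbone_forward(model, xng, masksng)
  }
  lg <- loss_grads(f1$probs, f2$probs, if (is.null(fng)) NULL else fng$probs,
                   y, config$alpha, config$negative_loss,
                   use_kl = config$use_kl, use_negative = config$use_negative)
  if (!is.finite(lg$breakdown$total)) {
    stop_negdrop("non-finite loss at training step; P1 range [",
                 paste(signif(range(f1$probs), 3), collapse = ", "),
                 "], P2 range [",
                 paste(signif(range(f2$probs), 3), collapse = ", "), "]")
  }
  grads <- add_grads(backbone_backward(model, f1$cache, lg$dz1),
                     backbone_backward(model, f2$cache, lg$dz2))
  if (config$use_negative && config$alpha > 0) {
    grads <- add_grads(grads, backbone_backward(model, fng$cache, lg$dzng))
  }
  if (config$optimizer == "adam") {
    upd <- adam_step(model$params, grads, opt_state, lr = config$learning_rate)
    model$params <- upd$params
    opt_state <- upd$state
  } else {
    model$params <- sgd_step(model$params, grads, config$learning_rate)
  }
  list(model = model, opt_state = opt_state, breakdown = lg$breakdown)
}

add_grads <- function(a, b) {
  for (nm in names(b)) a[[nm]] <- (a[[nm]] %||% 0) + b[[nm]]
  a
}

#' Train a backbone with negative-regularized dropout
#'
#' Epoch loop over shuffled mini-batches of the (already imputed) training
#' table, with per-epoch evaluation on the test table. Continuous features
#' are standardized using training-set statistics; the scaling is stored on
#' the returned model and applied automatically at prediction time, so
#' boolean and continuous features are commensurate when the max-minus
#' operator recombines them. Fully reproducible given
#' `config$base_seed`.
#'
#' @param model A [build_backbone()] model.
#' @param train_table Complete (imputed) [clinical_table()].
#' @param test_table Optional complete `clinical_table` evaluated after
#'   every epoch.
#' @param config A [train_config()].
#' @return A `negdrop_fit`: list with the trained `model`, `history`
#'   (`$steps`: per-step loss breakdown; `$epochs`: per-epoch test accuracy
#'   and macro-F1), and `config`.
#' @export
train_model <- function(model, train_table, test_table = NULL,
                        config = train_config()) {
  if (nrow(train_table$values) == 0L) stop_negdrop("training set is empty")
  if (any(train_table$missing_mask)) {
    stop_negdrop("training table contains missing cells; impute first")
  }
  if (!is.null(test_table) && any(test_table$missing_mask)) {
    stop_negdrop("test table contains missing cells; impute first")
  }
  sch <- train_table$schema
  ci <- continuous_idx(sch)
  if (length(ci) && is.null(model$scaling)) {
    ctr <- colMeans(train_table$values[, ci, drop = FALSE])
    scl <- apply(train_table$values[, ci, drop = FALSE], 2L, stats::sd)
    scl[!is.finite(scl) | scl == 0] <- 1
    model$scaling <- list(cols = ci, center = ctr, scale = scl)
  }
  xtr <- scale_apply(model, train_table$values)
  ytr <- class_index(train_table)
  n <- nrow(xtr)
  opt_state <- adam_init(model$params)
  steps <- list()
  epochs <- list()
  for (e in seq_len(config$epochs)) {
    ord <- if (config$shuffle) {
      with_rng_seed(derive_seed(config$base_seed, "shuffle", e), sample.int(n))
    } else seq_len(n)
    starts <- seq(1L, n, by = config$batch_size)
    for (t in seq_along(starts)) {
      idx <- ord[starts[t]:min(starts[t] + config$batch_size - 1L, n)]
      step_seed <- derive_seed(config$base_seed, "step", e, t)
      res <- train_step(model, xtr[idx, , drop = FALSE], ytr[idx], config,
                        step_seed, opt_state, schema = sch,
                        data = train_table$values)
      model <- res$model
      opt_state <- res$opt_state
      bd <- res$breakdown
      steps[[length(steps) + 1L]] <- data.frame(
        epoch = e, step = t, l_ce = bd$l_ce, l_kl = bd$l_kl,
        l_ng = bd$l_ng, total = bd$total)
    }
    if (!is.null(test_table)) {
      ev <- evaluate_model(model, test_table)
      epochs[[length(epochs) + 1L]] <- data.frame(
        epoch = e, accuracy = ev$accuracy, f1_macro = ev$f1_macro)
    }
  }
  structure(list(model = model,
                 history = list(
                   steps = if (length(steps)) do.call(rbind, steps)
                           else data.frame(epoch = integer(), step = integer(),
                                           l_ce = numeric(), l_kl = numeric(),
                                           l_ng = numeric(), total = numeric()),
                   epochs = if (length(epochs)) do.call(rbind, epochs)
                            else data.frame(epoch = integer(),
                                            accuracy = numeric(),
                                            f1_macro = numeric())),
                 config = config),
            class = "negdrop_fit")
}

#' @export
print.negdrop_fit <- function(x, ...) {
  cat("<negdrop_fit> ", x$config$epochs, " epochs", sep = "")
  if (nrow(x$history$epochs)) {
    last <- x$history$epochs[nrow(x$history$epochs), ]
    cat(sprintf("; final test accuracy %.4f, macro-F1 %.4f",
                last$accuracy, last$f1_macro))
  }
  cat("\n")
  invisible(x)
}

#' Multi-trial evaluation
#'
#' Runs the full training procedure `config$n_trials` times; trials differ
#' only by seed (`base_seed + trial - 1`, also used for parameter
#' initialization). Reports the mean and standard deviation of the
#' final-epoch test accuracy and macro-F1, the usual
#' mean-plus-minus-one-standard-deviation convention for seeded trials.
#'
#' @param train_table,test_table Complete [clinical_table()]s.
#' @param config A [train_config()].
#' @param backbone A [backbone_config()]; defaults to the standard MLP for
#'   the table's dimensions, with the config's dropout rate.
#' @return A `trial_summary`: list with `summary` (named means/sds) and
#'   `trials` (per-trial data frame).
#' @export
run_trials <- function(train_table, test_table, config = train_config(),
                       backbone = NULL) {
  sch <- train_table$schema
  if (is.null(backbone)) {
    backbone <- backbone_config(n_features(sch), n_classes_of(sch),
                                dropout_rate = config$dropout_rate)
  }
  backbone$dropout_rate <- config$dropout_rate
  rows <- lapply(seq_len(config$n_trials), function(k) {
    tc <- config
    tc$base_seed <- config$base_seed + k - 1L
    model <- build_backbone(backbone, seed = tc$base_seed)
    fit <- train_model(model, train_table, test_table, tc)
    last <- fit$history$epochs[nrow(fit$history$epochs), ]
    data.frame(trial = k, seed = tc$base_seed,
               accuracy = last$accuracy, f1_macro = last$f1_macro)
  })
  trials <- do.call(rbind, rows)
  sdz <- function(v) if (length(v) > 1L) stats::sd(v) else 0
  structure(list(
    summary = c(accuracy_mean = mean(trials$accuracy),
                accuracy_sd = sdz(trials$accuracy),
                f1_mean = mean(trials$f1_macro),
                f1_sd = sdz(trials$f1_macro)),
    trials = trials),
    class = "trial_summary")
}

#' @export
print.trial_summary <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<trial_summary> %d trials: accuracy %.4f +/- %.4f, macro-F1 %.4f +/- %.4f\n",
              nrow(x$trials), s["accuracy_mean"], s["accuracy_sd"],
              s["f1_mean"], s["f1_sd"]))
  invisible(x)
}

ablation_grids <- list(
  imputation = c("mode", "random", "bayesian", "nan_replace"),
  negative_strategy = c("random_generation", "in_batch", "max_minus"),
  dropout_rate = c(0.1, 0.2, 0.3, 0.4, 0.5),
  negative_loss = c("mse", "kl"),
  alpha = c(0.001, 0.01, 0.1, 1, 2, 4))

#' Ablation harness
#'
#' Sweeps one configuration axis, running [run_trials()] at each grid point
#' with everything else held fixed. For the `imputation` axis the supplied
#' tables may contain missing cells and are re-imputed per strategy; for
#' all other axes they are imputed once with mode imputation (a no-op on
#' complete tables).
#'
#' @param axis One of `"imputation"`, `"negative_strategy"`,
#'   `"dropout_rate"`, `"negative_loss"`, `"alpha"`.
#' @param train_table,test_table [clinical_table()]s (may contain missing
#'   cells; see above).
#' @param config Base [train_config()].
#' @param backbone Optional [backbone_config()].
#' @param values Grid points; defaults to the standard grid for the axis.
#' @return Data frame with one row per grid point (`value`,
#'   `accuracy_mean`, `accuracy_sd`, `f1_mean`, `f1_sd`).
#' @export
run_ablation <- function(axis, train_table, test_table,
                         config = train_config(), backbone = NULL,
                         values = NULL) {
  if (!axis %in% names(ablation_grids)) {
    stop_negdrop("unknown ablation axis '", axis, "'; expected one of ",
                 paste(names(ablation_grids), collapse = ", "))
  }
  if (is.null(values)) values <- ablation_grids[[axis]]
  rows <- lapply(values, function(v) {
    tc <- config
    if (axis == "imputation") {
      pol <- imputation_policy(v, seed = derive_seed(config$base_seed, "impute"))
      trt <- impute_table(train_table, pol)
      tet <- impute_table(test_table, pol)
    } else {
      pol <- imputation_policy("mode")
      trt <- if (any(train_table$missing_mask)) impute_table(train_table, pol) else train_table
      tet <- if (any(test_table$missing_mask)) impute_table(test_table, pol) else test_table
      if (axis == "dropout_rate") tc$dropout_rate <- v
      else tc[[axis]] <- v
    }
    res <- run_trials(trt, tet, tc, backbone)
    data.frame(axis = axis, value = as.character(v),
               accuracy_mean = res$summary[["accuracy_mean"]],
               accuracy_sd = res$summary[["accuracy_sd"]],
               f1_mean = res$summary[["f1_mean"]],
               f1_sd = res$summary[["f1_sd"]])
  })
  do.call(rbind, rows)
}
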