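# Shared fixtures and independent oracles for the test suite.

# ---- small schemas and tables --------------------------------------------

toy_schema <- function(n_bool = 3L, n_cont = 1L, n_classes = 2L) {
  bn <- sprintf("b%d", seq_len(n_bool))
  cn <- if (n_cont > 0) sprintf("c%d", seq_len(n_cont)) else character(0)
  feature_schema(
    c(bn, cn),
    c(rep("boolean", n_bool), rep("continuous", n_cont)),
    class_labels = sprintf("k%d", seq_len(n_classes)),
    continuous_ranges = stats::setNames(rep(list(c(0, 10)), n_cont), cn))
}

# random complete table over a toy schema
toy_table <- function(n = 12L, schema = toy_schema(), seed = 1L) {
  set.seed(seed)
  p <- length(schema$feature_names)
  bi <- which(schema$feature_types == "boolean")
  vals <- matrix(0, n, p)
  vals[, bi] <- rbinom(n * length(bi), 1L, 0.5)
  for (j in setdiff(seq_len(p), bi)) vals[, j] <- runif(n, 0, 10)
  labs <- schema$class_labels[sample.int(length(schema$class_labels), n,
                                         replace = TRUE)]
  # ensure every class appears
  labs[seq_along(schema$class_labels)] <- schema$class_labels
  clinical_table(vals, labs, schema)
}

# boolean-only table for exact-trajectory tests (no feature scaling)
bool_table <- function(n = 40L, n_bool = 6L, n_classes = 3L, seed = 2L) {
  sch <- toy_schema(n_bool = n_bool, n_cont = 0L, n_classes = n_classes)
  set.seed(seed)
  vals <- matrix(rbinom(n * n_bool, 1L, 0.5), n, n_bool)
  labs <- sch$class_labels[c(seq_len(n_classes),
                             sample.int(n_classes, n - n_classes,
                                        replace = TRUE))]
  clinical_table(vals, labs, sch)
}

# random probability triplet (batch x classes rows on the simplex)
random_triplet <- function(n = 8L, k = 5L) {
  rmat <- function() {
    m <- matrix(rexp(n * k), n, k)
    m / rowSums(m)
  }
  list(p1 = rmat(), p2 = rmat(), png = rmat(),
       y = sample.int(k, n, replace = TRUE))
}

# ---- loop oracles (independent term-by-term summation) -------------------

oracle_bikl <- function(p1, p2, eps = 1e-12) {
  tot <- 0
  for (i in seq_len(nrow(p1))) {
    a <- 0; b <- 0
    for (j in seq_len(ncol(p1))) {
      a <- a + p1[i, j] * (log(max(p1[i, j], eps)) - log(max(p2[i, j], eps)))
      b <- b + p2[i, j] * (log(max(p2[i, j], eps)) - log(max(p1[i, j], eps)))
    }
    tot <- tot + 0.5 * (a + b)
  }
  tot / nrow(p1)
}

oracle_dual_ce <- function(p1, p2, y, eps = 1e-12) {
  tot <- 0
  for (i in seq_len(nrow(p1))) {
    tot <- tot - log(max(p1[i, y[i]], eps)) - log(max(p2[i, y[i]], eps))
  }
  tot / nrow(p1)
}

oracle_neg_mse <- function(p1, p2, png) {
  tot <- 0
  for (i in seq_len(nrow(p1))) {
    for (j in seq_len(ncol(p1))) {
      m <- (p1[i, j] + p2[i, j]) / 2
      tot <- tot + (m - png[i, j])^2
    }
  }
  tot / (nrow(p1) * ncol(p1))
}

oracle_max_minus <- function(x) {
  out <- x
  for (j in seq_len(ncol(x))) {
    mj <- max(x[, j])
    for (i in seq_len(nrow(x))) out[i, j] <- mj - x[i, j]
  }
  out
}

oracle_accuracy <- function(cm) {
  correct <- 0
  for (c in seq_len(nrow(cm))) correct <- correct + cm[c, c]
  correct / sum(cm)
}

oracle_macro_f1 <- function(cm) {
  k <- nrow(cm)
  f1s <- numeric(k)
  for (c in seq_len(k)) {
    tp <- cm[c, c]
    fp <- sum(cm[, c]) - tp
    fn <- sum(cm[c, ]) - tp
    f1s[c] <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }
  mean(f1s)
}

# ---- numeric gradient -----------------------------------------------------

# total loss for a fixed parameter vector and fixed dropout masks; used by
# the central-finite-difference gradient check
loss_at_params <- function(model, params, x, y, config, masks1, masks2,
                           masksng, xng) {
  model$params <- params
  p1 <- negdrop:::backbone_forward(model, x, masks1)$probs
  p2 <- negdrop:::backbone_forward(model, x, masks2)$probs
  png <- if (config$use_negative) {
    negdrop:::backbone_forward(model, xng, masksng)$probs
  } else NULL
  lg <- negdrop:::loss_grads(p1, p2, png, y, config$alpha,
                             config$negative_loss,
                             use_kl = config$use_kl,
                             use_negative = config$use_negative)
  lg$breakdown$total
}

# move parameters off measure-zero ReLU kinks (zero-initialized biases put
# fully-dropped units exactly at a = 0, where one-sided derivatives and
# central differences legitimately disagree)
perturb_params <- function(model, sd = 0.05, seed = 123L) {
  set.seed(seed)
  model$params <- lapply(model$params, function(p) p + stats::rnorm(length(p), sd = sd))
  model
}

numeric_grad <- function(f, params, h = 1e-5) {
  g <- params
  for (nm in names(params)) {
    gp <- params[[nm]]
    for (idx in seq_along(gp)) {
      up <- params; up[[nm]][idx] <- up[[nm]][idx] + h
      dn <- params; dn[[nm]][idx] <- dn[[nm]][idx] - h
      gp[idx] <- (f(up) - f(dn)) / (2 * h)
    }
    g[[nm]] <- gp
  }
  g
}

# ---- independent reference trainers --------------------------------------
# These re-implement the degenerate objectives (dual-pass cross-entropy,
# dropout-consistency/R-Drop, plain CE) as stand-alone loops with their own
# gradient composition and their own Adam, sharing only the forward pass
# and the seed/mask streams with the package.

ref_adam_init <- function(params) {
  list(t = 0, m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

ref_adam_update <- function(params, grads, st, lr) {
  st$t <- st$t + 1
  for (nm in names(params)) {
    st$m[[nm]] <- 0.9 * st$m[[nm]] + 0.1 * grads[[nm]]
    st$v[[nm]] <- 0.999 * st$v[[nm]] + 0.001 * grads[[nm]]^2
    mh <- st$m[[nm]] / (1 - 0.9^st$t)
    vh <- st$v[[nm]] / (1 - 0.999^st$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + 1e-8)
  }
  list(params = params, st = st)
}

# objective: "dual_ce"  L = mean(-log P1[y] - log P2[y])
#            "rdrop"    L = dual CE + alpha * bidirectional KL
#            "plain_ce" L = -2 * mean log P[y]  (single pass, no dropout)
reference_train <- function(model, table, config, objective) {
  x <- table$values
  y <- class_index(table)
  n <- nrow(x)
  st <- ref_adam_init(model$params)
  for (e in seq_len(config$epochs)) {
    ord <- negdrop:::with_rng_seed(
      negdrop:::derive_seed(config$base_seed, "shuffle", e), sample.int(n))
    starts <- seq(1L, n, by = config$batch_size)
    for (t in seq_along(starts)) {
      idx <- ord[starts[t]:min(starts[t] + config$batch_size - 1L, n)]
      xb <- x[idx, , drop = FALSE]
      yb <- y[idx]
      nb <- length(idx)
      ss <- negdrop:::derive_seed(config$base_seed, "step", e, t)
      m1 <- negdrop:::with_rng_seed(negdrop:::derive_seed(ss, "pass1"),
                                    negdrop:::draw_dropout_masks(model, nb))
      m2 <- negdrop:::with_rng_seed(negdrop:::derive_seed(ss, "pass2"),
                                    negdrop:::draw_dropout_masks(model, nb))
      f1 <- negdrop:::backbone_forward(model, xb, m1)
      f2 <- negdrop:::backbone_forward(model, xb, m2)
      yh <- matrix(0, nb, ncol(f1$probs))
      yh[cbind(seq_len(nb), yb)] <- 1
      if (objective == "plain_ce") {
        dz <- 2 * (f1$probs - yh) / nb
        grads <- negdrop:::backbone_backward(model, f1$cache, dz)
      } else {
        dz1 <- (f1$probs - yh) / nb
        dz2 <- (f2$probs - yh) / nb
        if (objective == "rdrop" && config$alpha > 0) {
          p1 <- f1$probs; p2 <- f2$probs
          s <- log(pmax(p1, 1e-12)) - log(pmax(p2, 1e-12))
          dz1 <- dz1 + config$alpha * 0.5 / nb *
            (p1 * (s - rowSums(p1 * s)) + (p1 - p2))
          dz2 <- dz2 + config$alpha * 0.5 / nb *
            (p2 * (-s - rowSums(p2 * -s)) + (p2 - p1))
        }
        grads <- negdrop:::add_grads(
          negdrop:::backbone_backward(model, f1$cache, dz1),
          negdrop:::backbone_backward(model, f2$cache, dz2))
      }
      upd <- ref_adam_update(model$params, grads, st, config$learning_rate)
      model$params <- upd$params
      st <- upd$st
    }
  }
  model
}

max_param_diff <- function(p1, p2) {
  max(vapply(names(p1), function(nm) max(abs(p1[[nm]] - p2[[nm]])),
             numeric(1)))
}
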