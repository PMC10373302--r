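#' Backbone configuration
#'
#' Describes the classifier-with-dropout that produces the per-pass output
#' distributions. The regularization scheme is backbone-agnostic: any model
#' that maps a feature matrix to softmax probabilities under a stochastic
#' dropout mask fits the contract. Two backbones are provided: a
#' multi-layer perceptron (default: depth 5, hidden size 256, the standard
#' small-tabular configuration) and a small transformer encoder that treats
#' each feature as a token (embedding size 96).
#'
#' @param n_features Number of input features.
#' @param n_classes Number of output classes.
#' @param kind `"mlp"` or `"transformer"`.
#' @param hidden_size Hidden width of each MLP layer.
#' @param depth Number of hidden MLP layers.
#' @param embedding_size Token embedding dimension (transformer).
#' @param n_heads Attention heads (transformer); must divide
#'   `embedding_size`.
#' @param n_blocks Encoder blocks (transformer).
#' @param ffn_size Feed-forward width inside each block; default
#'   `2 * embedding_size`.
#' @param dropout_rate Dropout probability in [0, 1); applied after every
#'   hidden activation (MLP) or after attention/FFN sublayers
#'   (transformer).
#' @return A `backbone_config`.
#' @export
backbone_config <- function(n_features, n_classes, kind = c("mlp", "transformer"),
                            hidden_size = 256L, depth = 5L,
                            embedding_size = 96L, n_heads = 4L, n_blocks = 2L,
                            ffn_size = NULL, dropout_rate = 0.3) {
  kind <- match.arg(kind)
  if (!is_count(n_features) || n_features < 1) stop_negdrop("n_features must be positive")
  if (!is_count(n_classes) || n_classes < 2) stop_negdrop("n_classes must be >= 2")
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop_negdrop("dropout_rate must lie in [0, 1)")
  }
  if (is.null(ffn_size)) ffn_size <- 2L * embedding_size
  for (v in c(hidden_size, depth, embedding_size, n_heads, n_blocks, ffn_size)) {
    if (!is_count(v) || v < 1) stop_negdrop("backbone sizes must be positive integers")
  }
  if (kind == "transformer" && embedding_size %% n_heads != 0) {
    stop_negdrop("embedding_size must be divisible by n_heads")
  }
  structure(list(kind = kind, n_features = as.integer(n_features),
                 n_classes = as.integer(n_classes),
                 hidden_size = as.integer(hidden_size), depth = as.integer(depth),
                 embedding_size = as.integer(embedding_size),
                 n_heads = as.integer(n_heads), n_blocks = as.integer(n_blocks),
                 ffn_size = as.integer(ffn_size),
                 dropout_rate = dropout_rate),
            class = "backbone_config")
}

#' Build a backbone model
#'
#' Initializes parameters (He initialization for ReLU layers, Xavier for
#' linear outputs) under a fixed seed.
#'
#' @param config A [backbone_config()].
#' @param seed Integer seed for parameter initialization.
#' @return A `negdrop_backbone`: list with `config` and `params` (named
#'   list of weight matrices / bias vectors).
#' @export
build_backbone <- function(config, seed = 1L) {
  params <- with_rng_seed(derive_seed(seed, "init"), {
    if (config$kind == "mlp") init_mlp(config) else init_transformer(config)
  })
  structure(list(config = config, params = params, scaling = NULL),
            class = "negdrop_backbone")
}

#' @export
print.negdrop_backbone <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat("<negdrop_backbone> ", x$config$kind, ", ", x$config$n_features,
      " features -> ", x$config$n_classes, " classes, ", np,
      " parameters, dropout ", x$config$dropout_rate, "\n", sep = "")
  invisible(x)
}

init_mlp <- function(cfg) {
  p <- list()
  din <- cfg$n_features
  for (l in seq_len(cfg$depth)) {
    p[[paste0("W", l)]] <- matrix(stats::rnorm(din * cfg$hidden_size,
                                               sd = sqrt(2 / din)),
                                  din, cfg$hidden_size)
    p[[paste0("b", l)]] <- numeric(cfg$hidden_size)
    din <- cfg$hidden_size
  }
  p$Wout <- matrix(stats::rnorm(din * cfg$n_classes,
                                sd = sqrt(1 / din)), din, cfg$n_classes)
  p$bout <- numeric(cfg$n_classes)
  p
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Draw inverted-dropout masks (scaled by 1/(1-rate)) for a training pass
# from the current RNG state. Returns NULL when the rate is 0.
draw_dropout_masks <- function(model, n) {
  cfg <- model$config
  rate <- cfg$dropout_rate
  if (rate == 0) return(NULL)
  if (cfg$kind == "mlp") {
    lapply(seq_len(cfg$depth), function(l) {
      matrix(stats::rbinom(n * cfg$hidden_size, 1L, 1 - rate),
             n, cfg$hidden_size) / (1 - rate)
    })
  } else {
    nt <- n * cfg$n_features
    lapply(seq_len(cfg$n_blocks), function(b) {
      list(attn = matrix(stats::rbinom(nt * cfg$embedding_size, 1L, 1 - rate),
                         nt, cfg$embedding_size) / (1 - rate),
           ffn = matrix(stats::rbinom(nt * cfg$embedding_size, 1L, 1 - rate),
                        nt, cfg$embedding_size) / (1 - rate))
    })
  }
}

# Forward pass. `masks` NULL means inference (dropout off). Returns probs,
# logits and the cache needed by the backward pass.
backbone_forward <- function(model, x, masks = NULL) {
  if (ncol(x) != model$config$n_features) {
    stop_negdrop("batch has ", ncol(x), " features but model expects ",
                 model$config$n_features)
  }
  if (model$config$kind == "mlp") mlp_forward(model, x, masks)
  else tfm_forward(model, x, masks)
}

mlp_forward <- function(model, x, masks = NULL) {
  cfg <- model$config; pr <- model$params
  h <- x
  hs <- list(h); as <- list()
  for (l in seq_len(cfg$depth)) {
    a <- sweep(h %*% pr[[paste0("W", l)]], 2L, pr[[paste0("b", l)]], "+")
    r <- pmax(a, 0)
    if (!is.null(masks)) r <- r * masks[[l]]
    as[[l]] <- a
    h <- r
    hs[[l + 1L]] <- h
  }
  z <- sweep(h %*% pr$Wout, 2L, pr$bout, "+")
  list(probs = softmax_rows(z), logits = z,
       cache = list(hs = hs, as = as, masks = masks))
}

mlp_backward <- function(model, cache, dz) {
  cfg <- model$config; pr <- model$params
  g <- list()
  hlast <- cache$hs[[cfg$depth + 1L]]
  g$Wout <- crossprod(hlast, dz)
  g$bout <- colSums(dz)
  dh <- tcrossprod(dz, pr$Wout)
  for (l in rev(seq_len(cfg$depth))) {
    if (!is.null(cache$masks)) dh <- dh * cache$masks[[l]]
    da <- dh * (cache$as[[l]] > 0)
    g[[paste0("W", l)]] <- crossprod(cache$hs[[l]], da)
    g[[paste0("b", l)]] <- colSums(da)
    if (l > 1L) dh <- tcrossprod(da, pr[[paste0("W", l)]])
  }
  g
}

backbone_backward <- function(model, cache, dz) {
  if (model$config$kind == "mlp") mlp_backward(model, cache, dz)
  else tfm_backward(model, cache, dz)
}

#' Forward pass with dropout
#'
#' Runs one stochastic forward pass: dropout masks are drawn from `seed`
#' (or from the current RNG state when `seed` is `NULL`), so replaying the
#' same seed yields bit-identical output while two passes under different
#' seeds differ -- the source of the two sub-model distributions.
#'
#' @param model A [build_backbone()] model.
#' @param x Numeric feature matrix (batch x features), complete.
#' @param seed Optional integer seed for the dropout masks.
#' @return Probability matrix (batch x classes); rows sum to 1.
#' @export
forward_with_dropout <- function(model, x, seed = NULL) {
  x <- scale_apply(model, as.matrix(x))
  masks <- with_rng_seed(seed, draw_dropout_masks(model, nrow(x)))
  backbone_forward(model, x, masks)$probs
}

#' Deterministic prediction (dropout disabled)
#'
#' Inference uses the full model: dropout off, no stochasticity. With
#' `dropout_rate = 0` this coincides with [forward_with_dropout()].
#'
#' @inheritParams forward_with_dropout
#' @return Probability matrix (batch x classes).
#' @export
predict_proba <- function(model, x) {
  x <- scale_apply(model, as.matrix(x))
  backbone_forward(model, x, NULL)$probs
}

#' Predicted class indices
#' @inheritParams forward_with_dropout
#' @return Integer vector of 1-based class indices (row-wise argmax).
#' @export
predict_classes <- function(model, x) {
  max.col(predict_proba(model, x), ties.method = "first")
}

# Continuous-feature standardization learned at training time; identity
# when the model carries no scaling.
scale_apply <- function(model, x) {
  s <- model$scaling
  if (is.null(s)) return(x)
  x[, s$cols] <- sweep(sweep(x[, s$cols, drop = FALSE], 2L, s$center, "-"),
                       2L, s$scale, "/")
  x
}

# ---- Adam optimizer (internal) -------------------------------------------

adam_init <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

sgd_step <- function(params, grads, lr) {
  for (nm in names(params)) params[[nm]] <- params[[nm]] - lr * grads[[nm]]
  params
}
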