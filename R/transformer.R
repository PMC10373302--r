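# Small transformer encoder over feature tokens.
#
# Each of the p input features is a token: token t of sample i is embedded
# as x[i,t] * Wval[t,] + Wemb[t,] (a per-feature value direction plus a
# learned positional/feature embedding). Encoder blocks are post-LayerNorm
# residual blocks (multi-head self-attention, then a ReLU feed-forward),
# with inverted dropout after each sublayer output. Token states are
# mean-pooled and a linear head produces class logits. All gradients are
# hand-derived and checked against central finite differences in the test
# suite.
#
# Internal layout: token states live in an (n * p) x d matrix whose row
# (i - 1) * p + t holds token t of sample i.

LN_EPS <- 1e-6

init_transformer <- function(cfg) {
  p <- list()
  d <- cfg$embedding_size; tks <- cfg$n_features; f <- cfg$ffn_size
  gauss <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
  p$Wval <- gauss(tks, d, 1 / sqrt(d))
  p$Wemb <- gauss(tks, d, 1 / sqrt(d))
  for (b in seq_len(cfg$n_blocks)) {
    pre <- paste0("blk", b, "_")
    for (nm in c("Wq", "Wk", "Wv", "Wo")) p[[paste0(pre, nm)]] <- gauss(d, d, 1 / sqrt(d))
    for (nm in c("bq", "bk", "bv", "bo")) p[[paste0(pre, nm)]] <- numeric(d)
    p[[paste0(pre, "ln1_g")]] <- rep(1, d)
    p[[paste0(pre, "ln1_b")]] <- numeric(d)
    p[[paste0(pre, "W1")]] <- gauss(d, f, sqrt(2 / d))
    p[[paste0(pre, "b1")]] <- numeric(f)
    p[[paste0(pre, "W2")]] <- gauss(f, d, 1 / sqrt(f))
    p[[paste0(pre, "b2")]] <- numeric(d)
    p[[paste0(pre, "ln2_g")]] <- rep(1, d)
    p[[paste0(pre, "ln2_b")]] <- numeric(d)
  }
  p$Whead <- gauss(d, cfg$n_classes, 1 / sqrt(d))
  p$bhead <- numeric(cfg$n_classes)
  p
}

layernorm_fwd <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowMeans(xc * xc)
  inv <- 1 / sqrt(va + LN_EPS)
  xhat <- xc * inv
  list(out = sweep(xhat, 2L, g, "*") + rep(b, each = nrow(x)),
       xhat = xhat, inv = inv)
}

layernorm_bwd <- function(dout, cache, g) {
  xhat <- cache$xhat
  dxhat <- sweep(dout, 2L, g, "*")
  dx <- cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = colSums(dout * xhat), db = colSums(dout))
}

lin_fwd <- function(x, W, b) sweep(x %*% W, 2L, b, "+")

tfm_forward <- function(model, x, masks = NULL) {
  cfg <- model$config; pr <- model$params
  n <- nrow(x); tks <- cfg$n_features; d <- cfg$embedding_size
  nh <- cfg$n_heads; dh <- d %/% nh
  rows_of <- function(i) ((i - 1L) * tks + 1L):(i * tks)
  xvec <- as.vector(t(x))                         # (i1 t1..tp, i2 t1..tp, ...)
  trep <- rep(seq_len(tks), n)
  H <- xvec * pr$Wval[trep, , drop = FALSE] + pr$Wemb[trep, , drop = FALSE]
  blocks <- vector("list", cfg$n_blocks)
  for (b in seq_len(cfg$n_blocks)) {
    pre <- paste0("blk", b, "_")
    Q <- lin_fwd(H, pr[[paste0(pre, "Wq")]], pr[[paste0(pre, "bq")]])
    K <- lin_fwd(H, pr[[paste0(pre, "Wk")]], pr[[paste0(pre, "bk")]])
    V <- lin_fwd(H, pr[[paste0(pre, "Wv")]], pr[[paste0(pre, "bv")]])
    O <- matrix(0, n * tks, d)
    att <- vector("list", n)
    scal <- 1 / sqrt(dh)
    for (i in seq_len(n)) {
      ri <- rows_of(i)
      att[[i]] <- vector("list", nh)
      for (h in seq_len(nh)) {
        ch <- ((h - 1L) * dh + 1L):(h * dh)
        S <- tcrossprod(Q[ri, ch, drop = FALSE], K[ri, ch, drop = FALSE]) * scal
        P <- softmax_rows(S)
        O[ri, ch] <- P %*% V[ri, ch, drop = FALSE]
        att[[i]][[h]] <- P
      }
    }
    AO <- lin_fwd(O, pr[[paste0(pre, "Wo")]], pr[[paste0(pre, "bo")]])
    if (!is.null(masks)) AO <- AO * masks[[b]]$attn
    R1 <- H + AO
    ln1 <- layernorm_fwd(R1, pr[[paste0(pre, "ln1_g")]], pr[[paste0(pre, "ln1_b")]])
    H1 <- ln1$out
    A1 <- lin_fwd(H1, pr[[paste0(pre, "W1")]], pr[[paste0(pre, "b1")]])
    F1 <- pmax(A1, 0)
    F2 <- lin_fwd(F1, pr[[paste0(pre, "W2")]], pr[[paste0(pre, "b2")]])
    if (!is.null(masks)) F2 <- F2 * masks[[b]]$ffn
    R2 <- H1 + F2
    ln2 <- layernorm_fwd(R2, pr[[paste0(pre, "ln2_g")]], pr[[paste0(pre, "ln2_b")]])
    blocks[[b]] <- list(Hin = H, Q = Q, K = K, V = V, O = O, att = att,
                        ln1 = ln1, H1 = H1, A1 = A1, F1 = F1)
    H <- ln2$out
    blocks[[b]]$ln2 <- ln2
  }
  pool <- matrix(0, n, d)
  for (i in seq_len(n)) pool[i, ] <- colMeans(H[rows_of(i), , drop = FALSE])
  z <- lin_fwd(pool, pr$Whead, pr$bhead)
  list(probs = softmax_rows(z), logits = z,
       cache = list(x = x, blocks = blocks, Hfinal = H, pool = pool,
                    masks = masks))
}

tfm_backward <- function(model, cache, dz) {
  cfg <- model$config; pr <- model$params
  n <- nrow(dz); tks <- cfg$n_features; d <- cfg$embedding_size
  nh <- cfg$n_heads; dh <- d %/% nh
  rows_of <- function(i) ((i - 1L) * tks + 1L):(i * tks)
  g <- list()
  g$Whead <- crossprod(cache$pool, dz)
  g$bhead <- colSums(dz)
  dpool <- tcrossprod(dz, pr$Whead)
  dH <- matrix(0, n * tks, d)
  for (i in seq_len(n)) {
    dH[rows_of(i), ] <- matrix(dpool[i, ] / tks, tks, d, byrow = TRUE)
  }
  for (b in rev(seq_len(cfg$n_blocks))) {
    pre <- paste0("blk", b, "_")
    blk <- cache$blocks[[b]]
    l2 <- layernorm_bwd(dH, blk$ln2, pr[[paste0(pre, "ln2_g")]])
    g[[paste0(pre, "ln2_g")]] <- l2$dg
    g[[paste0(pre, "ln2_b")]] <- l2$db
    dR2 <- l2$dx
    dF2 <- dR2
    if (!is.null(cache$masks)) dF2 <- dF2 * cache$masks[[b]]$ffn
    g[[paste0(pre, "W2")]] <- crossprod(blk$F1, dF2)
    g[[paste0(pre, "b2")]] <- colSums(dF2)
    dF1 <- tcrossprod(dF2, pr[[paste0(pre, "W2")]])
    dA1 <- dF1 * (blk$A1 > 0)
    g[[paste0(pre, "W1")]] <- crossprod(blk$H1, dA1)
    g[[paste0(pre, "b1")]] <- colSums(dA1)
    dH1 <- dR2 + tcrossprod(dA1, pr[[paste0(pre, "W1")]])
    l1 <- layernorm_bwd(dH1, blk$ln1, pr[[paste0(pre, "ln1_g")]])
    g[[paste0(pre, "ln1_g")]] <- l1$dg
    g[[paste0(pre, "ln1_b")]] <- l1$db
    dR1 <- l1$dx
    dAO <- dR1
    if (!is.null(cache$masks)) dAO <- dAO * cache$masks[[b]]$attn
    g[[paste0(pre, "Wo")]] <- crossprod(blk$O, dAO)
    g[[paste0(pre, "bo")]] <- colSums(dAO)
    dO <- tcrossprod(dAO, pr[[paste0(pre, "Wo")]])
    dQ <- matrix(0, n * tks, d)
    dK <- matrix(0, n * tks, d)
    dV <- matrix(0, n * tks, d)
    scal <- 1 / sqrt(dh)
    for (i in seq_len(n)) {
      ri <- rows_of(i)
      for (h in seq_len(nh)) {
        ch <- ((h - 1L) * dh + 1L):(h * dh)
        P <- blk$att[[i]][[h]]
        dOh <- dO[ri, ch, drop = FALSE]
        Vh <- blk$V[ri, ch, drop = FALSE]
        dP <- tcrossprod(dOh, Vh)
        dV[ri, ch] <- crossprod(P, dOh)
        dS <- P * (dP - rowSums(dP * P))
        dQ[ri, ch] <- dS %*% blk$K[ri, ch, drop = FALSE] * scal
        dK[ri, ch] <- crossprod(dS, blk$Q[ri, ch, drop = FALSE]) * scal
      }
    }
    Hin <- blk$Hin
    g[[paste0(pre, "Wq")]] <- crossprod(Hin, dQ)
    g[[paste0(pre, "bq")]] <- colSums(dQ)
    g[[paste0(pre, "Wk")]] <- crossprod(Hin, dK)
    g[[paste0(pre, "bk")]] <- colSums(dK)
    g[[paste0(pre, "Wv")]] <- crossprod(Hin, dV)
    g[[paste0(pre, "bv")]] <- colSums(dV)
    dH <- dR1 +
      tcrossprod(dQ, pr[[paste0(pre, "Wq")]]) +
      tcrossprod(dK, pr[[paste0(pre, "Wk")]]) +
      tcrossprod(dV, pr[[paste0(pre, "Wv")]])
  }
  trep <- rep(seq_len(tks), n)
  xvec <- as.vector(t(cache$x))
  g$Wval <- rowsum(dH * xvec, trep)
  g$Wemb <- rowsum(dH, trep)
  # rowsum orders groups by sorted unique value; trep groups are 1..tks
  g
}
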