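# Numerical floor applied inside every logarithm so that losses stay
# finite on degenerate (one-hot) probability rows.
PROB_EPS <- 1e-12

as_prob_matrix <- function(p, arg) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
  p <- as.matrix(p)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop_negdrop(arg, " must contain probabilities in [0, 1]")
  }
  if (any(abs(rowSums(p) - 1) > 1e-6)) {
    stop_negdrop(arg, " rows must sum to 1 (tolerance 1e-6)")
  }
  p
}

check_same_shape <- function(a, b, na, nb) {
  if (!identical(dim(a), dim(b))) {
    stop_negdrop(na, " and ", nb, " must have identical shapes")
  }
}

kl_rows <- function(p, q) {
  rowSums(p * (log(pmax(p, PROB_EPS)) - log(pmax(q, PROB_EPS))))
}

#' Bidirectional Kullback-Leibler consistency loss
#'
#' Per row, `0.5 * (KL(P1 || P2) + KL(P2 || P1))` in nats, averaged over
#' the batch. This is the consistency term that pulls the two dropout
#' sub-model distributions of the same input toward each other. Symmetric
#' in its arguments; zero iff the distributions coincide.
#'
#' @param p1,p2 Probability matrices (batch x classes); vectors are treated
#'   as single rows.
#' @return Non-negative scalar (nats).
#' @export
bidirectional_kl <- function(p1, p2) {
  p1 <- as_prob_matrix(p1, "p1"); p2 <- as_prob_matrix(p2, "p2")
  check_same_shape(p1, p2, "p1", "p2")
  mean(0.5 * (kl_rows(p1, p2) + kl_rows(p2, p1)))
}

#' Dual-pass cross-entropy loss
#'
#' Per row, `-log P1[y] - log P2[y]` (natural log), averaged over the
#' batch: the classification objective applied to both dropout forward
#' passes of the same input.
#'
#' @inheritParams bidirectional_kl
#' @param y Integer class indices (1-based), one per row.
#' @return Non-negative scalar (nats).
#' @export
dual_cross_entropy <- function(p1, p2, y) {
  p1 <- as_prob_matrix(p1, "p1"); p2 <- as_prob_matrix(p2, "p2")
  check_same_shape(p1, p2, "p1", "p2")
  y <- as.integer(y)
  if (length(y) != nrow(p1)) stop_negdrop("y must have one label per row")
  if (any(y < 1L | y > ncol(p1))) {
    stop_negdrop("label index out of range 1..", ncol(p1))
  }
  ix <- cbind(seq_len(nrow(p1)), y)
  mean(-log(pmax(p1[ix], PROB_EPS)) - log(pmax(p2[ix], PROB_EPS)))
}

#' Negative-distribution mean-squared-error regularizer
#'
#' The separation term to be maximized: the MSE between the mean positive
#' distribution `M = (P1 + P2) / 2` and the negative-pass distribution
#' `P_ng`, averaged over batch rows and classes. Because all rows lie in
#' the probability simplex the value is bounded in [0, 1], so subtracting
#' it from the objective can never drive the total loss to -Inf.
#'
#' @inheritParams bidirectional_kl
#' @param p_ng Probability matrix for the negative batch, same shape.
#' @return Scalar in [0, 1].
#' @export
negative_mse <- function(p1, p2, p_ng) {
  p1 <- as_prob_matrix(p1, "p1"); p2 <- as_prob_matrix(p2, "p2")
  p_ng <- as_prob_matrix(p_ng, "p_ng")
  check_same_shape(p1, p2, "p1", "p2")
  check_same_shape(p1, p_ng, "p1", "p_ng")
  m <- (p1 + p2) / 2
  mean((m - p_ng)^2)
}

#' Negative-distribution bidirectional-KL regularizer (ablation variant)
#'
#' Alternative separation term: the bidirectional KL divergence between the
#' mean positive distribution `(P1 + P2) / 2` and `P_ng`. Used only in the
#' ablation comparing negative-loss forms; the MSE form is the default.
#'
#' @inheritParams negative_mse
#' @return Non-negative scalar (nats).
#' @export
negative_kl <- function(p1, p2, p_ng) {
  p1 <- as_prob_matrix(p1, "p1"); p2 <- as_prob_matrix(p2, "p2")
  p_ng <- as_prob_matrix(p_ng, "p_ng")
  check_same_shape(p1, p2, "p1", "p2")
  check_same_shape(p1, p_ng, "p1", "p_ng")
  bidirectional_kl((p1 + p2) / 2, p_ng)
}

#' Combined training objective
#'
#' `L = L_CE + alpha * (L_KL - L_NG)`: cross-entropy plus the consistency
#' term minus the negative-separation term, with one coefficient `alpha`
#' weighting both regularizers. With `alpha = 0` the objective reduces to
#' dual-pass cross-entropy; with the negative term removed it is the
#' dropout-consistency (R-Drop) objective.
#'
#' @param ce,kl,ng Scalar loss components.
#' @param alpha Non-negative coefficient weight.
#' @return A `loss_breakdown`: list with `l_ce`, `l_kl`, `l_ng`, `alpha`,
#'   `total`.
#' @export
total_loss <- function(ce, kl, ng, alpha) {
  if (alpha < 0) stop_negdrop("alpha must be non-negative")
  structure(list(l_ce = ce, l_kl = kl, l_ng = ng, alpha = alpha,
                 total = ce + alpha * (kl - ng)),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf(
    "<loss_breakdown> total %.6f = CE %.6f + %.3g * (KL %.6f - NG %.6f)\n",
    x$total, x$l_ce, x$alpha, x$l_kl, x$l_ng))
  invisible(x)
}

# ---- gradients (internal) -------------------------------------------------
# All gradients are taken with respect to the pre-softmax logits of the
# three passes; softmax_backward chains a gradient w.r.t. probabilities
# through the softmax Jacobian.

softmax_backward <- function(p, gp) {
  p * (gp - rowSums(p * gp))
}

# Gradient of the combined objective w.r.t. the logits z1, z2, z_ng.
# Returns the loss breakdown alongside so the forward values are computed
# once. `use_kl` / `use_negative` zero out terms (and their gradients) for
# the reduction properties (alpha = 0 -> dual CE; no negative -> R-Drop).
loss_grads <- function(p1, p2, p_ng, y, alpha,
                       negative_loss = c("mse", "kl"),
                       use_kl = TRUE, use_negative = TRUE) {
  negative_loss <- match.arg(negative_loss)
  n <- nrow(p1); k <- ncol(p1)
  yh <- matrix(0, n, k)
  yh[cbind(seq_len(n), y)] <- 1
  ce <- dual_cross_entropy(p1, p2, y)
  dz1 <- (p1 - yh) / n
  dz2 <- (p2 - yh) / n
  dzng <- matrix(0, n, k)
  kl <- if (use_kl) bidirectional_kl(p1, p2) else 0
  if (use_kl && alpha > 0) {
    s <- log(pmax(p1, PROB_EPS)) - log(pmax(p2, PROB_EPS))
    g1 <- 0.5 / n * (p1 * (s - rowSums(p1 * s)) + (p1 - p2))
    g2 <- 0.5 / n * (p2 * (-s - rowSums(p2 * -s)) + (p2 - p1))
    dz1 <- dz1 + alpha * g1
    dz2 <- dz2 + alpha * g2
  }
  ng <- 0
  if (use_negative && !is.null(p_ng)) {
    m <- (p1 + p2) / 2
    if (negative_loss == "mse") {
      ng <- negative_mse(p1, p2, p_ng)
      if (alpha > 0) {
        d <- m - p_ng
        gm <- 2 * d / (n * k)          # dNG/dM
        dz1 <- dz1 - alpha * softmax_backward(p1, gm / 2)
        dz2 <- dz2 - alpha * softmax_backward(p2, gm / 2)
        dzng <- -alpha * softmax_backward(p_ng, -gm)
      }
    } else {
      ng <- negative_kl(p1, p2, p_ng)
      if (alpha > 0) {
        mf <- pmax(m, PROB_EPS); qf <- pmax(p_ng, PROB_EPS)
        # d/dM of mean_i 0.5 [KL(M||Png) + KL(Png||M)]
        gm <- 0.5 / n * ((log(mf) - log(qf) + 1) - p_ng / mf)
        dz1 <- dz1 - alpha * softmax_backward(p1, gm / 2)
        dz2 <- dz2 - alpha * softmax_backward(p2, gm / 2)
        t2 <- log(qf) - log(mf)
        gq <- 0.5 / n * (p_ng * (t2 - rowSums(p_ng * t2)) + (p_ng - m))
        dzng <- -alpha * gq
      }
    }
  }
  list(breakdown = total_loss(ce, kl, ng, alpha),
       dz1 = dz1, dz2 = dz2, dzng = dzng)
}
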