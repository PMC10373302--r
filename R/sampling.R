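#' Max-minus negative sampling
#'
#' Builds one negative sample per row of a mini-batch by subtracting each
#' row from the vector of per-feature column maxima of that batch:
#' `x_ng[i, j] = max_i(x_b[i, j]) - x_b[i, j]`. The resulting rows combine
#' feature values in clinically implausible ways (e.g. a very young patient
#' with a very long course of treatment), making them semantically unlike
#' any real class while staying on the scale of the batch.
#'
#' Algebraic consequences used in the tests: every entry is non-negative,
#' each column's minimum is 0, each column's maximum equals the range
#' (max - min) of the source column, applying the operator twice gives
#' `x_b - colmin(x_b)`, and on a 0/1 column containing both values it is
#' exactly the bit-flip `1 - x`.
#'
#' @param x Numeric matrix (batch x features), imputed (no missing values).
#' @return Matrix of the same shape containing the negative batch.
#' @export
max_minus_negatives <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 1L) stop_negdrop("batch must contain at least one row")
  if (anyNA(x)) stop_negdrop("batch contains missing values; impute first")
  cmax <- apply(x, 2L, max)
  matrix(cmax, nrow(x), ncol(x), byrow = TRUE) - x
}

#' In-batch negative sampling
#'
#' Baseline strategy: each row's negative is a row drawn uniformly (seeded)
#' from the rows of the same batch whose label differs from the anchor's.
#'
#' @param x Numeric matrix (batch x features).
#' @param y Labels, one per row.
#' @param seed Integer seed for the draws.
#' @return Matrix of the same shape; row `i` is a batch row with a label
#'   different from `y[i]`.
#' @export
in_batch_negatives <- function(x, y, seed = 1L) {
  x <- as.matrix(x)
  if (length(y) != nrow(x)) stop_negdrop("y must have one label per row")
  if (length(unique(y)) < 2L) {
    stop_negdrop("in-batch negatives need at least two classes in the batch",
                 class = "negdrop_sampling_error")
  }
  idx <- with_rng_seed(derive_seed(seed, "in_batch"), {
    vapply(seq_len(nrow(x)), function(i) {
      cand <- which(y != y[i])
      if (length(cand) == 1L) cand else sample(cand, 1L)
    }, integer(1))
  })
  x[idx, , drop = FALSE]
}

#' Random-generation negative sampling
#'
#' Baseline strategy: rows are synthesized feature-wise -- boolean features
#' as Bernoulli(0.5) draws, continuous features uniform over their schema
#' range -- and any generated row that collides with a row of the reference
#' dataset is resampled (up to `max_retries` rounds).
#'
#' @param schema A [feature_schema()]; continuous ranges must be finite.
#' @param batch_size Number of negative rows to generate.
#' @param seed Integer seed.
#' @param data Optional numeric matrix of dataset rows that generated
#'   negatives must not duplicate.
#' @param max_retries Resampling rounds before giving up.
#' @return `batch_size x n_features` matrix.
#' @export
random_generation_negatives <- function(schema, batch_size, seed = 1L,
                                        data = NULL, max_retries = 100L) {
  p <- n_features(schema)
  bi <- boolean_idx(schema)
  ci <- continuous_idx(schema)
  for (nm in schema$feature_names[ci]) {
    r <- schema$continuous_ranges[[nm]]
    if (!all(is.finite(r))) {
      stop_negdrop("continuous feature '", nm,
                   "' needs a finite range for random generation")
    }
  }
  draw <- function(k) {
    m <- matrix(0, k, p, dimnames = list(NULL, schema$feature_names))
    if (length(bi)) m[, bi] <- stats::rbinom(k * length(bi), 1L, 0.5)
    for (j in ci) {
      r <- schema$continuous_ranges[[schema$feature_names[j]]]
      m[, j] <- stats::runif(k, r[1], r[2])
    }
    m
  }
  collides <- function(m) {
    if (is.null(data)) return(rep(FALSE, nrow(m)))
    key <- apply(m, 1L, paste, collapse = "\r")
    key %in% apply(as.matrix(data), 1L, paste, collapse = "\r")
  }
  with_rng_seed(derive_seed(seed, "random_generation"), {
    out <- draw(batch_size)
    bad <- collides(out)
    tries <- 0L
    while (any(bad)) {
      tries <- tries + 1L
      if (tries > max_retries) {
        stop_negdrop("could not generate non-colliding negatives within ",
                     max_retries, " retries",
                     class = "negdrop_sampling_error")
      }
      out[bad, ] <- draw(sum(bad))
      bad <- collides(out)
    }
    out
  })
}

# Dispatch used by the training loop.
make_negatives <- function(strategy, x, y, seed, schema = NULL, data = NULL) {
  switch(strategy,
    max_minus = max_minus_negatives(x),
    in_batch = in_batch_negatives(x, y, seed),
    random_generation = random_generation_negatives(
      schema, nrow(x), seed, data = data),
    stop_negdrop("unknown negative strategy '", strategy, "'"))
}
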