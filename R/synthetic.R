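#' Generator specification for synthetic clinical tables
#'
#' Defines a class-conditional generative model for clinical-like tabular
#' data: boolean symptom features are Bernoulli with per-class success
#' probabilities, continuous features are Gaussian with per-class means and
#' standard deviations (clipped to their range), labels follow given class
#' proportions, and missingness is injected completely at random (MCAR)
#' over boolean cells only -- either an exact cell count or an independent
#' per-cell rate. An optional MAR hook makes the missingness probability
#' of each boolean cell depend on one observed feature.
#'
#' @param n_rows Number of rows (patients).
#' @param n_boolean,n_continuous Feature counts by type.
#' @param n_classes Number of classes.
#' @param bernoulli `n_classes x n_boolean` matrix of success
#'   probabilities.
#' @param cont_means,cont_sds `n_classes x n_continuous` matrices of
#'   Gaussian parameters.
#' @param cont_ranges List of `c(min, max)` per continuous feature.
#' @param class_proportions Class probabilities (default balanced).
#' @param missing_count Exact number of missing boolean cells (MCAR).
#' @param missing_rate Alternative: independent per-cell missingness
#'   probability (ignored when `missing_count` given).
#' @param mar_feature,mar_slope Optional MAR hook: boolean-cell missingness
#'   odds shift with the (scaled) value of continuous feature
#'   `mar_feature`. Off by default.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A `generator_spec`.
#' @export
generator_spec <- function(n_rows, n_boolean, n_continuous, n_classes,
                           bernoulli, cont_means, cont_sds, cont_ranges,
                           class_proportions = rep(1 / n_classes, n_classes),
                           missing_count = NULL, missing_rate = NULL,
                           mar_feature = NULL, mar_slope = 0,
                           seed = 1L) {
  if (abs(sum(class_proportions) - 1) > 1e-8) {
    stop_negdrop("class_proportions must sum to 1")
  }
  bernoulli <- as.matrix(bernoulli)
  if (!identical(dim(bernoulli), c(as.integer(n_classes), as.integer(n_boolean)))) {
    stop_negdrop("bernoulli must be n_classes x n_boolean")
  }
  if (any(bernoulli < 0 | bernoulli > 1)) {
    stop_negdrop("Bernoulli parameters must lie in [0, 1]")
  }
  if (!is.null(missing_count) && missing_count > n_rows * n_boolean) {
    stop_negdrop("missing_count exceeds the number of boolean cells")
  }
  structure(list(n_rows = as.integer(n_rows), n_boolean = as.integer(n_boolean),
                 n_continuous = as.integer(n_continuous),
                 n_classes = as.integer(n_classes),
                 bernoulli = bernoulli,
                 cont_means = as.matrix(cont_means),
                 cont_sds = as.matrix(cont_sds),
                 cont_ranges = cont_ranges,
                 class_proportions = class_proportions,
                 missing_count = missing_count, missing_rate = missing_rate,
                 mar_feature = mar_feature, mar_slope = mar_slope,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

#' Built-in clinical profile
#'
#' The fixed synthetic profile used as the package's standard benchmark:
#' 1,920 patients, 22 boolean symptom features, 2 continuous features,
#' 7 classes (balanced), and exactly 275 MCAR-missing boolean cells --
#' matching the shape and missingness of a multi-syndrome clinical cohort.
#' Boolean parameters follow a 0.2/0.8 pattern (each class elevates its
#' own subset of symptoms, scaled by `separation`); continuous features
#' are unit-variance Gaussians with class-shifted means. At
#' `separation = 1` the Bayes-optimal classifier is nearly perfect; at
#' `separation = 0` all classes coincide and accuracy is at chance.
#'
#' @param separation Non-negative scale of between-class parameter spread
#'   (1 = the standard benchmark, 0 = no signal).
#' @param missing_count Number of MCAR boolean cells (default 275).
#' @param seed Generator seed.
#' @return A [generator_spec()].
#' @export
clinical_profile <- function(separation = 1, missing_count = 275L,
                             seed = 20230713L) {
  if (separation < 0) stop_negdrop("separation must be non-negative")
  n_classes <- 7L; n_boolean <- 22L; n_continuous <- 2L
  # each class elevates a balanced pseudo-random subset of the symptoms
  # (a deterministic LCG bit per class/feature), so any two classes differ
  # in about half of the 22 boolean features
  sgn <- matrix(-1, n_classes, n_boolean)
  for (c in seq_len(n_classes)) {
    s <- c
    for (j in seq_len(n_boolean)) {
      s <- (69069 * s + 1) %% 65536
      if (s >= 32768) sgn[c, j] <- 1
    }
  }
  bern <- pmin(pmax(0.5 + 0.3 * separation * sgn, 0), 1)
  means <- cbind(separation * (seq_len(n_classes) - 1L),
                 separation * (n_classes - seq_len(n_classes)))
  sds <- matrix(1, n_classes, n_continuous)
  generator_spec(
    n_rows = 1920L, n_boolean = n_boolean, n_continuous = n_continuous,
    n_classes = n_classes, bernoulli = bern,
    cont_means = means, cont_sds = sds,
    cont_ranges = list(c(-5, 12), c(-5, 12)),
    missing_count = missing_count, seed = seed)
}

spec_schema <- function(spec) {
  bnames <- sprintf("symptom_%02d", seq_len(spec$n_boolean))
  cnames <- if (spec$n_continuous > 0) {
    sprintf("measure_%02d", seq_len(spec$n_continuous))
  } else character(0)
  feature_schema(
    feature_names = c(bnames, cnames),
    feature_types = c(rep("boolean", spec$n_boolean),
                      rep("continuous", spec$n_continuous)),
    class_labels = sprintf("class_%d", seq_len(spec$n_classes)),
    continuous_ranges = stats::setNames(spec$cont_ranges, cnames))
}

#' Generate a synthetic clinical table
#'
#' Draws a [clinical_table()] from a [generator_spec()]: labels by class
#' proportions, boolean features from the class-conditional Bernoulli
#' parameters, continuous features from clipped class-conditional
#' Gaussians, then MCAR missingness on boolean cells (exact count, or
#' Binomial per cell when a rate is given). Bit-identical for a fixed
#' seed; continuous cells are never missing.
#'
#' @param spec A [generator_spec()].
#' @param seed Optional seed overriding `spec$seed`.
#' @return A [clinical_table()].
#' @export
generate_clinical_dataset <- function(spec, seed = NULL) {
  if (is.null(seed)) seed <- spec$seed
  sch <- spec_schema(spec)
  n <- spec$n_rows; nb <- spec$n_boolean; nc <- spec$n_continuous
  with_rng_seed(derive_seed(seed, "generate"), {
    y <- sample.int(spec$n_classes, n, replace = TRUE,
                    prob = spec$class_proportions)
    vals <- matrix(NA_real_, n, nb + nc)
    for (j in seq_len(nb)) {
      vals[, j] <- stats::rbinom(n, 1L, spec$bernoulli[y, j])
    }
    for (k in seq_len(nc)) {
      r <- spec$cont_ranges[[k]]
      v <- stats::rnorm(n, spec$cont_means[y, k], spec$cont_sds[y, k])
      vals[, nb + k] <- pmin(pmax(v, r[1]), r[2])
    }
    mask <- matrix(FALSE, n, nb + nc)
    if (!is.null(spec$missing_count) && spec$missing_count > 0) {
      cells <- mcar_cells(spec, vals, n, nb)
      mask[cells] <- TRUE
    } else if (!is.null(spec$missing_rate) && spec$missing_rate > 0) {
      mask[, seq_len(nb)] <- stats::rbinom(n * nb, 1L, spec$missing_rate) == 1L
    }
    vals[mask] <- NA_real_
    clinical_table(vals, sch$class_labels[y], sch, mask)
  })
}

# Pick exactly missing_count boolean cells. MCAR: uniform without
# replacement. MAR hook: cell weights tilt with one continuous feature.
mcar_cells <- function(spec, vals, n, nb) {
  total <- n * nb
  if (is.null(spec$mar_feature) || spec$mar_slope == 0) {
    flat <- sample.int(total, spec$missing_count)
  } else {
    drv <- vals[, nb + spec$mar_feature]
    w <- exp(spec$mar_slope * as.numeric(scale(drv)))
    flat <- sample.int(total, spec$missing_count,
                       prob = rep(w, times = nb))
  }
  cbind(((flat - 1L) %% n) + 1L, ((flat - 1L) %/% n) + 1L)
}

# log-density of a Gaussian clipped to [lo, hi]: interior points keep the
# normal density; the clip bounds carry the point masses of the tails.
clipped_gauss_logdens <- function(x, mu, sd, lo, hi) {
  out <- stats::dnorm(x, mu, sd, log = TRUE)
  at_lo <- x <= lo
  at_hi <- x >= hi
  out[at_lo] <- stats::pnorm(lo, mu[at_lo], sd[at_lo], log.p = TRUE)
  out[at_hi] <- stats::pnorm(hi, mu[at_hi], sd[at_hi], lower.tail = FALSE,
                             log.p = TRUE)
  out
}

#' Monte-Carlo Bayes-optimal accuracy
#'
#' Estimates the accuracy of the exact posterior-argmax classifier under
#' the generative model of a [generator_spec()] (missingness ignored: the
#' oracle sees complete draws). Serves as the upper-bound reference for any
#' trained classifier on data from the same spec.
#'
#' @param spec A [generator_spec()].
#' @param n_mc Number of Monte-Carlo draws.
#' @param seed Seed for the draws.
#' @return List with `accuracy`, its Monte-Carlo standard error `se`, and
#'   `n_mc`.
#' @export
bayes_optimal_accuracy <- function(spec, n_mc = 20000L, seed = 1L) {
  nb <- spec$n_boolean; nc <- spec$n_continuous
  with_rng_seed(derive_seed(seed, "bayes_oracle"), {
    y <- sample.int(spec$n_classes, n_mc, replace = TRUE,
                    prob = spec$class_proportions)
    xb <- matrix(0, n_mc, nb)
    for (j in seq_len(nb)) xb[, j] <- stats::rbinom(n_mc, 1L, spec$bernoulli[y, j])
    xc <- matrix(0, n_mc, max(nc, 1L))
    for (k in seq_len(nc)) {
      r <- spec$cont_ranges[[k]]
      v <- stats::rnorm(n_mc, spec$cont_means[y, k], spec$cont_sds[y, k])
      xc[, k] <- pmin(pmax(v, r[1]), r[2])
    }
    ll <- matrix(rep(log(spec$class_proportions), each = n_mc),
                 n_mc, spec$n_classes)
    for (c in seq_len(spec$n_classes)) {
      for (j in seq_len(nb)) {
        p <- spec$bernoulli[c, j]
        ll[, c] <- ll[, c] + xb[, j] * log(max(p, 1e-300)) +
          (1 - xb[, j]) * log(max(1 - p, 1e-300))
      }
      for (k in seq_len(nc)) {
        r <- spec$cont_ranges[[k]]
        mu <- rep(spec$cont_means[c, k], n_mc)
        sd <- rep(spec$cont_sds[c, k], n_mc)
        ll[, c] <- ll[, c] + clipped_gauss_logdens(xc[, k], mu, sd, r[1], r[2])
      }
    }
    yhat <- max.col(ll, ties.method = "first")
    acc <- mean(yhat == y)
    list(accuracy = acc, se = sqrt(acc * (1 - acc) / n_mc), n_mc = n_mc)
  })
}
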