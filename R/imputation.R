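#' Imputation policy
#'
#' Bundles the imputation choices for a table: the strategy for boolean
#' features (mode, random draw from the empirical observed distribution,
#' Beta-Bernoulli Bayesian posterior predictive, or constant fill), the
#' fixed mean strategy for continuous features, the fill value for the
#' constant strategy, and the seed for the stochastic strategies.
#'
#' @param boolean_strategy One of `"mode"`, `"random"`, `"bayesian"`,
#'   `"nan_replace"`. Mode imputation is the default, being the strategy
#'   that performed best in practice for boolean symptom data.
#' @param fill_value Constant used by `"nan_replace"` (default 0).
#' @param seed Integer seed; required for the stochastic strategies
#'   (`"random"`, `"bayesian"`), ignored otherwise.
#' @param statistics Either `"all"` (column statistics computed on the full
#'   table, mirroring an impute-then-split protocol) or `"train"`
#'   (statistics restricted to rows given via `stat_rows` in
#'   [impute_table()], for leakage-safe use).
#' @return An `imputation_policy` object.
#' @export
imputation_policy <- function(boolean_strategy = c("mode", "random",
                                                   "bayesian", "nan_replace"),
                              fill_value = 0, seed = NULL,
                              statistics = c("all", "train")) {
  boolean_strategy <- match.arg(boolean_strategy)
  statistics <- match.arg(statistics)
  stochastic <- boolean_strategy %in% c("random", "bayesian")
  if (stochastic && is.null(seed)) {
    stop_negdrop("strategy '", boolean_strategy, "' requires a seed")
  }
  structure(list(boolean_strategy = boolean_strategy,
                 continuous_strategy = "mean",
                 fill_value = fill_value,
                 seed = if (stochastic) as.integer(seed) else NULL,
                 statistics = statistics),
            class = "imputation_policy")
}

check_observed <- function(values, missing, what) {
  if (length(values) != length(missing)) {
    stop_negdrop("values and missing flags differ in length")
  }
  if (all(missing)) {
    stop_negdrop("cannot ", what, ": column is entirely missing",
                 class = "negdrop_imputation_error")
  }
}

#' Mode imputation for one column
#'
#' Missing cells are set to the most frequent observed value; ties are
#' broken toward the smaller value so the result is deterministic.
#'
#' @param values Numeric vector.
#' @param missing Logical vector, `TRUE` where missing.
#' @return The filled vector; observed cells are untouched.
#' @export
impute_mode <- function(values, missing = is.na(values)) {
  check_observed(values, missing, "mode-impute")
  obs <- values[!missing]
  tab <- table(obs)
  best <- names(tab)[tab == max(tab)]
  fill <- min(as.numeric(best))
  values[missing] <- fill
  values
}

#' Mean imputation for one continuous column
#'
#' @inheritParams impute_mode
#' @return The filled vector: missing cells set to the arithmetic mean of
#'   the observed cells.
#' @export
impute_mean <- function(values, missing = is.na(values)) {
  check_observed(values, missing, "mean-impute")
  values[missing] <- mean(values[!missing])
  values
}

#' Random imputation for one column
#'
#' Each missing cell is drawn independently from the empirical distribution
#' of the observed values in the same column (sampling with replacement),
#' which preserves the observed marginal. Draws come from the current RNG
#' state; callers wanting reproducibility should `set.seed()` first (done
#' by [impute_table()] via the policy seed).
#'
#' @inheritParams impute_mode
#' @return The filled vector.
#' @export
impute_random <- function(values, missing = is.na(values)) {
  check_observed(values, missing, "random-impute")
  obs <- values[!missing]
  k <- sum(missing)
  if (k > 0) values[missing] <- obs[sample.int(length(obs), k, replace = TRUE)]
  values
}

#' Bayesian imputation for one boolean column
#'
#' Beta(1,1)-Bernoulli conjugate model per column: with `s` observed ones
#' among `m` observed cells, the posterior predictive probability of a one
#' is `(s + 1) / (m + 2)`; each missing cell is an independent draw from
#' this posterior predictive. Uses the current RNG state (see
#' [impute_random()] for seeding).
#'
#' @inheritParams impute_mode
#' @param prior `c(a, b)` Beta prior pseudo-counts (default uniform
#'   `c(1, 1)`).
#' @return The filled vector.
#' @export
impute_bayes <- function(values, missing = is.na(values), prior = c(1, 1)) {
  check_observed(values, missing, "Bayes-impute")
  obs <- values[!missing]
  if (any(!(obs == 0 | obs == 1))) {
    stop_negdrop("Bayesian imputation requires a boolean (0/1) column",
                 class = "negdrop_imputation_error")
  }
  p1 <- (sum(obs) + prior[1]) / (length(obs) + prior[1] + prior[2])
  k <- sum(missing)
  if (k > 0) values[missing] <- stats::rbinom(k, 1L, p1)
  values
}

#' Constant-fill (NaN-replace) imputation for one column
#'
#' @inheritParams impute_mode
#' @param fill_value Constant written into every missing cell (default 0).
#'   A sentinel outside \{0, 1\} (e.g. -1) marks imputed boolean cells
#'   explicitly.
#' @return The filled vector.
#' @export
impute_nan_replace <- function(values, missing = is.na(values), fill_value = 0) {
  values[missing] <- fill_value
  values
}

#' Impute every missing cell of a clinical table
#'
#' Boolean columns are filled according to the policy's boolean strategy;
#' continuous columns by the mean of their observed cells. Column
#' statistics (mode, mean, posterior) are computed on the input table only
#' -- by default on all rows, or on `stat_rows` when the policy asks for
#' train-only statistics. Observed cells are never modified, and imputing
#' an already-complete table returns it unchanged for every strategy.
#'
#' @param table A [clinical_table()].
#' @param policy An [imputation_policy()].
#' @param stat_rows Optional integer row indices on which column statistics
#'   are computed (required when `policy$statistics == "train"`).
#' @return A complete `clinical_table` (all-`FALSE` missing mask).
#' @export
impute_table <- function(table, policy = imputation_policy(),
                         stat_rows = NULL) {
  if (policy$statistics == "train" && is.null(stat_rows)) {
    stop_negdrop("policy asks for train-only statistics but stat_rows is NULL")
  }
  if (is.null(stat_rows)) stat_rows <- seq_len(nrow(table$values))
  vals <- table$values
  mask <- table$missing_mask
  sch <- table$schema
  fill_col <- function(j) {
    nm <- sch$feature_names[j]
    v <- vals[, j]
    m <- mask[, j]
    sv <- v[stat_rows]
    sm <- m[stat_rows]
    if (!any(m)) return(v)
    res <- tryCatch({
      if (sch$feature_types[j] == "continuous") {
        check_observed(sv, sm, "mean-impute")
        v[m] <- mean(sv[!sm])
        v
      } else {
        switch(policy$boolean_strategy,
          mode = {
            check_observed(sv, sm, "mode-impute")
            tab <- table(sv[!sm])
            v[m] <- min(as.numeric(names(tab)[tab == max(tab)]))
            v
          },
          random = with_rng_seed(derive_seed(policy$seed, "impute", nm), {
            check_observed(sv, sm, "random-impute")
            obs <- sv[!sm]
            v[m] <- obs[sample.int(length(obs), sum(m), replace = TRUE)]
            v
          }),
          bayesian = with_rng_seed(derive_seed(policy$seed, "impute", nm), {
            check_observed(sv, sm, "Bayes-impute")
            obs <- sv[!sm]
            if (any(!(obs == 0 | obs == 1))) {
              stop_negdrop("Bayesian imputation requires a boolean (0/1) column",
                           class = "negdrop_imputation_error")
            }
            p1 <- (sum(obs) + 1) / (length(obs) + 2)
            v[m] <- stats::rbinom(sum(m), 1L, p1)
            v
          }),
          nan_replace = {
            v[m] <- policy$fill_value
            v
          })
      }
    }, negdrop_imputation_error = function(e) {
      stop_negdrop("column '", nm, "': ", conditionMessage(e),
                   class = "negdrop_imputation_error")
    })
    res
  }
  for (j in seq_len(ncol(vals))) vals[, j] <- fill_col(j)
  clinical_table(vals, table$labels, sch,
                 matrix(FALSE, nrow(vals), ncol(vals)))
}
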