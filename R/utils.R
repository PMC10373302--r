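#' @keywords internal
"_PACKAGE"

# Deterministic 31-bit seed derivation: one root seed fans out into named
# per-stage streams (split, dropout pass 1/2, negative sampling, generator,
# imputation) so that varying one stage never perturbs another.
derive_seed <- function(seed, ...) {
  parts <- c(as.character(seed), vapply(list(...), as.character, character(1)))
  h <- 2166136261 %% 2147483647
  for (s in parts) {
    for (k in utf8ToInt(s)) {
      h <- (bitwXor(as.integer(h), as.integer(k)) * 16777619) %% 2147483647
    }
  }
  as.integer(h)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_rng_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stop_negdrop <- function(..., class = "negdrop_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}
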