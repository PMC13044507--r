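# Internal helpers: seeded evaluation, seed derivation, input checks.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package functions are pure
#' functions of their `seed` argument and never disturb the caller's RNG
#' stream.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible sub-seed from a master seed and an index
#'
#' Mixing is a fixed affine map modulo the Mersenne prime 2^31 - 1, computed
#' in doubles (largest intermediate < 2^53, so exact). Results always lie in
#' [1, 2^31 - 2] and are valid `set.seed()` inputs.
#' @noRd
derive_seed <- function(seed, index, stream = 0L) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m) * 48271 + as.numeric(index) * 104729 +
    as.numeric(stream) * 7919 + 12345
  as.integer(s %% (m - 1)) + 1L
}

stop_if_not_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a finite scalar in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}

logistic <- function(x) 1 / (1 + exp(-x))
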