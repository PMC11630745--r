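# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the generator, evaluates `expr`, and restores the caller's RNG
#' state afterwards, so generators are pure functions of (parameters, seed).
#' @noRd
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a master seed and integer indices
#'
#' Deterministic mixing kept below 2^31 so the result is a valid R seed.
#' @noRd
derive_seed <- function(seed, ...) {
  ks <- c(seed, ...)
  acc <- 0
  for (k in ks) acc <- (acc * 7919 + as.numeric(k) + 1) %% 2147483587
  as.integer(acc) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_pre <- function(...) stop(..., call. = FALSE)
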