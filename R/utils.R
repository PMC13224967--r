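# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the global RNG state, seeds it with `seed`, evaluates `code`, and
#' restores the previous state on exit, so seeded internals never perturb the
#' caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
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
  code
}

# Derive a child seed from a base seed and a stream label; keeps independent
# random streams (init, dropout, sampling) reproducible and below 2^31.
derive_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(paste0(label, ":", seed))) {
    h <- (h * 31 + ch) %% 2147483629
  }
  as.integer(h)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 1 && x == floor(x)

assert_finite_matrix <- function(x, what) {
  if (!is.matrix(x) || !is.numeric(x)) stopf("%s must be a numeric matrix", what)
  if (!all(is.finite(x))) stopf("%s contains non-finite values", what)
  invisible(x)
}
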