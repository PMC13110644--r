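#' @keywords internal
#' @importFrom ggplot2 .data
"_PACKAGE"

# run code with a temporary RNG seed, restoring the caller's stream afterwards
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

check_prob <- function(x, name, allow_zero = TRUE, allow_one = TRUE) {
  if (!is.numeric(x) || anyNA(x))
    stop(sprintf("'%s' must be numeric and non-missing", name), call. = FALSE)
  lo <- if (allow_zero) x >= 0 else x > 0
  hi <- if (allow_one) x <= 1 else x < 1
  if (!all(lo & hi))
    stop(sprintf("'%s' must lie in %s0, 1%s (got %s)", name,
                 if (allow_zero) "[" else "(", if (allow_one) "]" else ")",
                 paste(signif(x[!(lo & hi)], 6), collapse = ", ")), call. = FALSE)
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0))
    stop(sprintf("'%s' must be non-negative", name), call. = FALSE)
  invisible(x)
}

# seeds for sub-draws, kept below .Machine$integer.max
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
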