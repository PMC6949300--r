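#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx coef cor lm median nls pf predict pt quantile
#'   rnorm runif sd setNames
#' @importFrom utils combn
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a local RNG seed
#'
#' Restores the caller's `.Random.seed` afterwards so seeded package
#' functions never disturb the global RNG stream.
#'
#' @param seed integer seed, or NULL to use the current stream.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

clamp01 <- function(x) pmin(1, pmax(0, x))

assert_prob <- function(x, what = deparse(substitute(x))) {
  if (any(!is.finite(x) | x < 0 | x > 1))
    stop(what, " must lie in [0, 1]", call. = FALSE)
  invisible(x)
}

assert_nonneg <- function(x, what = deparse(substitute(x))) {
  if (any(is.na(x)) || any(x < 0))
    stop(what, " must be non-negative", call. = FALSE)
  invisible(x)
}
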