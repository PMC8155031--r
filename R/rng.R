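#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded at `seed`, then restores the
#' previous RNG state, so seeded package functions do not disturb the
#' caller's random stream. With `seed = NULL` the expression runs on the
#' current stream.
#'
#' @param seed single integer seed, or `NULL` for no reseeding.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite integer or NULL", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive reproducible sub-seeds from a master seed
#'
#' @param seed master seed (integer) or `NULL`.
#' @param n number of sub-seeds.
#' @return Integer vector of length `n`; all values below 2^31. For
#'   `seed = NULL`, sub-seeds are drawn from the current RNG stream.
#' @export
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}
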