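#' Compositional null-model recipe
#'
#' Parameters of the compositional cohort generator: normalized
#' 'expression profiles' with no gene-to-gene coordination, used to
#' expose the spurious correlations that constant-sum normalization
#' induces. The master profile is drawn from a Pareto (power-law) density
#' proportional to x^(-gamma); small `exponent` means a heavy tail and
#' heterogeneous profiles, large `exponent` homogeneous ones.
#'
#' @param n_genes,n_cells cohort dimensions (defaults 200 x 100).
#' @param exponent power-law exponent gamma > 1.
#' @param noise_sd sd of the per-entry multiplicative factors
#'   phi ~ N(1, noise_sd^2); default 0.2.
#' @param x_min lower cutoff of the power law (default 1; the scale
#'   cancels in the normalization).
#' @param seed default seed for [generate_compositional_cohort()].
#' @return A list of class `compositional_spec`.
#' @export
compositional_spec <- function(n_genes = 200, n_cells = 100, exponent = 2,
                               noise_sd = 0.2, x_min = 1, seed = NULL) {
  if (exponent <= 1)
    stop("`exponent` must exceed 1 (heavy tail not normalizable)",
         call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (x_min <= 0) stop("`x_min` must be positive", call. = FALSE)
  structure(list(n_genes = n_genes, n_cells = n_cells, exponent = exponent,
                 noise_sd = noise_sd, x_min = x_min, seed = seed),
            class = "compositional_spec")
}

# Inverse-CDF sampler of the Pareto density gamma' x_min^gamma' x^-(gamma'+1)
# written with the density exponent gamma: p(x) ~ x^-gamma on [x_min, Inf).
rpareto <- function(n, exponent, x_min) {
  x_min * (1 - runif(n))^(-1 / (exponent - 1))
}

#' Generate a compositional null cohort
#'
#' Draws a master profile y0 with i.i.d. power-law entries, multiplies it
#' per cell by i.i.d. N(1, noise_sd^2) factors (negative products floored
#' at 0), and rescales every cell profile to sum to exactly 1. No step
#' couples distinct genes beyond the shared normalization, so any
#' measured gene-to-gene correlation is spurious.
#'
#' @param spec a [compositional_spec()].
#' @param seed integer seed; defaults to `spec$seed`.
#' @return An [expression_cohort()] whose columns each sum to 1.
#' @examples
#' co <- generate_compositional_cohort(
#'   compositional_spec(n_genes = 50, n_cells = 20, exponent = 2, seed = 1))
#' colSums(co$values)[1:3]
#' @export
generate_compositional_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "compositional_spec"))
  values <- with_seed(seed, {
    y0 <- rpareto(spec$n_genes, spec$exponent, spec$x_min)
    phi <- matrix(rnorm(spec$n_genes * spec$n_cells, 1, spec$noise_sd),
                  spec$n_genes, spec$n_cells)
    y <- pmax(y0 * phi, 0)
    totals <- colSums(y)
    if (any(totals <= 0))
      stop("degenerate cell with zero total expression", call. = FALSE)
    sweep(y, 2, totals, "/")
  })
  out <- expression_cohort(values)
  attr(out, "seed") <- seed
  out
}
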