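#' Cohort simulation recipe
#'
#' Bundles every knob of the GRN cohort simulator into one reproducible
#' recipe. Defaults follow the reference study conditions: N = 200 genes,
#' M = 100 cells, 5 inoperative genes per cell, an Erdős–Rényi
#' interaction network of average out-degree 2 on top of universal
#' self-regulation, link weights drawn from U(0, 2), degradation B = 1
#' and Hill exponent n = 1.
#'
#' @param n_genes number of genes N.
#' @param n_cells number of cells M.
#' @param heterogeneity p in \[0, 1\]: per-cell probability that each
#'   existing link weight (self-loops included) is redrawn from the weight
#'   distribution — the 'biological variability' dial.
#' @param noise_sd sigma >= 0 of the multiplicative measurement noise —
#'   the 'technical variability' dial.
#' @param n_inoperative genes clamped to zero expression per cell.
#' @param avg_degree mean number of incoming interaction links per gene
#'   (excluding the self-loop).
#' @param weight_low,weight_high bounds of the uniform weight distribution.
#' @param degradation self-degradation rate B.
#' @param hill_exponent Hill exponent n of the saturating activation.
#' @param interactions logical; `FALSE` removes all gene–gene links,
#'   leaving self-regulation only.
#' @param inoperative_per `"cell"` draws a fresh inoperative set per cell
#'   (default), `"cohort"` draws one set shared by all cells.
#' @param init_low,init_high bounds of the uniform random initial
#'   conditions of the ODE integration.
#' @param seed default seed used by [simulate_cohort()].
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_genes = 200, n_cells = 100, heterogeneity = 0,
                        noise_sd = 0, n_inoperative = 5, avg_degree = 2,
                        weight_low = 0, weight_high = 2, degradation = 1,
                        hill_exponent = 1, interactions = TRUE,
                        inoperative_per = c("cell", "cohort"),
                        init_low = 0, init_high = 1, seed = NULL) {
  inoperative_per <- match.arg(inoperative_per)
  if (n_genes < 2) stop("`n_genes` must be >= 2", call. = FALSE)
  if (heterogeneity < 0 || heterogeneity > 1)
    stop("`heterogeneity` must lie in [0, 1]", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (n_inoperative < 0 || n_inoperative > n_genes)
    stop("`n_inoperative` must lie in [0, n_genes]", call. = FALSE)
  if (avg_degree < 0 || avg_degree >= n_genes)
    stop("`avg_degree` must lie in [0, n_genes)", call. = FALSE)
  if (weight_high <= weight_low)
    stop("`weight_high` must exceed `weight_low`", call. = FALSE)
  structure(list(n_genes = n_genes, n_cells = n_cells,
                 heterogeneity = heterogeneity, noise_sd = noise_sd,
                 n_inoperative = n_inoperative, avg_degree = avg_degree,
                 weight_low = weight_low, weight_high = weight_high,
                 degradation = degradation, hill_exponent = hill_exponent,
                 interactions = interactions,
                 inoperative_per = inoperative_per,
                 init_low = init_low, init_high = init_high, seed = seed),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("GRN cohort spec: N =", x$n_genes, "genes, M =", x$n_cells, "cells\n")
  cat("  heterogeneity p =", x$heterogeneity, "| noise sd =", x$noise_sd,
      "| inoperative =", x$n_inoperative, "per", x$inoperative_per, "\n")
  cat("  avg degree =", x$avg_degree,
      if (!x$interactions) "(interactions disabled)" else "",
      "| weights U(", x$weight_low, ",", x$weight_high, ")\n")
  invisible(x)
}

#' Build the cohort's base regulatory network
#'
#' Every gene carries a self-regulation loop; each ordered off-diagonal
#' pair (i, j) carries an interaction link independently with probability
#' `avg_degree / (n_genes - 1)` (an Erdős–Rényi directed network). All
#' existing links, self-loops included, get i.i.d. uniform weights. With
#' `interactions = FALSE` in the spec, off-diagonal links are omitted.
#'
#' @param spec a [cohort_spec()].
#' @param seed optional integer seed.
#' @return An object of class `grn_model`: list with `weights` (N x N
#'   matrix; entry \[i, j\] is the strength with which gene j activates
#'   gene i), `degradation`, `hill_exponent`, `weight_low`, `weight_high`.
#' @export
build_base_network <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_genes
  p_link <- spec$avg_degree / (n - 1)
  if (p_link > 1) stop("link probability exceeds 1", call. = FALSE)
  w <- with_seed(seed, {
    w <- matrix(0, n, n)
    if (spec$interactions && p_link > 0) {
      links <- matrix(runif(n * n) < p_link, n, n)
      diag(links) <- FALSE
      w[links] <- runif(sum(links), spec$weight_low, spec$weight_high)
    }
    diag(w) <- runif(n, spec$weight_low, spec$weight_high)
    w
  })
  structure(list(weights = w, degradation = spec$degradation,
                 hill_exponent = spec$hill_exponent,
                 weight_low = spec$weight_low,
                 weight_high = spec$weight_high),
            class = "grn_model")
}

#' @export
print.grn_model <- function(x, ...) {
  n <- nrow(x$weights)
  off <- sum(x$weights[row(x$weights) != col(x$weights)] > 0)
  cat("GRN model:", n, "genes,", off, "interaction links",
      sprintf("(avg in-degree %.2f),", off / n), "B =", x$degradation,
      ", Hill n =", x$hill_exponent, "\n")
  invisible(x)
}

#' Per-cell perturbation of the network weights
#'
#' Produces a cell's regulatory network from the cohort base: the
#' topology is preserved exactly (zeros stay zero), and every existing
#' link weight — self-loops included — is independently redrawn from the
#' uniform weight distribution with probability `p`, otherwise copied
#' from the base.
#'
#' @param base a [build_base_network()] model.
#' @param p redraw probability in \[0, 1\].
#' @param seed optional integer seed.
#' @return A new `grn_model` with the same topology.
#' @export
perturb_weights <- function(base, p, seed = NULL) {
  stopifnot(inherits(base, "grn_model"))
  if (p < 0 || p > 1) stop("`p` must lie in [0, 1]", call. = FALSE)
  w <- base$weights
  if (p > 0) {
    nz <- which(w != 0)
    w[nz] <- with_seed(seed, {
      redraw <- runif(length(nz)) < p
      new_w <- runif(length(nz), base$weight_low, base$weight_high)
      ifelse(redraw, new_w, w[nz])
    })
  }
  out <- base
  out$weights <- w
  out
}

#' Steady state of the regulatory dynamics
#'
#' Integrates the saturating-activation GRN ODE
#' \deqn{\dot x_i = -B x_i + \sum_j w_{ij}\,\frac{x_j^n}{1 + x_j^n}}
#' from `x0` with an adaptive explicit Runge–Kutta scheme
#' (Dormand–Prince 5(4), relative tolerance `rtol`) until the max-norm of
#' the derivative falls below `deriv_tol`, or `t_max` time units.
#' Inoperative genes are clamped to zero throughout the integration, so a
#' dead gene also stops activating its targets.
#'
#' @param model a `grn_model`.
#' @param inoperative integer indices of genes clamped to zero.
#' @param x0 nonnegative initial state (length N).
#' @param deriv_tol convergence threshold on max |dx/dt| (default 1e-6).
#' @param t_max maximum integration time (default 50000; near-critical
#'   self-regulation weights produce genuinely slow relaxation modes).
#' @param rtol,atol local error tolerances of the integrator.
#' @return A list of class `steady_state`: `x_star` (length-N nonnegative
#'   vector), `residual`, `t_end`.
#' @export
steady_state <- function(model, inoperative = integer(0), x0,
                         deriv_tol = 1e-6, t_max = 50000,
                         rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "grn_model"))
  n <- nrow(model$weights)
  if (length(x0) != n || any(!is.finite(x0)) || any(x0 < 0))
    stop("`x0` must be a finite nonnegative vector of length ", n,
         call. = FALSE)
  if (any(model$weights < 0))
    stop("negative weights are not supported (activating links only)",
         call. = FALSE)
  inoperative <- as.integer(inoperative)
  if (length(inoperative) && (min(inoperative) < 1 || max(inoperative) > n))
    stop("`inoperative` indices out of range", call. = FALSE)
  res <- grn_steady_state_cpp(model$weights, model$degradation,
                              model$hill_exponent, as.numeric(x0),
                              inoperative - 1L, deriv_tol, t_max, rtol, atol)
  if (!res$converged)
    stop(sprintf(paste0("steady state not reached by t_max = %g ",
                        "(residual derivative norm %.3e)"),
                 t_max, res$residual), call. = FALSE)
  structure(list(x_star = as.numeric(res$x), residual = res$residual,
                 t_end = res$t_end),
            class = "steady_state")
}

#' Simulate a cohort of actual expression profiles
#'
#' For each cell: draw its inoperative gene set, perturb the base weights
#' with probability `heterogeneity`, draw uniform random initial
#' conditions, and integrate the regulatory ODE to its steady state. The
#' columns of the result are the actual (noise-free) expression profiles
#' x*. Apply [add_measurement_noise()] for measured profiles.
#'
#' @param spec a [cohort_spec()].
#' @param base optional [build_base_network()] model shared by the cells;
#'   built from `spec` (and the derived seed) when NULL.
#' @param seed integer seed; defaults to `spec$seed`.
#' @return An [expression_cohort()] of actual profiles, with the seed in
#'   attribute `"seed"`.
#' @examples
#' co <- simulate_cohort(cohort_spec(n_genes = 40, n_cells = 10, seed = 7))
#' @export
simulate_cohort <- function(spec, base = NULL, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  seeds <- derive_seeds(seed, spec$n_cells + 2L)
  if (is.null(base)) base <- build_base_network(spec, seed = seeds[1])
  if (nrow(base$weights) != spec$n_genes)
    stop("`base` network size does not match `spec$n_genes`", call. = FALSE)
  cohort_inop <- if (spec$inoperative_per == "cohort")
    with_seed(seeds[2], sample.int(spec$n_genes, spec$n_inoperative))
  values <- matrix(0, spec$n_genes, spec$n_cells)
  for (v in seq_len(spec$n_cells)) {
    cell <- with_seed(seeds[2L + v], {
      inop <- if (spec$inoperative_per == "cell")
        sample.int(spec$n_genes, spec$n_inoperative) else cohort_inop
      model <- perturb_weights(base, spec$heterogeneity, seed = NULL)
      x0 <- runif(spec$n_genes, spec$init_low, spec$init_high)
      list(inop = inop, model = model, x0 = x0)
    })
    st <- tryCatch(
      steady_state(cell$model, inoperative = cell$inop, x0 = cell$x0),
      error = function(e)
        stop("cell ", v, ": ", conditionMessage(e), call. = FALSE))
    values[, v] <- st$x_star
  }
  out <- expression_cohort(values)
  attr(out, "seed") <- seed
  attr(out, "spec") <- spec
  out
}

#' Add multiplicative measurement noise
#'
#' Models technical variability as
#' \eqn{\tilde x_i^{(\nu)} = x_i^{*(\nu)} (1 + \epsilon_i^{(\nu)})} with
#' \eqn{\epsilon \sim N(0, \sigma^2)} i.i.d. Expression is nonnegative,
#' so the rare negative results (possible for large sigma) are floored at
#' zero. Zero entries stay exactly zero.
#'
#' @param actual an [expression_cohort()] of actual profiles.
#' @param sigma noise standard deviation (>= 0).
#' @param seed optional integer seed.
#' @return An [expression_cohort()] of measured profiles.
#' @export
add_measurement_noise <- function(actual, sigma, seed = NULL) {
  actual <- as_cohort(actual)
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  if (sigma == 0) return(actual)
  x <- actual$values
  eps <- with_seed(seed, matrix(rnorm(length(x), 0, sigma), nrow(x)))
  expression_cohort(pmax(x * (1 + eps), 0), gene_ids = actual$gene_ids,
                    cell_ids = actual$cell_ids)
}
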