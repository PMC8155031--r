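#' Random half-split of the gene set
#'
#' Draws a uniformly random division of `n_genes` genes into two disjoint
#' parts of floor(n_genes / 2) genes each. For odd `n_genes` one uniformly
#' random gene is left out of both parts, keeping the two views
#' dimensionally balanced. Uses the current RNG stream.
#'
#' @param n_genes number of genes (>= 2).
#' @return A list of class `gene_split` with integer index vectors
#'   `part_a` and `part_b`.
#' @export
split_genes <- function(n_genes) {
  if (n_genes < 2)
    stop("need at least 2 genes to split (got ", n_genes, ")", call. = FALSE)
  half <- n_genes %/% 2
  perm <- sample.int(n_genes)
  structure(list(part_a = perm[seq_len(half)],
                 part_b = perm[half + seq_len(half)]),
            class = "gene_split")
}

#' Global coordination level of an expression cohort
#'
#' The GCL is the average bias-corrected distance correlation over `m`
#' independent random half-splits of the gene set:
#' \deqn{\mathrm{GCL}(X) = \frac{1}{m}\sum_{k=1}^m
#'   \mathrm{bcdCorr}(A^k, B^k),}
#' where each split divides the genes x cells matrix into two random
#' complementary gene subsets A and B (cells are the samples, the subset
#' genes the features). The statistic typically stabilizes for m > 10;
#' the default is m = 50.
#'
#' With the default `normalize = "cell"`, every cell's sub-profile is
#' rescaled to unit Euclidean norm within each view before distances
#' are computed. This makes the statistic invariant to per-cell
#' amplitude factors — the signature of sequencing-depth differences
#' and of constant-sum (compositional) normalization — so coordination
#' must show up in the expression *pattern* across genes, not in a
#' shared scale. Regulatory coordination survives this normalization;
#' compositional artifacts do not. The flip side: a cohort whose only
#' structure is a common per-cell amplitude (every gene proportional to
#' one cell scalar) scores 0 under the default; use
#' `normalize = "none"` to treat amplitude as signal.
#'
#' @param cohort an [expression_cohort()] or genes x cells matrix, with at
#'   least 2 genes and 4 cells.
#' @param m number of random splits (>= 1); default 50.
#' @param seed optional integer for reproducible splits.
#' @param normalize `"cell"` (default) rescales each cell to unit norm
#'   within each view; `"none"` uses raw values.
#' @return An object of class `gcl_result`: list with `gcl` (the mean),
#'   `per_split` (the m bcdCorr values), `m` and `seed`.
#' @examples
#' co <- simulate_cohort(cohort_spec(n_genes = 30, n_cells = 20, seed = 1))
#' compute_gcl(co, m = 10, seed = 1)
#' @export
compute_gcl <- function(cohort, m = 50, seed = NULL,
                        normalize = c("cell", "none")) {
  normalize <- match.arg(normalize)
  cohort <- as_cohort(cohort)
  x <- cohort$values
  if (nrow(x) < 2) stop("GCL needs at least 2 genes", call. = FALSE)
  if (ncol(x) < 4)
    stop("GCL needs at least 4 cells (bcdCorr undefined below that)",
         call. = FALSE)
  if (m < 1) stop("`m` must be >= 1", call. = FALSE)
  tx <- t(x)  # cells x genes: rows are the samples
  make_view <- function(idx) {
    v <- tx[, idx, drop = FALSE]
    if (normalize == "cell") {
      nrm <- sqrt(rowSums(v^2))
      nrm[nrm == 0] <- 1  # all-zero cells stay at the origin
      v <- v / nrm
    }
    v
  }
  per_split <- with_seed(seed, vapply(seq_len(m), function(k) {
    sp <- split_genes(nrow(x))
    bcd_corr(make_view(sp$part_a), make_view(sp$part_b))
  }, numeric(1)))
  structure(list(gcl = mean(per_split), per_split = per_split, m = m,
                 seed = seed, normalize = normalize),
            class = "gcl_result")
}

#' @export
print.gcl_result <- function(x, ...) {
  cat("GCL =", format(x$gcl, digits = 4), "over", x$m, "splits (per-split SD",
      format(sd(x$per_split), digits = 3), ")\n")
  invisible(x)
}

#' Significance of the GCL against a gene-shuffling null
#'
#' Assesses whether the observed GCL exceeds what uncoordinated genes
#' would produce. The null model permutes each gene's values independently
#' across cells, which destroys gene-to-gene coordination while preserving
#' every gene's marginal distribution; `n_resample` such shuffled cohorts
#' give the null GCL distribution. A leave-one-cell-out jackknife gives
#' the spread of the observed statistic. The p-value is one-sided with
#' add-one smoothing:
#' \eqn{p = (1 + \#\{\mathrm{null} \ge \mathrm{obs}\}) / (n + 1)}.
#'
#' @inheritParams compute_gcl
#' @param n_resample number of shuffled null cohorts (>= 20).
#' @param jackknife logical; also compute the leave-one-cell-out spread
#'   (default TRUE; costs M extra GCL evaluations).
#' @return An object of class `gcl_significance`: list with `observed`
#'   (a [compute_gcl()] result), `null_values`, `p_value`, and
#'   `jackknife_values` / `jackknife_se` (NULL when `jackknife = FALSE`).
#' @export
gcl_significance <- function(cohort, m = 50, n_resample = 100, seed = NULL,
                             jackknife = TRUE,
                             normalize = c("cell", "none")) {
  normalize <- match.arg(normalize)
  cohort <- as_cohort(cohort)
  x <- cohort$values
  if (ncol(x) < 5)
    stop("need at least 5 cells for the jackknife", call. = FALSE)
  if (n_resample < 20)
    stop("`n_resample` must be >= 20 for a usable null", call. = FALSE)
  seeds <- derive_seeds(seed, n_resample + ncol(x) + 1)
  observed <- compute_gcl(x, m = m, seed = seeds[1], normalize = normalize)

  null_values <- vapply(seq_len(n_resample), function(b) {
    sh <- with_seed(seeds[1 + b],
                    t(apply(x, 1, sample)))
    compute_gcl(sh, m = m, seed = seeds[1 + b],
                normalize = normalize)$gcl
  }, numeric(1))

  jk_values <- jk_se <- NULL
  if (jackknife) {
    jk_values <- vapply(seq_len(ncol(x)), function(j) {
      compute_gcl(x[, -j, drop = FALSE], m = m,
                  seed = seeds[1 + n_resample + j], normalize = normalize)$gcl
    }, numeric(1))
    mm <- length(jk_values)
    jk_se <- sqrt((mm - 1) / mm * sum((jk_values - mean(jk_values))^2))
  }

  p_value <- (1 + sum(null_values >= observed$gcl)) / (n_resample + 1)
  structure(list(observed = observed, null_values = null_values,
                 p_value = p_value, jackknife_values = jk_values,
                 jackknife_se = jk_se, n_resample = n_resample, seed = seed),
            class = "gcl_significance")
}

#' @export
print.gcl_significance <- function(x, ...) {
  cat("Observed GCL =", format(x$observed$gcl, digits = 4))
  if (!is.null(x$jackknife_se))
    cat(" (jackknife SE", format(x$jackknife_se, digits = 3), ")")
  cat("\nShuffling null:", x$n_resample, "resamples, mean",
      format(mean(x$null_values), digits = 3), "\n")
  cat("One-sided p-value:", format(x$p_value, digits = 4), "\n")
  invisible(x)
}
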