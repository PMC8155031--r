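#' Pairwise Euclidean distances between samples
#'
#' Computes the samples x samples Euclidean distance matrix of a view
#' (samples in rows, features in columns). Exact symmetry and a zero
#' diagonal are guaranteed by construction.
#'
#' @param view numeric matrix, samples x features.
#' @return Symmetric nonnegative matrix with zero diagonal.
#' @export
pairwise_distances <- function(view) {
  view <- as.matrix(view)
  bad <- which(!is.finite(view))
  if (length(bad)) {
    idx <- arrayInd(bad, dim(view))
    stop("non-finite values in view at (sample, feature) positions: ",
         paste(sprintf("(%d,%d)", idx[, 1], idx[, 2])[seq_len(min(5, nrow(idx)))],
               collapse = ", "),
         if (nrow(idx) > 5) " ..." else "", call. = FALSE)
  }
  d <- as.matrix(dist(view, method = "euclidean"))
  dimnames(d) <- NULL
  (d + t(d)) / 2
}

#' U-center a distance matrix
#'
#' The U-centering of an n x n distance matrix `d` sets, for i != j,
#' \deqn{u_{ij} = d_{ij} - \frac{r_i}{n-2} - \frac{c_j}{n-2} +
#'       \frac{g}{(n-1)(n-2)}}
#' with row sums r, column sums c, grand sum g, and zero diagonal. Every
#' row of the result sums to zero over its off-diagonal entries, which is
#' what makes the induced distance-covariance estimator unbiased.
#'
#' @param d symmetric distance matrix with zero diagonal, n >= 4.
#' @return U-centered matrix of the same dimension.
#' @export
u_center <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 4)
    stop("U-centering requires at least 4 samples (got ", n, ")",
         call. = FALSE)
  rs <- rowSums(d)
  cs <- colSums(d)
  g <- sum(rs)
  u <- d - outer(rs, rep(1, n)) / (n - 2) - outer(rep(1, n), cs) / (n - 2) +
    g / ((n - 1) * (n - 2))
  diag(u) <- 0
  u
}

# Normalized inner product over off-diagonal entries of two U-centered
# matrices: sum_{i != j} u v / (n (n-3)). Diagonals are zero, so a plain
# elementwise sum suffices.
ucentered_inner <- function(u, v) {
  n <- nrow(u)
  sum(u * v) / (n * (n - 3))
}

#' Bias-corrected distance correlation between two views
#'
#' The bias-corrected distance correlation (bcdCorr) between two
#' multivariate views of the same samples: the normalized inner product of
#' the U-centered Euclidean distance matrices,
#' \deqn{\mathrm{bcdCorr}(A, B) = \frac{\langle \tilde A, \tilde B\rangle}
#'   {\sqrt{\langle\tilde A,\tilde A\rangle\,\langle\tilde B,\tilde B\rangle}}.}
#' Its expectation is zero under independence, so values can be (slightly)
#' negative. When either self inner product is nonpositive — all samples
#' identical in a view, or a tiny-sample degeneracy — no dependence is
#' measurable and the function returns 0 with a warning.
#'
#' @param a,b numeric matrices, samples x features, with the same samples
#'   in the same order (same row count, >= 4).
#' @return Scalar in \[-1, 1\].
#' @examples
#' set.seed(1)
#' a <- matrix(rnorm(40), nrow = 10)
#' bcd_corr(a, a)          # exactly 1
#' bcd_corr(a, matrix(rnorm(40), nrow = 10))  # near 0
#' @export
bcd_corr <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  if (nrow(a) != nrow(b))
    stop("views must share the same samples: ", nrow(a), " vs ", nrow(b),
         " rows", call. = FALSE)
  if (nrow(a) < 4)
    stop("bcd_corr requires at least 4 samples (got ", nrow(a), ")",
         call. = FALSE)
  da <- pairwise_distances(a)
  db <- pairwise_distances(b)
  # a view whose samples all coincide (up to rounding) carries no
  # distance information; its "correlation" would be rounding noise
  coincident <- function(x, d) max(d) <= 1e-12 * max(abs(x), 1e-300)
  if (coincident(a, da) || coincident(b, db)) {
    warning("degenerate view (all samples coincide); returning 0",
            call. = FALSE)
    return(0)
  }
  ua <- u_center(da)
  ub <- u_center(db)
  vaa <- ucentered_inner(ua, ua)
  vbb <- ucentered_inner(ub, ub)
  if (vaa <= 0 || vbb <= 0) {
    warning("degenerate view (nonpositive self inner product); ",
            "returning 0", call. = FALSE)
    return(0)
  }
  vab <- ucentered_inner(ua, ub)
  r <- vab / sqrt(vaa * vbb)
  max(-1, min(1, r))
}
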