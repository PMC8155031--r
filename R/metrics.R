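# Spearman correlation matrix with a documented convention for constant
# profiles: a pair involving a zero-variance vector has no defined rank
# correlation; it is scored 0 with a warning (strict = TRUE errors
# instead, naming the offenders). Ties get average ranks (midranks).
spearman_matrix <- function(x, what, strict = FALSE) {
  const <- which(apply(x, 2, function(v) length(unique(v)) < 2))
  if (length(const)) {
    who <- paste(colnames(x)[const], collapse = ", ")
    if (strict)
      stop("constant ", what, " profile(s): ", who, call. = FALSE)
    warning("constant ", what, " profile(s) scored as correlation 0: ",
            who, call. = FALSE)
  }
  rho <- suppressWarnings(cor(x, method = "spearman"))
  rho[is.na(rho)] <- 0
  rho
}

#' Cell-to-cell variability of a cohort
#'
#' The mean dissimilarity over all unordered cell pairs, where
#' dissimilarity is one minus the Spearman rank correlation of the two
#' cells' expression profiles. Ranges over \[0, 2\]: 0 when all cells
#' share one ranking, 2 when rankings are exactly reversed.
#'
#' @param cohort an [expression_cohort()] or genes x cells matrix with at
#'   least 2 cells.
#' @param strict error on constant cell profiles instead of scoring the
#'   pair 0 (see Details in [average_coexpression()]).
#' @return A list of class `variability_result`: `value` and `n_pairs`
#'   (= M(M-1)/2).
#' @export
cell_to_cell_variability <- function(cohort, strict = FALSE) {
  cohort <- as_cohort(cohort)
  x <- cohort$values
  m <- ncol(x)
  if (m < 2) stop("variability needs at least 2 cells", call. = FALSE)
  rho <- spearman_matrix(x, "cell", strict)
  pairs <- upper.tri(rho)
  structure(list(value = mean(1 - rho[pairs]), n_pairs = sum(pairs)),
            class = "variability_result")
}

#' Average absolute co-expression of a cohort
#'
#' The 'bottom-up' baseline statistic
#' \deqn{\langle C\rangle = \frac{2}{N(N-1)}\sum_{i<j} |C_{ij}|,}
#' where \eqn{C_{ij}} is the Spearman correlation of genes i and j across
#' cells. Inflated by small sample sizes and by compositional
#' normalization, which is exactly what the coordination statistic is
#' contrasted against.
#'
#' Genes with constant expression across cells (e.g. inoperative,
#' all-zero genes) have no defined rank correlation; their pairs are
#' scored 0 with a warning so they cannot poison the cohort average, or
#' raise an error when `strict = TRUE`.
#'
#' @param cohort an [expression_cohort()] or genes x cells matrix with at
#'   least 2 genes and 3 cells.
#' @param strict error on constant genes instead of scoring their pairs 0.
#' @return A list of class `coexpression_result`: `value` in \[0, 1\] and
#'   `n_pairs` (= N(N-1)/2).
#' @export
average_coexpression <- function(cohort, strict = FALSE) {
  cohort <- as_cohort(cohort)
  x <- cohort$values
  if (nrow(x) < 2) stop("co-expression needs at least 2 genes", call. = FALSE)
  if (ncol(x) < 3)
    stop("co-expression needs at least 3 cells", call. = FALSE)
  rho <- spearman_matrix(t(x), "gene", strict)
  pairs <- upper.tri(rho)
  structure(list(value = mean(abs(rho[pairs])), n_pairs = sum(pairs)),
            class = "coexpression_result")
}

#' @export
print.variability_result <- function(x, ...) {
  cat("Cell-to-cell variability:", format(x$value, digits = 4), "over",
      x$n_pairs, "cell pairs\n")
  invisible(x)
}

#' @export
print.coexpression_result <- function(x, ...) {
  cat("Average |co-expression| <C>:", format(x$value, digits = 4), "over",
      x$n_pairs, "gene pairs\n")
  invisible(x)
}
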