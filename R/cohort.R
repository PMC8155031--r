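#' Expression cohort container
#'
#' An expression cohort is a numeric genes x cells matrix with gene and
#' cell identifiers: the object all statistics in this package consume.
#' Values are expression levels (unitless, nonnegative for simulated
#' cohorts); columns are cells, rows are genes.
#'
#' @param values numeric matrix, genes in rows, cells in columns.
#' @param gene_ids,cell_ids optional character identifiers; default to the
#'   dimnames of `values` or `gene_<i>` / `cell_<j>`.
#' @return An object of class `expression_cohort`: a list with elements
#'   `values` (matrix with dimnames set), `gene_ids`, `cell_ids`.
#' @examples
#' x <- matrix(rexp(60), nrow = 6)
#' co <- expression_cohort(x)
#' dim(co)
#' @export
expression_cohort <- function(values, gene_ids = NULL, cell_ids = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (genes x cells)", call. = FALSE)
  bad <- which(!is.finite(values))
  if (length(bad))
    stop("cohort contains ", length(bad), " non-finite entries; first at ",
         "position [", arrayInd(bad[1], dim(values))[1], ",",
         arrayInd(bad[1], dim(values))[2], "]", call. = FALSE)
  if (is.null(gene_ids)) gene_ids <- rownames(values)
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(nrow(values)))
  if (is.null(cell_ids)) cell_ids <- colnames(values)
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(ncol(values)))
  if (length(gene_ids) != nrow(values) || anyDuplicated(gene_ids))
    stop("`gene_ids` must be unique and match nrow(values)", call. = FALSE)
  if (length(cell_ids) != ncol(values) || anyDuplicated(cell_ids))
    stop("`cell_ids` must be unique and match ncol(values)", call. = FALSE)
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(
    list(values = values, gene_ids = as.character(gene_ids),
         cell_ids = as.character(cell_ids)),
    class = "expression_cohort")
}

#' @export
dim.expression_cohort <- function(x) dim(x$values)

#' @export
print.expression_cohort <- function(x, ...) {
  cat("Expression cohort:", nrow(x$values), "genes x", ncol(x$values),
      "cells\n")
  cat("  value range: [", format(min(x$values), digits = 4), ", ",
      format(max(x$values), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' Subset the cells of a cohort
#'
#' @param cohort an [expression_cohort()].
#' @param cells integer indices or cell identifiers; order is preserved.
#' @return A new `expression_cohort` with the selected cells.
#' @export
subset_cells <- function(cohort, cells) {
  cohort <- as_cohort(cohort)
  if (is.character(cells)) cells <- match(cells, cohort$cell_ids)
  if (anyNA(cells) || length(cells) == 0)
    stop("unknown or empty cell selection", call. = FALSE)
  expression_cohort(cohort$values[, cells, drop = FALSE])
}

# Accept a bare matrix anywhere a cohort is expected.
as_cohort <- function(x) {
  if (inherits(x, "expression_cohort")) return(x)
  expression_cohort(as.matrix(x))
}

#' Write a cohort to a TSV file
#'
#' Writes a genes x cells table with a header row of cell identifiers and
#' the gene identifiers in the first column, plus a `<path>.meta` sidecar
#' recording provenance (package version and the seed, when known).
#'
#' @param cohort an [expression_cohort()].
#' @param path output TSV path.
#' @param seed optional integer recorded in the sidecar metadata.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, seed = NULL) {
  cohort <- as_cohort(cohort)
  df <- data.frame(gene_id = cohort$gene_ids, cohort$values,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- c(
    paste0("package=gclsim ", as.character(utils::packageVersion("gclsim"))),
    paste0("n_genes=", nrow(cohort$values)),
    paste0("n_cells=", ncol(cohort$values)),
    paste0("seed=", if (is.null(seed)) "NA" else as.integer(seed)))
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}

#' Read a cohort from a TSV file
#'
#' @param path TSV file as written by [write_cohort()]: header row of cell
#'   identifiers, first column gene identifiers.
#' @return An [expression_cohort()].
#' @export
read_cohort <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  expression_cohort(values, gene_ids = df[[1]], cell_ids = colnames(df)[-1])
}
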