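# Cell-level quality filters recommended before computing coordination
# statistics on real cohorts: outlying cells distort the distance
# geometry, and near-duplicate cell pairs (e.g. a cell measured just
# after division) inflate dependence between any two gene subsets.

filter_report <- function(cell_ids, removed_idx, reason, distance,
                          thresholds) {
  status <- rep("kept", length(cell_ids))
  status[removed_idx] <- "removed"
  rsn <- rep(NA_character_, length(cell_ids))
  rsn[removed_idx] <- reason
  rep <- data.frame(cell_id = cell_ids, status = status, reason = rsn,
                    distance = distance, stringsAsFactors = FALSE)
  attr(rep, "thresholds") <- thresholds
  class(rep) <- c("filter_report", "data.frame")
  rep
}

#' Remove outlier cells
#'
#' Computes the average expression profile over cells and each cell's
#' Euclidean distance to it, then removes the cells whose distance
#' exceeds mean + `k_sd` standard deviations of the distance set. A
#' single pass: the threshold is computed once, on all cells
#' (re-applying the filter can therefore remove further cells).
#'
#' @param cohort an [expression_cohort()] with at least 3 cells.
#' @param k_sd threshold multiplier (default 2); `Inf` removes nothing.
#' @return A list with `cohort` (kept cells, input order preserved) and
#'   `report` (a `filter_report` data frame with per-cell distances).
#' @export
remove_outlier_cells <- function(cohort, k_sd = 2) {
  cohort <- as_cohort(cohort)
  x <- cohort$values
  if (ncol(x) < 3) stop("need at least 3 cells", call. = FALSE)
  center <- rowMeans(x)
  d <- sqrt(colSums((x - center)^2))
  cutoff <- mean(d) + k_sd * sd(d)
  out <- which(d > cutoff)
  if (length(out) == ncol(x))
    stop("outlier filter removed every cell (degenerate threshold)",
         call. = FALSE)
  report <- filter_report(cohort$cell_ids, out, "outlier", d,
                          c(k_sd = k_sd, cutoff = cutoff))
  kept <- if (length(out)) cohort$values[, -out, drop = FALSE] else
    cohort$values
  list(cohort = expression_cohort(kept), report = report)
}

#' Remove near-duplicate cells
#'
#' Flags cell pairs whose Euclidean distance is below `rel_threshold`
#' times the median pairwise distance and removes the later-indexed cell
#' of each flagged pair (greedy in column order, deterministic). With the
#' default 0.05 the rule is scale-free: it adapts to the cohort's own
#' distance scale.
#'
#' @param cohort an [expression_cohort()] with at least 2 cells.
#' @param rel_threshold fraction of the median pairwise distance below
#'   which a pair counts as duplicated (default 0.05).
#' @return A list with `cohort` and `report`, as in
#'   [remove_outlier_cells()]; the reported distance is each cell's
#'   nearest-neighbour distance.
#' @export
remove_near_duplicate_cells <- function(cohort, rel_threshold = 0.05) {
  cohort <- as_cohort(cohort)
  x <- cohort$values
  m <- ncol(x)
  if (m < 2) stop("need at least 2 cells", call. = FALSE)
  d <- as.matrix(dist(t(x)))
  med <- median(d[upper.tri(d)])
  cutoff <- rel_threshold * med
  removed <- logical(m)
  for (j in seq_len(m - 1)) {
    if (removed[j]) next
    close_later <- which(d[j, ] < cutoff)
    close_later <- close_later[close_later > j]
    removed[close_later] <- TRUE
  }
  out <- which(removed)
  diag(d) <- Inf
  report <- filter_report(cohort$cell_ids, out, "near_duplicate",
                          apply(d, 1, min),
                          c(rel_threshold = rel_threshold, cutoff = cutoff))
  kept <- if (length(out)) cohort$values[, -out, drop = FALSE] else
    cohort$values
  list(cohort = expression_cohort(kept), report = report)
}

#' Write a filter report to CSV
#'
#' @param report a `filter_report` from one of the cell filters.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
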