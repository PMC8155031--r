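# Fixtures built in code. All stochastic fixtures take an explicit seed.

# i.i.d. standard-uniform noise cohort (no coordination).
make_iid_cohort <- function(n_genes, n_cells, seed) {
  gclsim:::with_seed(seed,
    expression_cohort(matrix(runif(n_genes * n_cells), n_genes, n_cells)))
}

# Perfectly coordinated cohort: every gene's value in cell v equals a
# cell-specific scalar s_v, so any two gene-subset views have
# proportional distance geometry.
make_coordinated_cohort <- function(n_genes, n_cells) {
  s <- seq_len(n_cells)
  expression_cohort(matrix(rep(s, each = n_genes), n_genes, n_cells))
}

# Single-gene self-loop model with weight w (analytic fixed points:
# x* = w - 1 for w > 1, else 0, at B = 1, n = 1).
single_gene_model <- function(w) {
  structure(list(weights = matrix(w, 1, 1), degradation = 1,
                 hill_exponent = 1, weight_low = 0, weight_high = 2),
            class = "grn_model")
}

# Small interacting study spec used across tests.
small_spec <- function(...) {
  args <- list(...)
  do.call(cohort_spec, modifyList(
    list(n_genes = 40, n_cells = 20, heterogeneity = 0.5), args))
}

# Brute-force oracles -------------------------------------------------

# Per-pair loop Euclidean distances.
loop_distances <- function(x) {
  n <- nrow(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- sqrt(sum((x[i, ] - x[j, ])^2))
  d
}

# Element-wise U-centering by explicit loops.
loop_u_center <- function(d) {
  n <- nrow(d)
  u <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    u[i, j] <- d[i, j] - sum(d[i, ]) / (n - 2) - sum(d[, j]) / (n - 2) +
      sum(d) / ((n - 1) * (n - 2))
  }
  u
}

# From-scratch bias-corrected distance correlation via the loop oracles.
loop_bcd_corr <- function(a, b) {
  n <- nrow(a)
  ua <- loop_u_center(loop_distances(a))
  ub <- loop_u_center(loop_distances(b))
  ip <- function(u, v) {
    s <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
      s <- s + u[i, j] * v[i, j]
    s / (n * (n - 3))
  }
  ip(ua, ub) / sqrt(ip(ua, ua) * ip(ub, ub))
}

# Naive double-centered (biased) distance correlation, for the contrast
# test under independence.
naive_dcorr <- function(a, b) {
  dc <- function(d) {
    sweep(sweep(d, 1, rowMeans(d)), 2, colMeans(d)) + mean(d)
  }
  da <- dc(loop_distances(a))
  db <- dc(loop_distances(b))
  sum(da * db) / sqrt(sum(da * da) * sum(db * db))
}

# Pair-loop cell-to-cell variability.
loop_variability <- function(x) {
  m <- ncol(x)
  tot <- 0
  for (i in seq_len(m - 1)) for (j in (i + 1):m)
    tot <- tot + (1 - cor(x[, i], x[, j], method = "spearman"))
  tot / (m * (m - 1) / 2)
}

# Pair-loop average absolute gene co-expression.
loop_coexpression <- function(x) {
  n <- nrow(x)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + abs(cor(x[i, ], x[j, ], method = "spearman"))
  tot / (n * (n - 1) / 2)
}
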