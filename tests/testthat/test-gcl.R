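test_that("split_genes yields disjoint balanced halves, uniformly", {
  sp <- gclsim:::with_seed(1, split_genes(200))
  expect_length(sp$part_a, 100)
  expect_length(sp$part_b, 100)
  expect_length(intersect(sp$part_a, sp$part_b), 0)

  # odd N: one gene left out of both parts
  sp3 <- gclsim:::with_seed(1, split_genes(9))
  expect_length(sp3$part_a, 4)
  expect_length(sp3$part_b, 4)
  expect_length(union(sp3$part_a, sp3$part_b), 8)

  # n = 2: the only split up to labeling
  sp2 <- gclsim:::with_seed(1, split_genes(2))
  expect_setequal(c(sp2$part_a, sp2$part_b), 1:2)

  expect_error(split_genes(1), "at least 2")

  # each gene lands in part_a with frequency ~ 1/2
  counts <- integer(10)
  gclsim:::with_seed(99, for (k in 1:10000) {
    counts[split_genes(10)$part_a] <- counts[split_genes(10)$part_a] + 1L
  })
  expect_true(all(abs(counts / 10000 - 0.5) < 0.02))
})

test_that("GCL is 1 for perfectly coordinated cohorts and averages splits", {
  # amplitude coordination is exact under normalize = "none"; the
  # default treats a pure per-cell scale as non-signal
  co <- make_coordinated_cohort(12, 8)
  res <- compute_gcl(co, m = 7, seed = 5, normalize = "none")
  expect_equal(res$gcl, 1, tolerance = 1e-12)
  expect_equal(res$gcl, mean(res$per_split))
  expect_length(res$per_split, 7)
  expect_true(all(res$per_split >= -1 & res$per_split <= 1))
})

test_that("default GCL is invariant to per-cell amplitude factors", {
  co <- simulate_cohort(small_spec(seed = 19))
  scales <- gclsim:::with_seed(20, runif(20, 0.2, 5))
  scaled <- sweep(co$values, 2, scales, "*")
  r1 <- compute_gcl(co, m = 10, seed = 6)
  r2 <- compute_gcl(scaled, m = 10, seed = 6)
  expect_equal(r2$per_split, r1$per_split, tolerance = 1e-10)
  # a cohort that is nothing but a shared amplitude is degenerate under
  # the default: every normalized view collapses to one point
  flat <- make_coordinated_cohort(12, 8)
  expect_warning(r3 <- compute_gcl(flat, m = 1, seed = 7), "degenerate")
  expect_equal(r3$gcl, 0)
})

test_that("GCL input validation", {
  expect_error(compute_gcl(matrix(1:6, 1, 6)), "at least 2 genes")
  expect_error(compute_gcl(matrix(runif(30), 10, 3)), "at least 4 cells")
  expect_error(compute_gcl(make_iid_cohort(10, 10, 1), m = 0), ">= 1")
})

test_that("GCL is reproducible and invariant to cell order", {
  co <- make_iid_cohort(30, 12, seed = 8)
  r1 <- compute_gcl(co, m = 15, seed = 21)
  r2 <- compute_gcl(co, m = 15, seed = 21)
  expect_identical(r1$per_split, r2$per_split)

  perm <- gclsim:::with_seed(3, sample(12))
  r3 <- compute_gcl(co$values[, perm], m = 15, seed = 21)
  expect_equal(r3$per_split, r1$per_split, tolerance = 1e-12)
})

test_that("gene order only relabels the split space", {
  # across seeds, GCL distributions before/after a gene permutation agree
  co <- simulate_cohort(small_spec(seed = 31))
  perm <- gclsim:::with_seed(4, sample(40))
  g1 <- vapply(1:25, function(s) compute_gcl(co, m = 8, seed = s)$gcl,
               numeric(1))
  g2 <- vapply(1:25, function(s)
    compute_gcl(co$values[perm, ], m = 8, seed = 1000 + s)$gcl, numeric(1))
  expect_gt(suppressWarnings(ks.test(g1, g2)$p.value), 0.01)
})

test_that("GCL of i.i.d. noise is statistically zero", {
  co <- make_iid_cohort(60, 80, seed = 17)
  res <- compute_gcl(co, m = 40, seed = 2)
  sem <- sd(res$per_split) / sqrt(res$m)
  expect_lt(abs(res$gcl), 3 * sem + 0.02)
})

test_that("significance: coordination detected, noise calibrated, null flat", {
  co <- make_coordinated_cohort(16, 12)
  sig <- gcl_significance(co, m = 8, n_resample = 24, seed = 5,
                          normalize = "none")
  expect_equal(sig$p_value, 1 / 25)
  expect_equal(sig$observed$gcl, 1)

  # a shuffled cohort fed back in is itself null: individual p-values
  # are ~uniform, so check the median over a few shuffles
  p_sh <- vapply(1:5, function(r) {
    x <- make_iid_cohort(20, 16, seed = 9 + r)
    sh <- gclsim:::with_seed(10 + r, t(apply(x$values, 1, sample)))
    sig2 <- gcl_significance(sh, m = 8, n_resample = 24, seed = 6 + r,
                             jackknife = FALSE)
    expect_lt(abs(sig2$observed$gcl), 0.2)
    sig2$p_value
  }, numeric(1))
  expect_gt(median(p_sh), 0.1)

  expect_error(gcl_significance(make_iid_cohort(10, 4, 1)), "at least 5")
  expect_error(gcl_significance(make_iid_cohort(10, 10, 1), n_resample = 5),
               ">= 20")
})

test_that("significance rejection rate under the null is calibrated", {
  n_rep <- 30
  pvals <- vapply(seq_len(n_rep), function(r) {
    co <- make_iid_cohort(16, 12, seed = 300 + r)
    gcl_significance(co, m = 5, n_resample = 39, seed = 600 + r,
                     jackknife = FALSE)$p_value
  }, numeric(1))
  # one-sided level-0.05 test rejects ~5% of the time
  expect_lt(mean(pvals <= 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / n_rep))
})
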