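test_that("base network has self-loops, ER links and bounded weights", {
  spec <- cohort_spec(n_genes = 200, avg_degree = 2)
  net <- build_base_network(spec, seed = 1)
  w <- net$weights
  expect_true(all(diag(w) > 0))
  expect_true(all(w >= 0 & w < 2))
  # expected off-diagonal link count N * avg_degree = 400, within 4 SD
  n_links <- sum(w[row(w) != col(w)] > 0)
  sd_links <- sqrt(200 * 199 * (2 / 199) * (1 - 2 / 199))
  expect_lt(abs(n_links - 400), 4 * sd_links)

  only_self <- build_base_network(cohort_spec(n_genes = 50, avg_degree = 0),
                                  seed = 2)$weights
  expect_equal(sum(only_self[row(only_self) != col(only_self)] != 0), 0)
})

test_that("perturb_weights preserves topology and redraws at rate p", {
  base <- build_base_network(cohort_spec(n_genes = 80), seed = 3)
  expect_identical(perturb_weights(base, 0, seed = 1)$weights, base$weights)

  all_new <- perturb_weights(base, 1, seed = 4)$weights
  nz <- base$weights != 0
  expect_identical(all_new != 0, nz)
  expect_equal(sum(all_new[nz] == base$weights[nz]), 0)

  half <- perturb_weights(base, 0.5, seed = 5)$weights
  n_links <- sum(nz)
  frac_changed <- mean(half[nz] != base$weights[nz])
  expect_lt(abs(frac_changed - 0.5), 4 * sqrt(0.25 / n_links))
})

test_that("single-gene fixed points match the analytic solution", {
  # x* solves -x + w x/(1+x) = 0: x* = w - 1 for w > 1, else 0
  for (w in c(0.5, 1.5, 2)) {
    st <- steady_state(single_gene_model(w), x0 = 0.5)
    expect_equal(st$x_star, max(w - 1, 0), tolerance = 1e-5)
  }
  expect_lt(steady_state(single_gene_model(2), x0 = 0.5)$residual, 1e-6)
})

test_that("steady states agree with an independent ODE solver", {
  skip_if_not_installed("deSolve")
  for (seed in 1:4) {
    spec <- cohort_spec(n_genes = 6, avg_degree = 2, seed = seed)
    model <- build_base_network(spec, seed = seed)
    x0 <- gclsim:::with_seed(seed + 50, runif(6))
    mine <- steady_state(model, x0 = x0)$x_star
    ref <- deSolve::ode(
      y = x0, times = c(0, 2000),
      func = function(t, x, parms) {
        f <- -x + parms %*% (x / (1 + x))
        list(as.numeric(f))
      },
      parms = model$weights, method = "lsoda",
      rtol = 1e-10, atol = 1e-12)
    expect_equal(mine, as.numeric(ref[2, -1]), tolerance = 1e-4)
  }
})

test_that("inoperative genes are clamped and stop activating targets", {
  # gene 2 activates gene 1; killing gene 2 removes that input
  w <- matrix(c(0.5, 0, 2, 1.8), 2, 2)  # w[1,2] = 2: gene 1 <- gene 2
  model <- structure(list(weights = w, degradation = 1, hill_exponent = 1,
                          weight_low = 0, weight_high = 2),
                     class = "grn_model")
  st_alive <- steady_state(model, x0 = c(0.5, 0.5))
  expect_gt(st_alive$x_star[1], 0.1)
  st_dead <- steady_state(model, inoperative = 2, x0 = c(0.5, 0.5))
  expect_identical(st_dead$x_star[2], 0)
  expect_equal(st_dead$x_star[1], 0, tolerance = 1e-5)
})

test_that("cohorts carry the configured inoperative zeros", {
  spec <- cohort_spec(n_genes = 60, n_cells = 8, n_inoperative = 5,
                      seed = 21)
  co <- simulate_cohort(spec)
  expect_true(all(colSums(co$values == 0) >= 5))

  # deterministic dynamics: p = 0, no dead genes, shared x0 -> identical
  # columns
  spec0 <- cohort_spec(n_genes = 30, n_cells = 5, heterogeneity = 0,
                       n_inoperative = 0, init_low = 0.5, init_high = 0.5,
                       seed = 22)
  co0 <- simulate_cohort(spec0)
  expect_lt(max(abs(co0$values - co0$values[, 1])), 1e-5)
})

test_that("simulated cohorts are reproducible from (spec, seed)", {
  spec <- small_spec(seed = 77)
  expect_identical(simulate_cohort(spec)$values, simulate_cohort(spec)$values)
})

test_that("variability increases with heterogeneity p", {
  vr <- vapply(c(0, 0.5, 1), function(p) {
    mean(vapply(1:3, function(r) {
      co <- simulate_cohort(small_spec(heterogeneity = p,
                                       seed = 500 + 10 * r))
      suppressWarnings(cell_to_cell_variability(co))$value
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(vr) > 0))
})

test_that("measurement noise follows the multiplicative model", {
  co <- expression_cohort(matrix(10, 1, 10000))
  expect_identical(add_measurement_noise(co, 0, seed = 1)$values, co$values)

  noisy <- add_measurement_noise(co, 0.2, seed = 2)$values
  expect_lt(abs(mean(noisy) - 10), 4 * 2 / sqrt(10000))
  expect_lt(abs(sd(noisy) - 2) / 2, 0.05)

  zero <- expression_cohort(matrix(0, 5, 50))
  expect_true(all(add_measurement_noise(zero, 3, seed = 3)$values == 0))
  # flooring keeps large-noise output nonnegative
  expect_true(all(add_measurement_noise(co, 2, seed = 4)$values >= 0))
})
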