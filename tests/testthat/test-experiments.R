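# Sweeps run here at desk scale (small N, M, few realizations); the
# full study conditions are exercised in the acceptance suite.

tiny_spec <- function() cohort_spec(n_genes = 20, n_cells = 12,
                                    n_inoperative = 2)

test_that("heterogeneity sweep is tidy, seeded and reproducible", {
  tab <- run_heterogeneity_sweep(c(0, 1), tiny_spec(), n_realizations = 2,
                                 m = 4, seed = 11)
  expect_s3_class(tab, "sweep_table")
  expect_equal(nrow(tab), 4)
  expect_named(tab, c("p", "realization", "seed", "variability", "gcl",
                      "avg_coexpression"))
  tab2 <- run_heterogeneity_sweep(c(0, 1), tiny_spec(), n_realizations = 2,
                                  m = 4, seed = 11)
  expect_identical(tab, tab2)
})

test_that("p-sigma grid nests the noise-free sweep under shared seeds", {
  p_grid <- c(0.25, 0.75)
  grid <- run_p_sigma_grid(p_grid, c(0, 0.4), tiny_spec(),
                           n_realizations = 2, m = 4, seed = 12)
  het <- run_heterogeneity_sweep(p_grid, tiny_spec(), n_realizations = 2,
                                 m = 4, seed = 12)
  zero <- grid[grid$sigma == 0, names(het)]
  rownames(zero) <- NULL
  expect_equal(zero, as.data.frame(het), ignore_attr = TRUE)
  # noise moves the measurements
  expect_false(any(grid$variability[grid$sigma > 0] %in% zero$variability))
})

test_that("contour tracing recovers a closed-form level set", {
  # synthetic surface: variability = p + sigma, gcl = p; the level-0.5
  # set is the line p + sigma = 0.5 and gcl grows with log(p/sigma)
  grid <- expand.grid(p = seq(0.05, 0.95, by = 0.05),
                      sigma = seq(0.05, 0.95, by = 0.05))
  tab <- data.frame(grid, realization = 1, seed = 1,
                    variability = grid$p + grid$sigma, gcl = grid$p,
                    avg_coexpression = 0)
  trace <- trace_iso_variability(tab, 0.5)
  expect_true(all(abs(trace$p + trace$sigma - 0.5) < 1e-9))
  expect_true(all(abs(trace$variability - 0.5) < 1e-6))
  expect_equal(trace$gcl, trace$p, tolerance = 1e-9)
  expect_false(is.unsorted(trace$log_ratio))
  expect_gt(cor(trace$gcl, trace$log_ratio, method = "spearman"), 0.99)

  expect_error(trace_iso_variability(tab, 5), "outside")
})

test_that("sample-size sweep uses nested prefixes of one master cohort", {
  tab <- run_sample_size_sweep(c(12, 8, 4), tiny_spec(),
                               n_realizations = 2, m = 4, seed = 13)
  expect_equal(sort(unique(tab$n_cells)), c(4, 8, 12))
  # same master cohort per realization: seeds agree across M
  expect_equal(length(unique(tab$seed)), 2)
  tab2 <- run_sample_size_sweep(c(12, 8, 4), tiny_spec(),
                                n_realizations = 2, m = 4, seed = 13)
  expect_identical(tab, tab2)
})

test_that("compositional sweep records gamma and reproduces", {
  spec <- compositional_spec(n_genes = 25, n_cells = 12)
  tab <- run_compositional_sweep(c(1.5, 3), spec, n_realizations = 2,
                                 m = 4, seed = 14)
  expect_equal(nrow(tab), 4)
  expect_identical(tab, run_compositional_sweep(c(1.5, 3), spec,
                                                n_realizations = 2, m = 4,
                                                seed = 14))
})

test_that("sweep tables round-trip through the provenance CSV", {
  tab <- run_heterogeneity_sweep(c(0.5), tiny_spec(), n_realizations = 2,
                                 m = 3, seed = 15)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sweep_table(tab, path)
  header <- readLines(path, n = 3)
  expect_match(header[1], "^# gclsim")
  expect_match(header[2], "^# seed=15$")
  expect_match(header[3], "^# config_hash=[0-9a-f]{8}$")
  back <- read_sweep_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tab),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_identical(attr(back, "seed"), 15L)
})

test_that("config files parse into specs", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# a comment", "n_genes = 30", "n_cells = 8",
               "heterogeneity = 0.25", "interactions = FALSE",
               "p_grid = 0.1, 0.5, 0.9"), path)
  cfg <- read_config(path)
  expect_equal(cfg$p_grid, c(0.1, 0.5, 0.9))
  sp <- gclsim:::spec_from_config(cfg)
  expect_equal(sp$n_genes, 30)
  expect_false(sp$interactions)
})
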