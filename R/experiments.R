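# Orchestration of the simulation studies: parameter sweeps over the
# heterogeneity p, the measurement noise sigma, the cell count M and the
# compositional exponent gamma, each producing a tidy "sweep table" with
# one row per (parameter point x realization) carrying the cell-to-cell
# variability, the GCL and the average co-expression <C>.

sweep_row <- function(...) {
  data.frame(..., stringsAsFactors = FALSE)
}

finish_sweep <- function(rows, seed, params) {
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  attr(tab, "seed") <- seed
  attr(tab, "params") <- params
  class(tab) <- c("sweep_table", "data.frame")
  tab
}

# Per-(p, realization) cohort seeds, shared between the heterogeneity
# sweep and the p-sigma grid so the grid's sigma = 0 column reproduces
# the heterogeneity sweep under the same master seed. Each cohort seed
# spawns a fixed-length block of 64 sub-seeds: entries 2j-1 and 2j are
# the noise and split seeds of the j-th sigma level (the heterogeneity
# sweep is the j = 1, sigma = 0 level).
sigma_subseeds <- function(cohort_seed) derive_seeds(cohort_seed, 64)

measure_cohort <- function(cohort, m, split_seed) {
  vr <- suppressWarnings(cell_to_cell_variability(cohort))
  cx <- suppressWarnings(average_coexpression(cohort))
  g <- compute_gcl(cohort, m = m, seed = split_seed)
  list(variability = vr$value, gcl = g$gcl, avg_coexpression = cx$value)
}

#' Heterogeneity sweep: variability and GCL versus p
#'
#' For every heterogeneity level in `p_grid` and every realization, a
#' fresh base network and a noise-free cohort of actual profiles are
#' generated and the cell-to-cell variability, GCL and average
#' co-expression recorded. With `interactions = FALSE` the networks keep
#' only their self-regulation loops — the contrast that shows the GCL
#' responds to gene-gene interactions while the variability does not.
#'
#' @param p_grid heterogeneity values in \[0, 1\].
#' @param spec a [cohort_spec()] template (its `heterogeneity` and
#'   `interactions` fields are overridden per run).
#' @param n_realizations independent repetitions per p (default 20).
#' @param m number of gene-set splits per GCL (default 50).
#' @param interactions logical, passed into the spec.
#' @param seed master seed; every row's cohort seed derives from it.
#' @return A `sweep_table` data frame with columns `p`, `realization`,
#'   `seed`, `variability`, `gcl`, `avg_coexpression`.
#' @export
run_heterogeneity_sweep <- function(p_grid, spec = cohort_spec(),
                                    n_realizations = 20, m = 50,
                                    interactions = TRUE, seed = NULL) {
  stopifnot(all(p_grid >= 0 & p_grid <= 1))
  cohort_seeds <- derive_seeds(seed, length(p_grid) * n_realizations)
  rows <- list()
  for (i in seq_along(p_grid)) {
    for (r in seq_len(n_realizations)) {
      cseed <- cohort_seeds[(i - 1) * n_realizations + r]
      sp <- spec
      sp$heterogeneity <- p_grid[i]
      sp$interactions <- interactions
      sp$noise_sd <- 0
      cohort <- simulate_cohort(sp, seed = cseed)
      met <- measure_cohort(cohort, m, sigma_subseeds(cseed)[2])
      rows[[length(rows) + 1]] <- sweep_row(
        p = p_grid[i], realization = r, seed = cseed,
        variability = met$variability, gcl = met$gcl,
        avg_coexpression = met$avg_coexpression)
    }
  }
  finish_sweep(rows, seed, list(p_grid = p_grid, m = m,
                                n_realizations = n_realizations,
                                interactions = interactions))
}

#' Full factorial sweep over heterogeneity and measurement noise
#'
#' Simulates, for each realization and each p, one cohort of actual
#' profiles, then overlays every noise level sigma on it, so the
#' biological and technical axes are varied independently. Records
#' variability, GCL and average co-expression per (p, sigma,
#' realization).
#'
#' When `sigma_grid[1] == 0` and the master seed matches, the sigma = 0
#' rows coincide with [run_heterogeneity_sweep()] on the same `p_grid`.
#'
#' @param p_grid,sigma_grid parameter grids (sigma >= 0; at most 32
#'   sigma levels).
#' @inheritParams run_heterogeneity_sweep
#' @return A `sweep_table` with columns `p`, `sigma`, `realization`,
#'   `seed`, `variability`, `gcl`, `avg_coexpression`.
#' @export
run_p_sigma_grid <- function(p_grid, sigma_grid, spec = cohort_spec(),
                             n_realizations = 20, m = 50, seed = NULL) {
  stopifnot(all(p_grid >= 0 & p_grid <= 1), all(sigma_grid >= 0),
            length(sigma_grid) <= 32)
  cohort_seeds <- derive_seeds(seed, length(p_grid) * n_realizations)
  rows <- list()
  for (i in seq_along(p_grid)) {
    for (r in seq_len(n_realizations)) {
      cseed <- cohort_seeds[(i - 1) * n_realizations + r]
      sp <- spec
      sp$heterogeneity <- p_grid[i]
      sp$noise_sd <- 0
      actual <- simulate_cohort(sp, seed = cseed)
      sub <- sigma_subseeds(cseed)
      for (j in seq_along(sigma_grid)) {
        measured <- if (sigma_grid[j] > 0)
          add_measurement_noise(actual, sigma_grid[j],
                                seed = sub[2 * j - 1]) else actual
        met <- measure_cohort(measured, m, sub[2 * j])
        rows[[length(rows) + 1]] <- sweep_row(
          p = p_grid[i], sigma = sigma_grid[j], realization = r,
          seed = cseed, variability = met$variability, gcl = met$gcl,
          avg_coexpression = met$avg_coexpression)
      }
    }
  }
  finish_sweep(rows, seed, list(p_grid = p_grid, sigma_grid = sigma_grid,
                                m = m, n_realizations = n_realizations))
}

#' Trace an iso-variability contour through the (p, sigma) plane
#'
#' Locates the level set of the realization-mean variability surface of a
#' [run_p_sigma_grid()] table by marching squares on the grid (linear
#' interpolation along cell edges), interpolates the realization-mean GCL
#' bilinearly at the traced points, and orders the points by the
#' biological-to-technical log-ratio log(p / sigma). Points with sigma or
#' p equal to 0 (log-ratio undefined) are dropped from the trace.
#'
#' @param table a `sweep_table` from [run_p_sigma_grid()].
#' @param level variability level to trace; must lie inside the observed
#'   range of the mean-variability surface.
#' @return A data frame of class `contour_trace` with columns `p`,
#'   `sigma`, `log_ratio`, `gcl`, `variability` (the interpolated surface
#'   value at each point, equal to `level` up to interpolation
#'   tolerance), ordered by increasing `log_ratio`.
#' @export
trace_iso_variability <- function(table, level) {
  stopifnot(is.data.frame(table),
            all(c("p", "sigma", "variability", "gcl") %in% names(table)))
  p_grid <- sort(unique(table$p))
  s_grid <- sort(unique(table$sigma))
  if (length(p_grid) < 2 || length(s_grid) < 2)
    stop("need at least a 2 x 2 grid to trace a contour", call. = FALSE)
  mean_surface <- function(col) {
    fi <- factor(match(table$p, p_grid), levels = seq_along(p_grid))
    fj <- factor(match(table$sigma, s_grid), levels = seq_along(s_grid))
    z <- tapply(table[[col]], list(fi, fj), mean)
    matrix(as.numeric(z), length(p_grid), length(s_grid))
  }
  zv <- mean_surface("variability")
  zg <- mean_surface("gcl")
  if (anyNA(zv)) stop("incomplete grid: missing (p, sigma) cells",
                      call. = FALSE)
  if (level <= min(zv) || level >= max(zv))
    stop(sprintf("level %g outside the observed variability range [%g, %g]",
                 level, min(zv), max(zv)), call. = FALSE)
  pts <- level_crossings(p_grid, s_grid, zv, level)
  if (!nrow(pts)) stop("no contour found at this level", call. = FALSE)
  pts <- pts[pts$p > 0 & pts$sigma > 0, , drop = FALSE]
  if (!nrow(pts))
    stop("contour lies entirely on the p = 0 or sigma = 0 boundary",
         call. = FALSE)
  # interp2 interpolates Z indexed as (y = rows, x = columns)
  pts$gcl <- pracma::interp2(x = p_grid, y = s_grid, Z = t(zg),
                             xp = pts$p, yp = pts$sigma)
  pts$variability <- pracma::interp2(x = p_grid, y = s_grid, Z = t(zv),
                                     xp = pts$p, yp = pts$sigma)
  pts$log_ratio <- log(pts$p / pts$sigma)
  pts <- pts[order(pts$log_ratio), c("p", "sigma", "log_ratio", "gcl",
                                     "variability")]
  rownames(pts) <- NULL
  attr(pts, "level") <- level
  class(pts) <- c("contour_trace", "data.frame")
  pts
}

#' Sample-size sweep: statistic stability under fewer cells
#'
#' Per realization, one master cohort of `max(m_grid)` cells is simulated
#' (default study conditions p = 0.5, sigma = 0) and its first-M-cells
#' subsets are evaluated for every M in `m_grid`, isolating the
#' sample-size effect: the average co-expression inflates as M shrinks
#' while the GCL stays comparatively stable. Subsets are nested by
#' construction.
#'
#' @param m_grid cell counts (all >= 4); the master cohort has
#'   `max(m_grid)` cells.
#' @param spec a [cohort_spec()] template; its `n_cells` is overridden by
#'   `max(m_grid)` and `heterogeneity` defaults to 0.5 unless already set
#'   nonzero.
#' @inheritParams run_heterogeneity_sweep
#' @return A `sweep_table` with columns `n_cells`, `realization`, `seed`,
#'   `variability`, `gcl`, `avg_coexpression`.
#' @export
run_sample_size_sweep <- function(m_grid, spec = cohort_spec(
                                    heterogeneity = 0.5, n_cells = 150),
                                  n_realizations = 20, m = 50, seed = NULL) {
  stopifnot(all(m_grid >= 4))
  m_grid <- sort(unique(m_grid), decreasing = TRUE)
  cohort_seeds <- derive_seeds(seed, n_realizations)
  rows <- list()
  for (r in seq_len(n_realizations)) {
    cseed <- cohort_seeds[r]
    sp <- spec
    sp$n_cells <- max(m_grid)
    sp$noise_sd <- 0
    master <- simulate_cohort(sp, seed = cseed)
    sub <- sigma_subseeds(cseed)
    for (j in seq_along(m_grid)) {
      cohort <- subset_cells(master, seq_len(m_grid[j]))
      met <- measure_cohort(cohort, m, sub[2 * j])
      rows[[length(rows) + 1]] <- sweep_row(
        n_cells = m_grid[j], realization = r, seed = cseed,
        variability = met$variability, gcl = met$gcl,
        avg_coexpression = met$avg_coexpression)
    }
  }
  finish_sweep(rows, seed, list(m_grid = m_grid, m = m,
                                n_realizations = n_realizations))
}

#' Compositional sweep: spurious correlation versus heterogeneity
#'
#' Per power-law exponent gamma and realization, a compositional null
#' cohort (no true gene-to-gene coordination) is generated and measured.
#' The average co-expression inflates as gamma approaches 1 (heavier
#' tails, stronger compositional distortion) while the GCL stays at
#' zero.
#'
#' @param gamma_grid power-law exponents, all > 1.
#' @param spec a [compositional_spec()] template (its `exponent` is
#'   overridden per run).
#' @inheritParams run_heterogeneity_sweep
#' @return A `sweep_table` with columns `gamma`, `realization`, `seed`,
#'   `variability`, `gcl`, `avg_coexpression`.
#' @export
run_compositional_sweep <- function(gamma_grid, spec = compositional_spec(),
                                    n_realizations = 20, m = 50,
                                    seed = NULL) {
  stopifnot(all(gamma_grid > 1))
  cohort_seeds <- derive_seeds(seed, length(gamma_grid) * n_realizations)
  rows <- list()
  for (i in seq_along(gamma_grid)) {
    for (r in seq_len(n_realizations)) {
      cseed <- cohort_seeds[(i - 1) * n_realizations + r]
      sp <- spec
      sp$exponent <- gamma_grid[i]
      cohort <- generate_compositional_cohort(sp, seed = cseed)
      met <- measure_cohort(cohort, m, sigma_subseeds(cseed)[2])
      rows[[length(rows) + 1]] <- sweep_row(
        gamma = gamma_grid[i], realization = r, seed = cseed,
        variability = met$variability, gcl = met$gcl,
        avg_coexpression = met$avg_coexpression)
    }
  }
  finish_sweep(rows, seed, list(gamma_grid = gamma_grid, m = m,
                                n_realizations = n_realizations))
}

# Marching-squares level extraction without the level fuzzing that
# grDevices::contourLines applies (it perturbs the level by ~1e-3 of the
# z range when it hits grid nodes, which breaks the interpolation
# contract). Finds every linear crossing of `level` along the grid-cell
# edges; the trace is later ordered by log(p/sigma), so segment
# connectivity is not needed.
level_crossings <- function(p_grid, s_grid, z, level) {
  pts <- list()
  edge_cross <- function(c1, c2, z1, z2) {
    # returns interpolation fraction in [0, 1], or NA when no crossing
    if ((z1 - level) * (z2 - level) > 0) return(NA_real_)
    if (z1 == z2) return(if (z1 == level) 0 else NA_real_)
    t <- (level - z1) / (z2 - z1)
    if (t < 0 || t > 1) NA_real_ else t
  }
  for (j in seq_along(s_grid)) for (i in seq_len(length(p_grid) - 1)) {
    t <- edge_cross(p_grid[i], p_grid[i + 1], z[i, j], z[i + 1, j])
    if (!is.na(t))
      pts[[length(pts) + 1]] <- c(p_grid[i] + t * (p_grid[i + 1] - p_grid[i]),
                                  s_grid[j])
  }
  for (i in seq_along(p_grid)) for (j in seq_len(length(s_grid) - 1)) {
    t <- edge_cross(s_grid[j], s_grid[j + 1], z[i, j], z[i, j + 1])
    if (!is.na(t))
      pts[[length(pts) + 1]] <- c(p_grid[i],
                                  s_grid[j] + t * (s_grid[j + 1] - s_grid[j]))
  }
  if (!length(pts)) return(data.frame(p = numeric(0), sigma = numeric(0)))
  m <- do.call(rbind, pts)
  m <- m[!duplicated(round(m, 12)), , drop = FALSE]
  data.frame(p = m[, 1], sigma = m[, 2])
}

# Polynomial rolling hash (mod 2^31 - 1) of a string; stamps a short
# config fingerprint into sweep-table headers.
config_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write a sweep table to CSV with provenance header
#'
#' Prepends `#`-comment lines recording the package version, the master
#' seed and a fingerprint of the run configuration, so reruns can be
#' verified byte-for-byte.
#'
#' @param table a `sweep_table`.
#' @param path output CSV path.
#' @param config optional named list echoed into the fingerprint
#'   (defaults to the table's recorded parameters).
#' @return `path`, invisibly.
#' @export
write_sweep_table <- function(table, path, config = attr(table, "params")) {
  seed <- attr(table, "seed")
  cfg <- paste(names(unlist(config)), unlist(config), sep = "=",
               collapse = ";")
  header <- c(
    paste0("# gclsim ", as.character(utils::packageVersion("gclsim"))),
    paste0("# seed=", if (is.null(seed)) "NA" else seed),
    paste0("# config_hash=", config_hash(cfg)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(as.data.frame(table), con, row.names = FALSE)
  invisible(path)
}

#' Read a sweep table written by [write_sweep_table()]
#'
#' @param path CSV path.
#' @return A `sweep_table` data frame; the header seed is restored into
#'   the `"seed"` attribute.
#' @export
read_sweep_table <- function(path) {
  header <- readLines(path, n = 3)
  tab <- utils::read.csv(path, comment.char = "#")
  seed_line <- grep("^# seed=", header, value = TRUE)
  if (length(seed_line)) {
    seed <- sub("^# seed=", "", seed_line[1])
    attr(tab, "seed") <- if (seed == "NA") NULL else as.integer(seed)
  }
  class(tab) <- c("sweep_table", "data.frame")
  tab
}
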