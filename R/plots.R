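# Plotting companions to the sweep tables. Tables are the quantitative
# surface; these figures are conveniences for eyeballing the trends.

#' Plot a sweep table: realization mean and SD versus a parameter
#'
#' @param table a `sweep_table`.
#' @param x name of the parameter column (`"p"`, `"gamma"`, `"n_cells"`,
#'   ...).
#' @param y name of the metric column (default `"gcl"`).
#' @return A ggplot object.
#' @export
plot_sweep <- function(table, x, y = "gcl") {
  stopifnot(x %in% names(table), y %in% names(table))
  agg <- aggregate(table[[y]], list(param = table[[x]]),
                   function(v) c(mean = mean(v), sd = sd(v)))
  df <- data.frame(param = agg$param, mean = agg$x[, "mean"],
                   sd = agg$x[, "sd"])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$param, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = x, y = y) +
    ggplot2::theme_minimal()
}

#' Heat map of a metric over the (p, sigma) grid
#'
#' @param table a `sweep_table` from [run_p_sigma_grid()].
#' @param y metric column to map (default `"variability"`).
#' @return A ggplot object with contour lines overlaid.
#' @export
plot_grid_heatmap <- function(table, y = "variability") {
  stopifnot(all(c("p", "sigma", y) %in% names(table)))
  agg <- aggregate(table[[y]], list(p = table$p, sigma = table$sigma), mean)
  names(agg)[3] <- "value"
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$p, y = .data$sigma,
                                    fill = .data$value,
                                    z = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_contour(colour = "black", linetype = "dashed") +
    ggplot2::scale_fill_viridis_c(name = y) +
    ggplot2::theme_minimal()
}

#' Plot the GCL along an iso-variability contour
#'
#' @param trace a `contour_trace` from [trace_iso_variability()].
#' @return A ggplot object of GCL versus log(p / sigma).
#' @export
plot_contour_trace <- function(trace) {
  stopifnot(inherits(trace, "contour_trace"))
  ggplot2::ggplot(trace, ggplot2::aes(x = .data$log_ratio, y = .data$gcl)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "log(p / sigma)", y = "GCL",
                  title = sprintf("iso-variability level %.3g",
                                  attr(trace, "level"))) +
    ggplot2::theme_minimal()
}
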