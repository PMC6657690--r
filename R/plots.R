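# ggplot2 helpers for the tabular results.

#' Plot mean separation sensitivity by cluster size
#'
#' @param report an `fs_report` from [evaluate_pipelines()] / [run_compare()].
#' @return a ggplot object.
#' @export
plot_sensitivity <- function(report) {
  stopifnot(inherits(report, "fs_report"))
  df <- report$sensitivity_by_size
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$n),
                                   y = .data$mean_sensitivity,
                                   fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "reference cluster size n",
                  y = "mean separation sensitivity", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot fibre-area density curves
#'
#' @param areas_list named list of area vectors (px^2), e.g. groundtruth
#'   and per-pipeline reconstructed areas.
#' @param bin_size,bandwidth_factor passed to [area_density()].
#' @return a ggplot object.
#' @export
plot_area_density <- function(areas_list, bin_size = 800,
                              bandwidth_factor = 0.2) {
  dfs <- lapply(names(areas_list), function(nm) {
    d <- area_density(areas_list[[nm]], bin_size, bandwidth_factor)
    d$source <- nm
    d
  })
  df <- dplyr::bind_rows(dfs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$area, y = .data$density,
                                   colour = .data$source)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "fibre area (px²)", y = "density", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot KL-divergence curves over histogram bin sizes
#'
#' @param report an `fs_report` with a `kl` table.
#' @return a ggplot object.
#' @export
plot_kl_curves <- function(report) {
  stopifnot(inherits(report, "fs_report"))
  ggplot2::ggplot(report$kl, ggplot2::aes(x = .data$bin_size, y = .data$kl,
                                          colour = .data$method)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "histogram bin size (px²)",
                  y = "KL divergence from groundtruth areas",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
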