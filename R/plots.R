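#' Boxplot of spread distances by group
#'
#' The spread figure: pooled nearest-positive-voxel distances per group,
#' shorter distances meaning higher tracer spread.
#'
#' @param samples a tibble as from [distance_sample()].
#' @return a ggplot object.
#' @export
plot_spread <- function(samples) {
  ggplot2::ggplot(samples,
                  ggplot2::aes(x = .data$group, y = .data$distance_um)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.2) +
    ggplot2::labs(x = NULL, y = "distance to nearest positive voxel (µm)",
                  caption = "shorter distances = higher tracer spread") +
    ggplot2::theme_minimal()
}

#' Point chart of hemisphere-split positive-voxel counts
#'
#' @param counts tibble with columns `brain_id`, `group`, `ipsi`, `contra`.
#' @return a ggplot object.
#' @export
plot_hemisphere_counts <- function(counts) {
  long <- counts |>
    dplyr::select("brain_id", "group", "ipsi", "contra") |>
    tidyr::pivot_longer(c("ipsi", "contra"), names_to = "hemisphere",
                        values_to = "positive_voxels")
  ggplot2::ggplot(long, ggplot2::aes(x = interaction(.data$group,
                                                     .data$hemisphere),
                                     y = .data$positive_voxels,
                                     shape = .data$brain_id)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::stat_summary(ggplot2::aes(group = 1), fun = mean,
                          geom = "crossbar", width = 0.4, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "positive voxels") +
    ggplot2::theme_minimal()
}

#' Display a maximum projection
#'
#' @param mat numeric matrix from [maximum_projection()].
#' @return a ggplot object (raster heat map; row 1 at the top).
#' @export
plot_projection <- function(mat) {
  df <- expand.grid(row = seq_len(nrow(mat)), col = seq_len(ncol(mat)))
  df$value <- as.vector(mat)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' @export
autoplot.spread_summary <- function(object, ...) {
  ggplot2::ggplot(object$by_group,
                  ggplot2::aes(x = .data$group)) +
    ggplot2::geom_boxplot(ggplot2::aes(ymin = .data$min, lower = .data$q25,
                                       middle = .data$median,
                                       upper = .data$q75, ymax = .data$max),
                          stat = "identity") +
    ggplot2::labs(x = NULL, y = "distance (µm)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
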