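#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_tile geom_line
#'   geom_histogram geom_vline geom_abline geom_point facet_wrap labs
#'   scale_fill_viridis_c coord_equal theme_minimal after_stat
NULL

#' Plot a raster stack as tiled maps
#'
#' @param object A [raster_stack()].
#' @param layers Layers to draw (default: all).
#' @param ... Unused.
#' @return A ggplot: one facet per layer, cells colored by value.
#' @export
autoplot.raster_stack <- function(object, layers = NULL, ...) {
  layers <- layers %||% names(object$layers)
  df <- as_tibble(select_layers(object, layers), drop_na = FALSE)
  long <- tidyr::pivot_longer(df, dplyr::all_of(layers),
                              names_to = "layer", values_to = "value")
  ggplot(long, aes(x = .data$lon, y = .data$lat, fill = .data$value)) +
    geom_raster() +
    facet_wrap(~layer) +
    scale_fill_viridis_c(na.value = "grey90") +
    coord_equal() +
    labs(x = "longitude", y = "latitude", fill = NULL) +
    theme_minimal()
}

#' Plot a niche density grid in PCA space
#'
#' @param object A [density_grid()] result.
#' @param grid Which grid to draw: `"occ_corrected"` (default),
#'   `"occ_density"` or `"env_density"`.
#' @param ... Unused.
#' @return A ggplot of the density over the two PCA axes.
#' @export
autoplot.niche_density <- function(object,
                                   grid = c("occ_corrected", "occ_density",
                                            "env_density"), ...) {
  grid <- match.arg(grid)
  df <- tibble(
    axis1 = rep(object$axis1, times = object$R),
    axis2 = rep(object$axis2, each = object$R),
    density = as.vector(object[[grid]]))
  ggplot(df, aes(x = .data$axis1, y = .data$axis2, fill = .data$density)) +
    geom_raster() +
    scale_fill_viridis_c() +
    labs(x = "PCA axis 1", y = "PCA axis 2", fill = grid) +
    theme_minimal()
}

#' Plot a permutation null distribution with the observed overlap
#'
#' @param object An `overlap_test`.
#' @param bins Histogram bin count (default 20).
#' @param ... Unused.
#' @return A ggplot histogram of null D values with the observed D marked.
#' @export
autoplot.overlap_test <- function(object, bins = 20, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$null_d)) +
    geom_histogram(bins = bins, fill = "grey70", color = "white") +
    geom_vline(xintercept = object$d_obs, color = "red", linewidth = 1) +
    labs(x = "Schoener's D (null replicates)", y = "count",
         title = sprintf("%s test%s: D = %.4f, p = %.4f (%s)",
                         object$kind,
                         if (is.null(object$direction)) "" else
                           paste0(" ", object$direction),
                         object$d_obs, object$p_value, object$verdict)) +
    theme_minimal()
}

#' Plot the ROC curve of a model evaluation
#'
#' @param object A `maxent_eval`.
#' @param ... Unused.
#' @return A ggplot of the ROC curve with the chance diagonal.
#' @export
autoplot.maxent_eval <- function(object, ...) {
  ggplot(object$roc, aes(x = .data$fpr, y = .data$tpr)) +
    geom_line(color = "steelblue", linewidth = 1) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    labs(x = "false positive rate (1 - specificity)",
         y = "true positive rate (sensitivity)",
         title = sprintf("AUC = %.4f, TSS = %.4f", object$auc, object$tss)) +
    theme_minimal()
}
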