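#' Plot layer profiles
#'
#' Layer-wise metric means (pial to WM) as lines per ROI, faceted by metric —
#' the standard way to inspect how FA rises and diffusivity falls with
#' cortical depth.
#'
#' @param profiles LayerProfile tibble (one subject, or pass a pre-filtered
#'   subset).
#' @param metrics metrics to show (default: all present).
#' @return a ggplot object.
#' @export
plot_layer_profile <- function(profiles, metrics = unique(profiles$metric)) {
  df <- dplyr::filter(profiles, .data$metric %in% metrics,
                      is.finite(.data$value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$layer, y = .data$value,
                                   colour = factor(.data$roi),
                                   group = interaction(.data$roi, .data$subject))) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::scale_x_continuous(breaks = sort(unique(df$layer)),
                                labels = roman_layers(sort(unique(df$layer)))) +
    ggplot2::labs(x = "cortical layer (pial to WM)", y = "mean value",
                  colour = "ROI") +
    ggplot2::theme_minimal()
}

#' Plot per-layer stain density profiles
#'
#' @param density DensityProfile tibble from [layer_density()].
#' @return a ggplot object.
#' @export
plot_density_profile <- function(density) {
  ggplot2::ggplot(density, ggplot2::aes(x = .data$layer, y = .data$fraction,
                                        colour = .data$stain,
                                        group = interaction(.data$slide, .data$stain))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = sort(unique(density$layer)),
                                labels = roman_layers(sort(unique(density$layer)))) +
    ggplot2::labs(x = "cortical layer (pial to WM)",
                  y = "positive-pixel fraction") +
    ggplot2::theme_minimal()
}

#' Heatmap of group-test statistics across ROIs and layers
#'
#' @param stat_results StatResult tibble from [group_ttest()]
#'   (`scope == "roi_layer"` rows are shown).
#' @param metric metric to display.
#' @return a ggplot object.
#' @export
plot_stat_heatmap <- function(stat_results, metric = "MD") {
  df <- dplyr::filter(stat_results, .data$scope == "roi_layer",
                      .data$metric == !!metric)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$layer, y = .data$roi,
                                   fill = .data$t)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(.data$q < 0.05, "*", "")
    ), size = 5) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", high = "#B2182B",
                                  mid = "white", midpoint = 0) +
    ggplot2::labs(x = "cortical layer", y = "ROI", fill = "t",
                  title = paste0(metric, ": group t (BH-significant cells starred)")) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_stage_lmm Coefficient forest plot per layer.
#' @param object a `stage_lmm` object.
#' @export
autoplot.stage_lmm <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = .data$estimate - 1.96 * .data$se,
      xmax = .data$estimate + 1.96 * .data$se
    ), height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~layer, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "coefficient", y = NULL,
                  title = paste("Stage model:", object$metric)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
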