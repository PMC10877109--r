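# ggplot2 views of the main result types.

#' Plot an RGB raster (slide or painted label map)
#'
#' @param img RGB array `(rows, cols, 3)`, e.g. from
#'   [reconstruct_label_map()].
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_slide_raster <- function(img, title = NULL) {
  d <- dim(img)
  ggplot2::ggplot() +
    ggplot2::annotation_raster(
      grDevices::as.raster(clamp(img)),
      xmin = 0, xmax = d[2], ymin = 0, ymax = d[1]
    ) +
    ggplot2::xlim(0, d[2]) +
    ggplot2::ylim(0, d[1]) +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' Pie charts of per-slide cluster composition
#'
#' One pie per slide, showing its tumour-tile proportions per cluster —
#' the slide-level view used to compare model contingents against
#' pathology and immunohistochemistry.
#'
#' @param reports Tibble from [compute_slide_proportions()] (optionally
#'   after [predict_major_contingent()]).
#' @param colours Cluster fill colours.
#' @return A ggplot object faceted by slide.
#' @export
plot_slide_composition <- function(reports,
                                   colours = c("#2e9e4f", "#2b6fb3", "#e8a33d", "#8c4fb0")) {
  long <- tibble(
    slide_id = rep(reports$slide_id, ncol(reports$proportion)),
    cluster = factor(rep(colnames(reports$proportion), each = nrow(reports))),
    proportion = as.vector(reports$proportion)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = "", y = .data$proportion, fill = .data$cluster)) +
    ggplot2::geom_col(width = 1, colour = "white", linewidth = 0.2) +
    ggplot2::coord_polar(theta = "y") +
    ggplot2::facet_wrap(~slide_id) +
    ggplot2::scale_fill_manual(values = colours, name = "Cluster") +
    ggplot2::theme_void()
}

#' Training curves of the weak classifier
#'
#' @param object A `histo_cnn` model.
#' @param ... Unused.
#' @return A ggplot of per-epoch train/validation accuracy and loss.
#' @export
autoplot.histo_cnn <- function(object, ...) {
  long <- object$report |>
    tidyr::pivot_longer(
      c("train_loss", "train_accuracy", "val_loss", "val_accuracy"),
      names_to = c("set", "metric"), names_sep = "_"
    )
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$value, colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Reduced-feature scatter coloured by cluster
#'
#' @param object A `histo_gmm` fit.
#' @param reduced Reduced features (matrix or feature tibble) to project;
#'   the first two dimensions are shown.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.histo_gmm <- function(object, reduced, ...) {
  a <- assign_clusters(object, reduced)
  x <- if (is.data.frame(reduced)) reduced$feature else as.matrix(reduced)
  df <- tibble(
    dim1 = x[, 1],
    dim2 = if (ncol(x) > 1) x[, 2] else 0,
    cluster = factor(a$cluster_id)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2, colour = .data$cluster)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::labs(x = "Component 1", y = "Component 2", colour = "Cluster") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
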