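# ggplot2 visualizations for the main result types

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bland-Altman plot
#'
#' @param object A [bland_altman()] result.
#' @param ... Unused.
#' @return A ggplot: per-pair mean vs difference with bias and limits of
#'   agreement.
#' @export
autoplot.bland_altman <- function(object, ...) {
  df <- tibble::tibble(mean = object$means, diff = object$diffs)
  ggplot2::ggplot(df, ggplot2::aes(x = mean, y = diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$bias, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = object$loa, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "Mean of methods", y = "Difference (manual - automatic)",
                  title = sprintf("Bias %.2f, LoA [%.2f, %.2f]",
                                  object$bias, object$loa[1], object$loa[2])) +
    ggplot2::theme_minimal()
}

#' Plot a phantom case slice
#'
#' Intensity raster with the multiclass labels overlaid.
#'
#' @param object A `phantom_case`.
#' @param slice Slice index (default: middle slice).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.phantom_case <- function(object, slice = NULL, ...) {
  d <- dim(object$image$voxels)
  if (is.null(slice)) slice <- middle_slice_index(d[1])
  img <- object$image$voxels[slice, , ]
  lab <- object$labels$labels[slice, , ]
  df <- tibble::tibble(row = rep(seq_len(d[2]), d[3]),
                       col = rep(seq_len(d[3]), each = d[2]),
                       intensity = as.vector(img),
                       class = factor(as.vector(lab), levels = 0:4,
                                      labels = names(label_codes())))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::geom_tile(data = dplyr::filter(df, .data$class != "background"),
                       ggplot2::aes(colour = .data$class), fill = NA,
                       linewidth = 0.1, alpha = 0.4) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("slice %d", slice), colour = "class") +
    ggplot2::theme_void()
}

#' Bar chart of qualitative rating proportions
#'
#' @param ratings Tibble from [tabulate_ratings()].
#' @return A ggplot with bootstrap CI error bars, facetted by method.
#' @export
plot_ratings <- function(ratings) {
  ggplot2::ggplot(ratings,
                  ggplot2::aes(x = .data$rating, y = .data$pct,
                               fill = .data$method)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lo_pct,
                                        ymax = .data$hi_pct),
                           position = ggplot2::position_dodge(width = 0.8),
                           width = 0.25) +
    ggplot2::labs(x = NULL, y = "Percent of rated slices") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
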