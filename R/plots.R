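# ggplot2 displays for score tables, spatial maps and certainty maps.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot score distributions by class
#'
#' @param object an `ood_experiment`.
#' @param score_name which score to display.
#' @param ... unused.
#' @return A ggplot: one box per group, in-distribution first.
#' @export
autoplot.ood_experiment <- function(object, score_name = "loglik", ...) {
  tb <- dplyr::filter(object$scores, .data$score_name == !!score_name)
  tb$group_label <- stats::reorder(tb$group_label,
                                   tb$group_label != "in_distribution")
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$group_label,
                                   y = .data$score_value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = score_name,
                  title = "Score distribution by corruption class") +
    ggplot2::theme_minimal()
}

#' Plot an axial slice of a 3D array
#'
#' @param arr 3D numeric array (an intensity volume, spatial likelihood map
#'   or certainty map).
#' @param slice axial slice index (default: middle).
#' @param title plot title.
#' @return A ggplot raster of the slice.
#' @export
plot_slice <- function(arr, slice = NULL, title = NULL) {
  d <- dim(arr)
  slice <- slice %||% (d[3] %/% 2L)
  df <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]))
  df$value <- as.vector(arr[, , slice])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = title %||% sprintf("axial slice %d", slice)) +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "right",
                   plot.title = ggplot2::element_text(hjust = 0.5))
}

#' @rdname plot_slice
#' @param object a `likelihood_result` or `certainty_map`.
#' @param upsample_factor upsampling for the likelihood map.
#' @param ... passed to [plot_slice()].
#' @export
autoplot.likelihood_result <- function(object, upsample_factor = 1L, ...) {
  plot_slice(spatial_likelihood_map(object, upsample_factor),
             title = "conditional log-probability", ...)
}

#' @rdname plot_slice
#' @export
autoplot.certainty_map <- function(object, ...) {
  plot_slice(object$values, title = paste0("certainty (", object$method, ")"), ...)
}
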