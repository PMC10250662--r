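#' Plot a sampled signal curve
#'
#' @param object An [asl_signal()].
#' @param ... Unused.
#' @method autoplot asl_signal
#' @return A ggplot.
#' @export
autoplot.asl_signal <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time from label start (s)",
                  y = expression(Delta * M ~ "(units of" ~ M["0a"] * ")"))
}

#' Slice-wise raster plot of a fitted parameter map
#'
#' @param maps An `asl_param_maps` (or any voxel tibble with `x`,
#'   `y`, `z`).
#' @param var Column to display, e.g. `"cbf"`, `"att"`, `"abv"`.
#' @return A ggplot faceted by slice.
#' @export
plot_map <- function(maps, var = "ftiss") {
  stopifnot(var %in% names(maps))
  ggplot2::ggplot(maps, ggplot2::aes(.data$x, .data$y,
                                     fill = .data[[var]])) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~z, labeller = ggplot2::label_both) +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(fill = var)
}

#' Regional bar plot of a summary table
#'
#' @param summary Output of [regional_summary()].
#' @param variable Which summarised variable to show.
#' @return A ggplot with mean +/- SD error bars per region.
#' @export
plot_regional <- function(summary, variable) {
  df <- dplyr::filter(summary, .data$variable == !!variable)
  fill <- if ("model" %in% names(df)) "model" else NULL
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$region, .data$mean))
  if (!is.null(fill)) {
    p <- p + ggplot2::geom_col(ggplot2::aes(fill = .data$model),
                               position = "dodge")
  } else {
    p <- p + ggplot2::geom_col()
  }
  p + ggplot2::geom_errorbar(
    ggplot2::aes(ymin = .data$mean - .data$sd,
                 ymax = .data$mean + .data$sd,
                 group = if (!is.null(fill)) .data$model else 1),
    position = ggplot2::position_dodge(width = 0.9), width = 0.2
  ) +
    ggplot2::labs(y = variable)
}
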