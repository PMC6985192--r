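#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot seasonal class patterns
#'
#' Mean band curves over the agricultural year, one panel per class, one
#' line per band - the synthetic analogue of the usual per-class temporal
#' pattern figure.
#'
#' @param object A `luc_patterns` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.luc_patterns <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$step, y = .data$mean,
                                       color = .data$band)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~label) +
    ggplot2::labs(x = "composite step (Sep-Aug)", y = "index / reflectance",
                  color = "band") +
    ggplot2::theme_minimal()
}

#' Plot a categorical class map
#'
#' @param object A `luc_class_map`.
#' @param ... Unused.
#' @return A ggplot using the vocabulary's rendering colors.
#' @export
autoplot.luc_class_map <- function(object, ...) {
  df <- as_tibble(object)
  pal <- stats::setNames(luc_classes()$color, luc_classes()$label)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$label)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = pal, na.value = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "class", title = attr(object, "year")) +
    ggplot2::theme_void()
}

#' Plot per-class probability planes
#'
#' @param object A `luc_prob_cube`.
#' @param ... Unused.
#' @return A ggplot, one facet per class.
#' @export
autoplot.luc_prob_cube <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$probability)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~class) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' Plot class area trajectories
#'
#' @param areas An [area_series()] tibble.
#' @param drop_zero Drop classes whose area is zero in every year.
#' @return A ggplot of area (ha) against year, one line per class.
#' @export
plot_area_series <- function(areas, drop_zero = TRUE) {
  if (drop_zero) {
    keep <- dplyr::group_by(areas, .data$class)
    keep <- dplyr::filter(keep, sum(.data$area_ha) > 0)
    areas <- dplyr::ungroup(keep)
  }
  pal <- stats::setNames(luc_classes()$color, luc_classes()$label)
  ggplot2::ggplot(areas, ggplot2::aes(x = .data$year, y = .data$area_ha,
                                      color = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_color_manual(values = pal) +
    ggplot2::labs(x = "year", y = "area (ha)", color = "class") +
    ggplot2::theme_minimal()
}
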