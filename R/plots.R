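#' Plot a rendered channel
#'
#' @param object a [channel_image()].
#' @param trans intensity transform for display (`"sqrt"`, `"log1p"` or
#'   `"identity"`).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.channel_image <- function(object, trans = "sqrt", ...) {
  s_um <- object$pixel_size_nm / 1000
  df <- expand.grid(r = seq_len(nrow(object$pixels)),
                    c = seq_len(ncol(object$pixels)))
  df$value <- object$pixels[cbind(df$r, df$c)]
  df$x <- (df$c - 0.5) * s_um
  df$y <- (df$r - 0.5) * s_um
  f <- switch(trans, sqrt = sqrt, log1p = log1p, identity = identity)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = f(.data$value))) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = object$label) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = sprintf("%s (%s, %.4g nm/px)", object$label,
                                  object$modality, object$pixel_size_nm)) +
    ggplot2::theme_minimal()
}

#' Plot ground-truth scene placements
#'
#' PSD centres, NC offsets, bouton substructures and astro domains as a
#' point overlay in physical coordinates.
#'
#' @param scene a [ground_truth_scene()].
#' @return A ggplot object.
#' @export
plot_scene <- function(scene) {
  stopifnot(inherits(scene, "ground_truth_scene"))
  layers <- dplyr::bind_rows(
    dplyr::mutate(dplyr::select(scene$ncs, "x_um", "y_um"), what = "NC"),
    dplyr::mutate(dplyr::select(scene$bouton_subs, "x_um", "y_um"),
                  what = "bouton"),
    dplyr::mutate(dplyr::select(scene$astros, "x_um", "y_um"), what = "astro"))
  ggplot2::ggplot(layers, ggplot2::aes(.data$x_um, .data$y_um,
                                       colour = .data$what)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::geom_point(data = scene$psds, colour = "black", shape = 3,
                        size = 1.5) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of tripartite categories
#'
#' @param psd_table a PSD table carrying a `category` column (see
#'   [run_pipeline()]).
#' @return A ggplot object.
#' @export
plot_category_counts <- function(psd_table) {
  ggplot2::ggplot(psd_table, ggplot2::aes(.data$category)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "PSD count") +
    ggplot2::theme_minimal()
}

#' Stacked NC-class fractions
#'
#' @param nc_table a PSD table carrying `nc_class` (see [psd_nc_table()]).
#' @param drop_zero drop the 0NC class from the denominator (default).
#' @return A ggplot object.
#' @export
plot_nc_class_fractions <- function(nc_table, drop_zero = TRUE) {
  d <- if (drop_zero) nc_table[nc_table$nc_class != "0NC", ] else nc_table
  ggplot2::ggplot(d, ggplot2::aes(x = "PSDs", fill = .data$nc_class)) +
    ggplot2::geom_bar(position = "fill") +
    ggplot2::labs(x = NULL, y = "fraction of PSDs", fill = "NC class") +
    ggplot2::theme_minimal()
}
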