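#' Per-position information content plot
#'
#' Bar chart of information content (bits) across the 11 context positions,
#' annotated with the consensus letters — the text analog of a sequence
#' logo.
#'
#' @param fm A `freq_matrix`.
#' @return A ggplot object.
#' @export
plot_information_content <- function(fm) {
  ic <- information_content(fm)
  ggplot2::ggplot(ic, ggplot2::aes(x = .data$position, y = .data$ic)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$consensus), vjust = -0.4) +
    ggplot2::scale_x_continuous(breaks = POSITIONS) +
    ggplot2::labs(x = "position (0 = mutated base)",
                  y = "information content (bits)",
                  title = fm$name %||% NULL) +
    ggplot2::ylim(0, 2.2) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.freq_matrix <- function(object, ...) plot_information_content(object)

#' @exportS3Method ggplot2::autoplot
autoplot.weight_matrix <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$position, y = .data$base,
                               fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick") +
    ggplot2::scale_x_continuous(breaks = POSITIONS) +
    ggplot2::labs(x = "position", y = NULL, fill = "W (bits)",
                  title = object$name %||% NULL) +
    ggplot2::theme_minimal()
}

#' Grayscale footprint heatmap
#'
#' Tiles of matrix x tissue cells shaded by the discretized ratio (or
#' false-positive fraction), reproducing the grayscale binning of
#' [heatmap_export()]: white cells are below the ramp.
#'
#' @param results Footprint scan (or control outcome) tibble.
#' @param value_col,class_col,config As in [heatmap_export()].
#' @return A ggplot object.
#' @export
plot_footprint_heatmap <- function(results, value_col = "ratio",
                                   class_col = "subclass",
                                   config = heatmap_class_config()) {
  binned <- heatmap_export(results, value_col, class_col, config)
  ggplot2::ggplot(binned,
                  ggplot2::aes(x = .data$matrix_id, y = .data$tissue,
                               fill = .data$gray_bin)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_gradient(low = "grey95", high = "black",
                                 na.value = "white") +
    ggplot2::labs(x = NULL, y = NULL, fill = "bin") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @exportS3Method ggplot2::autoplot
autoplot.mixture_fit <- function(object, weights = NULL, ...) {
  comp <- tidy(object)
  p <- ggplot2::ggplot()
  if (!is.null(weights)) {
    p <- p + ggplot2::geom_histogram(
      data = tibble(w = weights),
      ggplot2::aes(x = .data$w, y = ggplot2::after_stat(.data$density)),
      breaks = seq(0, 100, 10), fill = "grey85", color = "grey60")
  }
  grid <- tibble(x = seq(0, 100, 0.5))
  dens <- purrr::pmap_dfr(comp, function(component, mean, sd, weight) {
    tibble(x = grid$x, component = component,
           density = weight * dnorm(grid$x, mean, sd))
  })
  p + ggplot2::geom_line(data = dens,
                         ggplot2::aes(x = .data$x, y = .data$density,
                                      color = .data$component)) +
    ggplot2::labs(x = "weight (% matching score)", y = "density",
                  color = "component") +
    ggplot2::theme_minimal()
}

#' Binned weight distribution plot
#'
#' Histogram of weights in the 0-9, 10-19, ..., 90-100 bins used by the
#' mixture goodness-of-fit test.
#'
#' @param weights Numeric vector of weights.
#' @return A ggplot object.
#' @export
plot_weight_distribution <- function(weights) {
  ggplot2::ggplot(tibble(w = weights), ggplot2::aes(x = .data$w)) +
    ggplot2::geom_histogram(breaks = seq(0, 100, 10), fill = "grey40",
                            color = "white") +
    ggplot2::labs(x = "weight (% matching score)", y = "sites") +
    ggplot2::theme_minimal()
}
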