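# ggplot2 displays for the result types.

#' Plot an Oxford grid
#'
#' Tile plot of shared-marker counts between two chromosome sets; cells are
#' labelled with their counts and, when present, coloured by annotation.
#'
#' @param object An `oxford_grid`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot oxford_grid
#' @export
autoplot.oxford_grid <- function(object, ...) {
  cells <- tibble::as_tibble(object)
  if (attr(object, "kind") == "arm") {
    cells <- dplyr::rename(cells, row = "arm_a", col = "arm_b")
  } else {
    cells <- dplyr::rename(cells, row = "arm", col = "model_chrom")
  }
  p <- ggplot2::ggplot(cells, ggplot2::aes(x = .data$col, y = .data$row))
  if ("annotation" %in% names(cells)) {
    p <- p + ggplot2::geom_tile(ggplot2::aes(fill = .data$annotation),
                                colour = "grey60")
  } else {
    p <- p + ggplot2::geom_tile(ggplot2::aes(fill = .data$count),
                                colour = "grey60") +
      ggplot2::scale_fill_gradient(low = "grey95", high = "steelblue")
  }
  p +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' @export
plot.oxford_grid <- function(x, ...) print(autoplot.oxford_grid(x, ...))

#' Plot a synthetic map
#'
#' Linkage groups drawn side by side with loci as ticks; centromeric loci
#' are highlighted.
#'
#' @param object A `synthetic_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot synthetic_map
#' @export
autoplot.synthetic_map <- function(object, ...) {
  m <- tibble::as_tibble(object)
  ggplot2::ggplot(m, ggplot2::aes(x = .data$linkage_group,
                                  y = .data$position_cM)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$linkage_group),
                       linewidth = 2, colour = "grey80") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$arm), shape = 95,
                        size = 4) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = "position (cM)", colour = "arm") +
    ggplot2::theme_minimal()
}

#' @export
plot.synthetic_map <- function(x, ...) print(autoplot.synthetic_map(x, ...))
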