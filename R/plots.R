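# ggplot2 views of the main result types.

stain_palette <- c(N = "#4575b4", W = "#a6d96a", M = "#fdae61", S = "#d73027")

#' Plot a synthetic scene with its ground truth
#'
#' @param object An `ihc_scene`.
#' @param ... Unused.
#' @return A ggplot object: the rendered field with ground-truth centroids
#'   coloured by stain class.
#' @export
autoplot.ihc_scene <- function(object, ...) {
  h <- dim(object$image)[1]; w <- dim(object$image)[2]
  p <- ggplot2::ggplot() +
    ggplot2::annotation_raster(object$image, xmin = -0.5, xmax = w - 0.5,
                               ymin = -(h - 0.5), ymax = 0.5) +
    ggplot2::coord_fixed(xlim = c(-0.5, w - 0.5), ylim = c(-(h - 0.5), 0.5)) +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
  if (nrow(object$truth) > 0) {
    p <- p + ggplot2::geom_point(
      data = object$truth,
      ggplot2::aes(x = .data$x, y = -.data$y, colour = .data$label),
      shape = 3, size = 2
    ) +
      ggplot2::scale_colour_manual(values = stain_palette, name = "class")
  }
  p
}

#' Plot a score map
#'
#' @param object A `score_map`.
#' @param ... Unused.
#' @return A ggplot raster of the per-pixel cell-centre proximity score.
#' @export
autoplot.score_map <- function(object, ...) {
  df <- expand.grid(y = seq_len(nrow(object)) - 1,
                    x = seq_len(ncol(object)) - 1)
  df$score <- as.numeric(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = -.data$y,
                                   fill = .data$score)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)", fill = "score") +
    ggplot2::theme_minimal()
}

#' Plot manual against automated Allred scores
#'
#' Slide-by-slide comparison of the two score series, ordered by the
#' manual score.
#'
#' @param object An `allred_agreement` from [agreement_stats()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.allred_agreement <- function(object, ...) {
  ord <- order(object$manual)
  df <- tibble::tibble(
    slide = rep(seq_along(ord), 2),
    score = c(object$manual[ord], object$automated[ord]),
    series = rep(c("manual", "automated"), each = length(ord))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$slide, y = .data$score,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(breaks = 0:8) +
    ggplot2::labs(x = "slide (ordered by manual score)",
                  y = "Allred score", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
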