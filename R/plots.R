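# ggplot2 autoplot methods for the main result types.

#' Plot a PCoA ordination
#'
#' Scatter of the first two axes, optionally coloured by group.
#'
#' @param object An `mg_pcoa`.
#' @param metadata Optional metadata to colour samples by `group`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mg_pcoa <- function(object, metadata = NULL, ...) {
  pts <- object$points
  if (object$k_returned < 2) abort("need at least two axes to plot.")
  if (!is.null(metadata)) {
    pts$group <- unname(group_lookup(metadata, pts$sample_id))
  }
  pct <- round(100 * object$rel_eigen[1:2], 1)
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$Axis1, y = .data$Axis2))
  p <- if (!is.null(metadata)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
  p +
    ggplot2::labs(x = sprintf("Axis 1 (%.1f%%)", pct[1]),
                  y = sprintf("Axis 2 (%.1f%%)", pct[2])) +
    ggplot2::theme_minimal()
}

#' Plot guild sizes
#'
#' Bar chart of taxa per guild, a quick structural overview of a partition.
#'
#' @param object A `guild_partition`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.guild_partition <- function(object, ...) {
  sizes <- object$assignment %>%
    dplyr::count(.data$guild, name = "n_taxa")
  ggplot2::ggplot(sizes, ggplot2::aes(x = factor(.data$guild),
                                      y = .data$n_taxa)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "guild", y = "taxa") +
    ggplot2::theme_minimal()
}

#' Plot a network's edge-weight distribution
#'
#' Histogram of edge correlations split by sign; a fast sanity view of a
#' co-occurrence network without graph layout.
#'
#' @param object An `mg_network`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mg_network <- function(object, ...) {
  if (nrow(object$edges) == 0) {
    abort("network has no edges to plot.")
  }
  ggplot2::ggplot(object$edges, ggplot2::aes(x = .data$weight,
                                             fill = .data$sign)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::labs(x = "correlation", y = "edges") +
    ggplot2::theme_minimal()
}
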