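#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an alignment graph
#'
#' Draws the alignment graph with a deterministic Fruchterman–Reingold
#' layout; each point is a matched node pair, each segment a conserved
#' edge, coloured by connected component (largest components first).
#'
#' @param object an [build_alignment_graph()] result.
#' @param max_label components at or below this rank get labelled points
#'   (default 0 = no labels).
#' @param ... unused.
#' @return a `ggplot`.
#' @export
autoplot.alignment_graph <- function(object, max_label = 0, ...) {
  g <- object$graph
  set.seed(1L)  # deterministic layout
  xy <- igraph::layout_with_fr(g)
  comp <- igraph::components(g)$membership
  nodes <- tibble::tibble(x = xy[, 1], y = xy[, 2],
                          name = igraph::V(g)$name,
                          component = factor(comp))
  el <- igraph::as_edgelist(g, names = FALSE)
  seg <- tibble::tibble(x = xy[el[, 1], 1], y = xy[el[, 1], 2],
                        xend = xy[el[, 2], 1], yend = xy[el[, 2], 2])
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey60") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$component),
                        size = 2, show.legend = FALSE) +
    ggplot2::theme_void() +
    ggplot2::labs(title = sprintf("Alignment graph: %d pairs, %d conserved edges",
                                  igraph::gorder(g), igraph::gsize(g)))
  if (max_label > 0) {
    p <- p + ggplot2::geom_text(
      data = nodes, ggplot2::aes(x = .data$x, y = .data$y,
                                 label = .data$name),
      size = 2.5, vjust = -1)
  }
  p
}

#' Plot an assessment summary
#'
#' Histogram of alignment-graph component sizes; when enrichment was
#' computed, enriched and non-enriched components are distinguished.
#'
#' @param object an [assessment_report()] result.
#' @param ... unused.
#' @return a `ggplot`.
#' @export
autoplot.alignment_assessment <- function(object, ...) {
  df <- object$component_sizes
  if (!is.null(object$enrichment) && nrow(object$enrichment$terms) > 0) {
    enr <- dplyr::summarise(
      dplyr::group_by(object$enrichment$terms, .data$component),
      enriched = any(.data$enriched), .groups = "drop")
    df <- dplyr::left_join(df, enr, by = "component")
    df$enriched[is.na(df$enriched)] <- FALSE
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$size,
                                          fill = .data$enriched))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$size))
  }
  p + ggplot2::geom_bar() +
    ggplot2::labs(x = "component size (matched pairs)",
                  y = "number of components",
                  title = "Common connected subgraphs") +
    ggplot2::theme_minimal()
}

#' Similarity-score heatmap
#'
#' @param object an `isorank_sim` matrix.
#' @param ... unused.
#' @return a `ggplot` tile map of the diffused node-pair scores.
#' @export
autoplot.isorank_sim <- function(object, ...) {
  df <- tidy.isorank_sim(object)
  df$node_a <- factor(df$node_a, levels = rownames(object))
  df$node_b <- factor(df$node_b, levels = colnames(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$node_b, y = .data$node_a,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "score",
                  title = sprintf("Diffused similarity (alpha = %g)",
                                  attr(object, "alpha"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
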