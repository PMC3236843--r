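#' Plot a highlighted reference pathway
#'
#' Draws the gene-level interaction graph of a pathway with matched
#' (EST-supported) nodes in the highlight colour, using a deterministic
#' force-directed layout.
#'
#' @param object A `highlighted_pathway` from [highlight_pathway()].
#' @param include_reactions Passed to [to_interaction_graph()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.highlighted_pathway <- function(object, include_reactions = NULL,
                                         ...) {
  ig <- to_interaction_graph(object$base,
                             include_reactions = include_reactions)
  nodes <- ig$nodes
  if (nrow(nodes) == 0L) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::ggtitle(object$base$title))
  }
  g <- igraph::graph_from_data_frame(
    if (nrow(ig$edges)) ig$edges[, c("from", "to")] else
      data.frame(from = character(), to = character()),
    directed = FALSE, vertices = data.frame(name = nodes$entry_id))
  xy <- with_local_seed(1L, igraph::layout_with_fr(g))  # reproducible layout
  nodes$x <- xy[, 1]
  nodes$y <- xy[, 2]
  nodes$matched <- nodes$entry_id %in% object$matched_nodes
  lab <- stats::setNames(object$relabel$koid, object$relabel$entry_id)
  nodes$label <- ifelse(nodes$matched, unname(lab[nodes$entry_id]),
                        dplyr::coalesce(nodes$display_name, nodes$entry_id))
  edges <- ig$edges %>%
    dplyr::left_join(nodes[, c("entry_id", "x", "y")],
                     by = c(from = "entry_id")) %>%
    dplyr::left_join(nodes[, c("entry_id", "x", "y")],
                     by = c(to = "entry_id"), suffix = c("", "end"))
  pl <- ggplot2::ggplot(nodes, ggplot2::aes(x = .data$x, y = .data$y))
  if (nrow(edges) > 0L) {
    pl <- pl + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      colour = "grey60")
  }
  pl +
    ggplot2::geom_point(ggplot2::aes(colour = .data$matched), size = 4) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), vjust = -1,
                       size = 3) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = object$highlight_color, `FALSE` = "grey40"),
      labels = c(`TRUE` = "EST-supported", `FALSE` = "unmatched"),
      name = NULL) +
    ggplot2::theme_void() +
    ggplot2::ggtitle(object$base$title)
}

#' Plot pathway coverage of an annotated EST set
#'
#' Bar chart of the coverage counts: assigned vs mapped queries and the
#' metabolic / non-metabolic / both split.
#'
#' @param object A `ko_coverage` from [coverage_stats()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ko_coverage <- function(object, ...) {
  d <- tibble::tibble(
    what = factor(
      c("total", "assigned", "mapped", "metabolic", "non-metabolic", "both"),
      levels = c("total", "assigned", "mapped", "metabolic",
                 "non-metabolic", "both")),
    n = c(object$n_queries_total, object$n_queries_assigned,
          object$n_queries_mapped, object$n_queries_metabolic,
          object$n_queries_nonmetabolic, object$n_queries_both)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$what, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "queries (ESTs)",
                  title = "Pathway coverage of query set") +
    ggplot2::theme_minimal()
}
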