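#' Plot a regulatory network or a set of mined pathways
#'
#' Networks are drawn with a deterministic layered layout: each node's
#' column is its breadth-first depth from the network's source nodes (nodes
#' without in-edges; in cyclic components the lexicographically first node
#' seeds the sweep), and nodes are spread vertically within a column in
#' lexicographic order. Edges carry the `(tfr_count, tfb_count)` evidence
#' label used in pathway figures. For a pathway set, the union subnetwork
#' induced by the pathways' edges is drawn.
#'
#' @param object A [trp_network] or a pathway tibble.
#' @param network Evidence source when `object` is a pathway tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' fx <- gln3_fixture()
#' net <- build_direct_regulatory_network(fx$tfb, fx$tfr,
#'   condition = "nitrogen source quality/availability")
#' autoplot(net)
#' @export
autoplot.trp_network <- function(object, ...) {
  if (nrow(object$edges) == 0) {
    abort("cannot plot an empty network", class = "trp_query_error")
  }
  lay <- layered_layout(object$edges)
  edges <- object$edges %>%
    dplyr::mutate(
      x = lay$x[.data$tf], y = lay$y[.data$tf],
      xend = lay$x[.data$target], yend = lay$y[.data$target],
      evidence = sprintf("(%d, %d)", .data$tfr_count, .data$tfb_count)
    )
  nodes <- tibble(name = names(lay$x), x = lay$x, y = lay$y)
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      arrow = ggplot2::arrow(length = ggplot2::unit(2.5, "mm"),
                             type = "closed"),
      color = "grey40") +
    ggplot2::geom_text(
      data = edges,
      ggplot2::aes(x = (.data$x + .data$xend) / 2,
                   y = (.data$y + .data$yend) / 2,
                   label = .data$evidence),
      size = 3, vjust = -0.6, color = "grey30") +
    ggplot2::geom_label(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$name),
      fill = "white") +
    ggplot2::expand_limits(
      x = c(min(nodes$x) - 0.4, max(nodes$x) + 0.4),
      y = c(min(nodes$y) - 0.4, max(nodes$y) + 0.4)) +
    ggplot2::labs(
      title = sprintf("%s network (condition: %s)", object$kind,
                      object$condition),
      subtitle = "edge label: (# TFR publications, # TFB publications)") +
    ggplot2::theme_void()
}

#' @rdname autoplot.trp_network
#' @export
autoplot.trp_paths <- function(object, network = NULL, ...) {
  if (is.null(network)) {
    abort("plotting a pathway set needs `network` to look up edge evidence",
          class = "trp_query_error")
  }
  edges <- paths_edge_union(object, network)
  autoplot(new_trp_network(network$kind, network$condition, edges), ...)
}

# deterministic layered layout: x = BFS depth, y = lexicographic rank in layer
layered_layout <- function(edges) {
  nodes <- sort(unique(c(edges$tf, edges$target)))
  adj <- adjacency(edges)
  indeg <- table(factor(edges$target, levels = nodes))
  depth <- stats::setNames(rep(NA_real_, length(nodes)), nodes)
  roots <- nodes[indeg == 0]
  if (length(roots) == 0) roots <- nodes[1]
  frontier <- roots
  depth[roots] <- 0
  while (length(frontier) > 0) {
    nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)),
                   names(depth)[!is.na(depth)])
    if (length(nxt) > 0) depth[nxt] <- depth[frontier[1]] + 1
    frontier <- nxt
  }
  while (anyNA(depth)) {          # remaining cycle-only components
    seed <- nodes[is.na(depth)][1]
    depth[seed] <- 0
    frontier <- seed
    while (length(frontier) > 0) {
      nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)),
                     names(depth)[!is.na(depth)])
      if (length(nxt) > 0) depth[nxt] <- depth[frontier[1]] + 1
      frontier <- nxt
    }
  }
  y <- stats::setNames(rep(0, length(nodes)), nodes)
  for (d in unique(depth)) {
    members <- sort(nodes[depth == d])
    y[members] <- seq_along(members) - (length(members) + 1) / 2
  }
  list(x = depth, y = y)
}
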