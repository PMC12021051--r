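#' Node homophily of a labeled graph
#'
#' Mean over non-isolated nodes of the fraction of each node's neighbors that
#' carry the node's own label. Isolated nodes (degree 0) have an undefined
#' fraction and are excluded from the mean; their count is reported by
#' [homophily_report()].
#'
#' @param graph a [cell_graph()].
#' @param labels per-node labels, length `n_nodes`.
#' @return A value in `[0, 1]`.
#' @export
node_homophily <- function(graph, labels) {
  stopifnot(length(labels) == graph$n_nodes)
  labels <- as.character(labels)
  e <- graph$edges
  deg <- graph_degree(graph)
  if (all(deg == 0)) stop("all nodes are isolated", call. = FALSE)
  same <- labels[e[, 1]] == labels[e[, 2]]
  same_cnt <- tabulate(c(e[same, 1], e[same, 2]), nbins = graph$n_nodes)
  keep <- deg > 0
  mean(same_cnt[keep] / deg[keep])
}

#' Edge homophily of a labeled graph
#'
#' Fraction of undirected edges whose endpoints share a label, each edge
#' counted once.
#'
#' @inheritParams node_homophily
#' @return A value in `[0, 1]`.
#' @export
edge_homophily <- function(graph, labels) {
  stopifnot(length(labels) == graph$n_nodes)
  labels <- as.character(labels)
  e <- graph$edges
  if (!nrow(e)) stop("graph has no edges", call. = FALSE)
  mean(labels[e[, 1]] == labels[e[, 2]])
}

#' Homophily report for a labeled graph
#'
#' @inheritParams node_homophily
#' @return An object of class `HomophilyReport`: list with `node_homophily`,
#'   `edge_homophily`, `n_isolated` (degree-0 nodes excluded from the node
#'   metric).
#' @export
homophily_report <- function(graph, labels) {
  structure(list(
    node_homophily = node_homophily(graph, labels),
    edge_homophily = edge_homophily(graph, labels),
    n_isolated = sum(graph_degree(graph) == 0)
  ), class = "HomophilyReport")
}

#' @export
print.HomophilyReport <- function(x, ...) {
  cat(sprintf("HomophilyReport: node %.4f | edge %.4f | %d isolated node(s)\n",
              x$node_homophily, x$edge_homophily, x$n_isolated))
  invisible(x)
}
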