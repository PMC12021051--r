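#' Construct a cell graph
#'
#' Undirected, simple, unweighted graph over cells. Edges are stored once as
#' unordered pairs with `i < j` (1-based cell indices); duplicates and
#' self-loops are dropped.
#'
#' @param n_nodes number of cells.
#' @param edges 2-column integer matrix of endpoints (any orientation).
#' @param k neighbors-per-node parameter used at construction (`NA` for
#'   precomputed graphs).
#' @param metric distance metric name used at construction.
#' @return An object of class `CellGraph` with fields `n_nodes`, `edges`,
#'   `k`, `metric`.
#' @export
cell_graph <- function(n_nodes, edges, k = NA_integer_,
                       metric = "euclidean") {
  edges <- matrix(as.integer(as.matrix(edges)), ncol = 2)
  if (nrow(edges)) {
    if (any(edges < 1 | edges > n_nodes)) {
      stop("edge endpoints must lie in 1..", n_nodes, call. = FALSE)
    }
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    edges <- cbind(pmin(edges[, 1], edges[, 2]),
                   pmax(edges[, 1], edges[, 2]))
    edges <- unique(edges)
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  colnames(edges) <- c("i", "j")
  structure(list(n_nodes = as.integer(n_nodes), edges = edges,
                 k = as.integer(k), metric = metric),
            class = "CellGraph")
}

#' @export
print.CellGraph <- function(x, ...) {
  cat("CellGraph: ", x$n_nodes, " nodes, ", nrow(x$edges),
      " undirected edges (k = ", x$k, ", metric = ", x$metric, ")\n",
      sep = "")
  invisible(x)
}

#' Sparse adjacency matrix of a cell graph
#' @param graph a [cell_graph()].
#' @return Symmetric binary `dgCMatrix` with zero diagonal.
#' @export
adjacency_matrix <- function(graph) {
  n <- graph$n_nodes
  e <- graph$edges
  if (!nrow(e)) return(Matrix::sparseMatrix(i = integer(), j = integer(),
                                            dims = c(n, n)) * 1)
  Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                       x = 1, dims = c(n, n))
}

#' Build a KNN cell graph
#'
#' Computes the directed k-nearest-neighbor relation of each cell in the
#' normalized HVG feature space (self excluded), then symmetrizes by union
#' into an undirected simple graph with all edge weights 1. Ties at the k-th
#' distance are broken by ascending cell index, so the edge set is
#' deterministic.
#'
#' @param ds an [expression_dataset()] with a normalized layer, or a numeric
#'   feature matrix (cells x features).
#' @param k neighbors per cell (default 15); must satisfy `1 <= k < n_cells`.
#' @param metric `"euclidean"` (default) or `"manhattan"`.
#' @return A [cell_graph()].
#' @export
build_knn_graph <- function(ds, k = 15, metric = c("euclidean", "manhattan")) {
  metric <- match.arg(metric)
  feats <- if (inherits(ds, "ExpressionDataset")) {
    if (is.null(ds$normalized)) {
      stop("dataset has no normalized layer; run normalize_log() first",
           call. = FALSE)
    }
    ds$normalized
  } else {
    as.matrix(ds)
  }
  n <- nrow(feats)
  if (k < 1 || k >= n) {
    stop("k must satisfy 1 <= k < n_cells (k = ", k, ", n_cells = ", n, ")",
         call. = FALSE)
  }
  d <- as.matrix(stats::dist(feats, method = metric))
  idx <- seq_len(n)
  from <- rep(idx, each = k)
  to <- integer(n * k)
  for (i in idx) {
    di <- d[i, ]
    di[i] <- Inf
    nb <- order(di, idx)[seq_len(k)]  # ties broken by ascending index
    to[((i - 1) * k + 1):(i * k)] <- nb
  }
  g <- cell_graph(n, cbind(from, to), k = k, metric = metric)
  attr(g, "out_neighbors") <- matrix(to, nrow = n, byrow = TRUE)
  g
}

#' Per-node degree of a cell graph
#' @param graph a [cell_graph()].
#' @return integer vector of length `n_nodes`.
#' @export
graph_degree <- function(graph) {
  tabulate(c(graph$edges[, 1], graph$edges[, 2]), nbins = graph$n_nodes)
}

#' One-hop and two-hop neighborhood index
#'
#' For each node, `one_hop` is its adjacency neighborhood and `two_hop` the
#' set of nodes at shortest-path distance exactly 2 (the union of neighbors'
#' neighborhoods minus the one-hop set and the node itself). Returned both as
#' neighbor lists and as sparse binary matrices `A1`, `A2` used by the
#' encoder's two-hop message passing.
#'
#' @param graph a [cell_graph()].
#' @return An object of class `NeighborhoodIndex`: list with `A1`, `A2`
#'   (sparse symmetric binary), `one_hop`, `two_hop` (lists of integer
#'   vectors), `n_nodes`.
#' @export
two_hop_neighborhoods <- function(graph) {
  A1 <- adjacency_matrix(graph)
  n <- graph$n_nodes
  walk2 <- A1 %*% A1          # counts of 2-step walks
  t2 <- methods::as(walk2, "TsparseMatrix")
  keep <- t2@i != t2@j        # drop self
  i <- t2@i[keep] + 1L
  j <- t2@j[keep] + 1L
  # drop pairs already adjacent (shortest path 1, not 2)
  adj_key <- paste(c(graph$edges[, 1], graph$edges[, 2]),
                   c(graph$edges[, 2], graph$edges[, 1]))
  keep2 <- !(paste(i, j) %in% adj_key)
  A2 <- Matrix::sparseMatrix(i = i[keep2], j = j[keep2], x = 1,
                             dims = c(n, n), use.last.ij = TRUE)
  one_hop <- row_index_list(A1)
  two_hop <- row_index_list(A2)
  structure(list(A1 = A1, A2 = A2, one_hop = one_hop, two_hop = two_hop,
                 n_nodes = n),
            class = "NeighborhoodIndex")
}

row_index_list <- function(A) {
  At <- methods::as(A, "TsparseMatrix")
  split(At@j + 1L, factor(At@i + 1L, levels = seq_len(nrow(A))))
}
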