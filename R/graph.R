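#' Adjacency graph for attention layers
#'
#' A node set with per-node neighbor lists; every node's list contains the
#' node itself (the self-loop required by the attention aggregation).
#'
#' @param neighbors List of integer vectors (1-based node indices).
#' @return An object of class `adj_graph` with elements `n_nodes` and
#'   `neighbors`.
#' @export
adj_graph <- function(neighbors) {
  n <- length(neighbors)
  neighbors <- lapply(seq_len(n), function(i) {
    nb <- sort(unique(as.integer(c(i, neighbors[[i]]))))
    if (any(nb < 1L | nb > n)) stop("neighbor index out of range", call. = FALSE)
    nb
  })
  structure(list(n_nodes = n, neighbors = neighbors), class = "adj_graph")
}

#' @export
print.adj_graph <- function(x, ...) {
  deg <- lengths(x$neighbors)
  cat(sprintf("<adj_graph> %d nodes, mean degree %.1f (incl. self-loop)\n",
              x$n_nodes, mean(deg)))
  invisible(x)
}

# k nearest rows of a coordinate/feature matrix by Euclidean distance,
# ties broken by lower index; returns a list of neighbor vectors incl. self.
knn_neighbors <- function(X, k) {
  n <- nrow(X)
  if (k < 0) stop("k must be >= 0", call. = FALSE)
  if (k >= n) stop("k must be smaller than the number of nodes", call. = FALSE)
  sq <- rowSums(X^2)
  # full pairwise squared distances; fine at desk scale (n <= ~1e4)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  diag(d2) <- Inf
  lapply(seq_len(n), function(i) {
    if (k == 0L) return(i)
    ord <- order(d2[i, ], seq_len(n))[seq_len(k)]
    c(i, ord)
  })
}

#' Expression k-nearest-neighbor graph
#'
#' Connects each cell to its `k` nearest cells by Euclidean distance in
#' normalized expression space (plus a self-loop). Ties are broken by lower
#' row index, so the graph is deterministic.
#'
#' @param E [expression_matrix()] with layer `"cpm_log2"`.
#' @param k Number of neighbors (default 15).
#' @return An [adj_graph()].
#' @export
build_expression_knn_graph <- function(E, k = 15) {
  validate_expr_matrix(E)
  if (E$layer != "cpm_log2")
    stop("build_expression_knn_graph expects cpm_log2 normalized data", call. = FALSE)
  if (k <= 0) stop("k must be positive", call. = FALSE)
  adj_graph(knn_neighbors(E$values, as.integer(k)))
}

#' Spatial k-nearest-neighbor graph for ST spots
#'
#' Connects each spot to its `k` spatially nearest spots (plus a self-loop).
#' The default `k = 6` matches the hexagonal packing of Visium arrays.
#' Duplicate coordinates make neighbors ill-defined; ties are broken by lower
#' spot index and a warning is emitted.
#'
#' @param G [spot_geometry()].
#' @param k Number of spatial neighbors (default 6).
#' @param radius Optional radius; when given, all spots within `radius`
#'   (rather than the `k` nearest) are connected.
#' @return An [adj_graph()].
#' @export
build_spatial_graph <- function(G, k = 6, radius = NULL) {
  if (!inherits(G, "spot_geometry")) stop("G must be a spot_geometry", call. = FALSE)
  if (anyDuplicated(G$coords) > 0)
    warning("duplicated spot coordinates; neighbor ties broken by spot index")
  if (!is.null(radius)) {
    d <- as.matrix(stats::dist(G$coords))
    diag(d) <- Inf
    nb <- lapply(seq_len(nrow(d)), function(i) c(i, which(d[i, ] <= radius)))
    return(adj_graph(nb))
  }
  if (k < 0) stop("k must be >= 0", call. = FALSE)
  adj_graph(knn_neighbors(G$coords, as.integer(k)))
}

# Disjoint union of two graphs (block-diagonal adjacency); used to train one
# autoencoder jointly on cells and spots.
graph_disjoint_union <- function(g1, g2) {
  off <- g1$n_nodes
  adj_graph(c(g1$neighbors, lapply(g2$neighbors, function(nb) nb + off)))
}

# Flatten a graph into parallel edge vectors (i = target/query node whose
# neighborhood is softmax-normalized, j = source node).
graph_edges <- function(graph) {
  deg <- lengths(graph$neighbors)
  list(i = rep.int(seq_len(graph$n_nodes), deg),
       j = unlist(graph$neighbors, use.names = FALSE),
       deg = deg)
}
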