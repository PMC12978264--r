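#' Graph construction configuration
#'
#' @param k neighbour count for the k-nearest-neighbour graph (capped at
#'   M - 1 for tiny inputs)
#' @param symmetrise symmetrise the neighbour relation by union (an edge
#'   j -> i implies i -> j), making the graph undirected
#' @return an object of class `graph_config`
#' @export
graph_config <- function(k = 8, symmetrise = TRUE) {
  stopifnot(k >= 1)
  structure(list(k = as.integer(k), symmetrise = isTRUE(symmetrise)),
            class = "graph_config")
}

#' Normalise signals by the b0 level
#'
#' E_i = S_i / mean(S_j over b = 0 measurements). Scale-invariant:
#' multiplying all signals by a positive constant leaves E unchanged.
#'
#' @param voxel a [voxel_data()]
#' @return numeric vector of normalised signals, aligned with the protocol
#' @export
normalise_signals <- function(voxel) {
  stopifnot(inherits(voxel, "voxel_data"))
  idx <- voxel$protocol$b0_indices
  if (length(idx) == 0) stop("no b = 0 measurement; cannot normalise")
  m <- mean(voxel$signals[idx])
  if (!is.finite(m) || m <= 0) stop("non-positive mean b0 signal")
  voxel$signals / m
}

#' Mirror the diffusion-weighted point cloud
#'
#' Drops b = 0 points and adds the antipode (-q, E) of every remaining
#' point, yielding M = 2 (N - |B0|) nodes. Nodes are returned in canonical
#' order (sorted by b, then lexicographically by position) so that any
#' permutation of the input measurements yields the identical node set.
#'
#' @param voxel a [voxel_data()]
#' @return list with `positions` (M x 3), `E`, `b`
#' @export
mirror_points <- function(voxel) {
  E <- normalise_signals(voxel)
  p <- voxel$protocol
  dwi <- p$b > 0
  if (!any(dwi)) stop("no diffusion-weighted measurements left to mirror")
  q <- p$q[dwi, , drop = FALSE]
  pos <- rbind(q, -q)
  b <- rep(p$b[dwi], 2)
  e <- rep(E[dwi], 2)
  ord <- order(b, pos[, 1], pos[, 2], pos[, 3])
  list(positions = pos[ord, , drop = FALSE], E = e[ord], b = b[ord])
}

#' k-nearest-neighbour edges in q-space
#'
#' For each node, its k nearest other nodes by Euclidean distance
#' (deterministic ties: smaller index wins under the canonical node
#' order), symmetrised by union into an undirected neighbour relation.
#' Returned as a directed pair list: a row (i, j) means j is a neighbour
#' of i (messages flow j -> i). No self loops.
#'
#' @param positions M x 3 node positions
#' @param config a [graph_config()]
#' @return integer matrix with columns `i` (destination) and `j` (source)
#' @export
knn_edges <- function(positions, config = graph_config()) {
  M <- nrow(positions)
  if (M < 2) stop("a graph needs at least two nodes")
  k <- min(config$k, M - 1)
  d2 <- as.matrix(stats::dist(positions))^2
  nb <- vector("list", M)
  for (i in seq_len(M)) {
    ordi <- order(d2[i, -i], seq_len(M)[-i])
    nb[[i]] <- (seq_len(M)[-i])[ordi[seq_len(k)]]
  }
  adj <- matrix(FALSE, M, M)
  for (i in seq_len(M)) adj[i, nb[[i]]] <- TRUE
  if (config$symmetrise) adj <- adj | t(adj)
  which(adj, arr.ind = TRUE)[, c(1, 2), drop = FALSE] -> e
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  colnames(e) <- c("i", "j")
  e
}

#' Invariant edge features
#'
#' For an edge from j to i: the Euclidean distance between the q-space
#' positions, the absolute cosine of the angle between them (absolute
#' because of antipodal symmetry), and the signed b-value difference
#' b_i - b_j. The first two components are invariant under any orthogonal
#' transform applied jointly to all positions.
#'
#' @param q_i,q_j q-space positions: 3-vectors or n x 3 matrices
#' @param b_i,b_j b-values
#' @return n x 3 matrix with columns `dist`, `abscos`, `db`
#' @export
edge_features <- function(q_i, q_j, b_i, b_j) {
  q_i <- rbind(q_i); q_j <- rbind(q_j)
  ni <- sqrt(rowSums(q_i^2)); nj <- sqrt(rowSums(q_j^2))
  if (any(ni == 0 | nj == 0)) stop("edge features are undefined at the q-space origin")
  cbind(dist = sqrt(rowSums((q_i - q_j)^2)),
        abscos = pmin(abs(rowSums(q_i * q_j)) / (ni * nj), 1),
        db = b_i - b_j)
}

#' Build the invariant q-space graph for one voxel
#'
#' Composition of b0 normalisation, antipodal mirroring, k-NN adjacency
#' and invariant feature computation. Node features are (E_i, b_i) only;
#' positions are kept solely for graph building and never enter the
#' network, which is what makes the downstream model O(3)-invariant.
#'
#' @param voxel a [voxel_data()] with at least one b0 and one DWI
#' @param config a [graph_config()]
#' @return an object of class `qgraph`: `node_features` (M x 2),
#'   `positions` (M x 3), `edges` (directed pairs, columns i, j),
#'   `edge_features` (per-edge 3-vectors), `M`
#' @export
build_graph <- function(voxel, config = graph_config()) {
  E <- normalise_signals(voxel)
  p <- voxel$protocol
  dwi <- p$b > 0
  if (!any(dwi)) stop("cannot build a graph without diffusion-weighted measurements")
  g <- cpp_build_qgraph(t(p$q[dwi, , drop = FALSE]), p$b[dwi], E[dwi],
                        config$k)
  colnames(g$edges) <- c("i", "j")
  colnames(g$edge_features) <- c("dist", "abscos", "db")
  colnames(g$node_features) <- c("E", "b")
  structure(list(node_features = g$node_features,
                 positions = g$positions,
                 edges = g$edges,
                 edge_features = g$edge_features,
                 M = nrow(g$node_features)),
            class = "qgraph")
}

#' @export
print.qgraph <- function(x, ...) {
  cat(sprintf("<qgraph: %d nodes, %d directed edges>\n", x$M, nrow(x$edges)))
  invisible(x)
}

#' Write a graph to node/edge tables
#'
#' Debugging export: two CSV files, one row per node and per directed edge.
#'
#' @param graph a [build_graph()] result
#' @param node_path,edge_path output CSV paths
#' @return invisibly, the two paths
#' @export
write_qgraph <- function(graph, node_path, edge_path) {
  stopifnot(inherits(graph, "qgraph"))
  nodes <- data.frame(graph$node_features, graph$positions)
  names(nodes) <- c("E", "b", "qx", "qy", "qz")
  write.csv(nodes, node_path, row.names = FALSE)
  write.csv(data.frame(graph$edges, graph$edge_features), edge_path,
            row.names = FALSE)
  invisible(c(node_path, edge_path))
}
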