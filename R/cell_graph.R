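#' Build the undirected k-NN cell-cell graph from a latent space
#'
#' Computes pairwise Euclidean distances between cells, links each cell to
#' its `k` nearest neighbours (self excluded; distance ties broken by
#' ascending cell index, so the graph is deterministic), and symmetrises the
#' directed neighbourhoods by union into an undirected edge set. Union
#' symmetrisation can only add edges, so every node keeps degree `>= k`.
#'
#' The object keeps both the undirected edge set (consumed by the
#' classifiers) and the directed `n x k` neighbour matrix (consumed by the
#' homogeneity metric, whose divisor is exactly `k`).
#'
#' @param latent an `n x p` coordinate matrix, a `trained_autoencoder`
#'   (its latent), or a `geometry_embedding` (its coordinates).
#' @param k number of nearest neighbours (default 15).
#' @param source provenance string recorded in the object.
#' @return an object of class `cell_graph`: `n_nodes`, `edges` (two-column
#'   matrix of undirected node pairs, lower index first), `neighbors`
#'   (`n x k` directed neighbour indices), `k`, `source`.
#' @export
knn_graph <- function(latent, k = 15, source = "latent") {
  X <- .as_feature_matrix(latent)
  n <- nrow(X)
  .assert(n > k, "need more cells (%d) than neighbours k = %d", n, k)
  .assert(all(is.finite(X)), "latent coordinates contain non-finite values")
  D <- .pairwise_dist(X)
  diag(D) <- Inf
  neighbors <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    ord <- order(D[i, ], seq_len(n))
    neighbors[i, ] <- ord[seq_len(k)]
  }
  src <- rep(seq_len(n), k)
  dst <- as.integer(neighbors)
  a <- pmin(src, dst); b <- pmax(src, dst)
  key <- (a - 1) * n + b
  keep <- !duplicated(key)
  ord <- order(a[keep], b[keep])
  edges <- cbind(from = a[keep][ord], to = b[keep][ord])
  structure(list(n_nodes = n, edges = edges, neighbors = neighbors,
                 k = as.integer(k), source = source),
            class = "cell_graph")
}

#' @export
print.cell_graph <- function(x, ...) {
  cat(sprintf("<cell_graph> %d nodes, %d undirected edges, k = %d (%s)\n",
              x$n_nodes, nrow(x$edges), x$k, x$source))
  invisible(x)
}

#' Node degrees of the undirected graph
#' @param g a `cell_graph`.
#' @return integer vector of length `n_nodes`.
#' @export
graph_degrees <- function(g) {
  tabulate(c(g$edges[, 1], g$edges[, 2]), nbins = g$n_nodes)
}

#' Write the edge list as TSV (+ JSON sidecar)
#'
#' Two 0-based node-index columns, one row per undirected edge, lower index
#' first; `k`, `n` and the provenance go to `<path>.json`.
#'
#' @param g a `cell_graph`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_edges_tsv <- function(g, path) {
  utils::write.table(
    data.frame(from = g$edges[, 1] - 1L, to = g$edges[, 2] - 1L),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  .write_json(list(k = g$k, n = g$n_nodes, source = g$source),
              paste0(path, ".json"))
  invisible(path)
}
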