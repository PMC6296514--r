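# Segregation and integration measures for binary undirected networks.
# Conventions follow the standard binary-undirected formulas used throughout
# the functional-connectivity literature: disconnected node pairs contribute
# zero inverse distance to global efficiency, isolated nodes stay in the node
# set, and modularity is maximized over partitions at a resolution parameter.

as_adjacency <- function(net) {
  adj <- if (inherits(net, "binary_network")) net$adjacency else as.matrix(net)
  check_square_symmetric(adj, "adjacency")
  if (!all(adj %in% c(0, 1))) stop2("adjacency must be binary (0/1)")
  diag(adj) <- 0
  adj
}

#' Newman modularity of a given partition
#'
#' Evaluates \eqn{Q = (1/2m) \sum_{ij} [a_{ij} - \gamma k_i k_j / (2m)]
#' \delta(c_i, c_j)} for a fixed community assignment; no optimization.
#'
#' @param net A `binary_network` or 0/1 adjacency matrix.
#' @param membership Integer vector of community labels, one per node.
#' @param resolution Resolution parameter \eqn{\gamma}; 1 recovers classical
#'   Newman modularity.
#' @return The modularity value Q of that partition.
#' @export
partition_modularity <- function(net, membership, resolution = 1) {
  adj <- as_adjacency(net)
  k <- rowSums(adj)
  two_m <- sum(k)
  if (two_m == 0) stop2("modularity undefined for an edgeless network (2m = 0)")
  same <- outer(membership, membership, "==")
  sum((adj - resolution * outer(k, k) / two_m) * same) / two_m
}

#' Maximized modularity (Q) of a binary network
#'
#' Searches for the community partition maximizing Newman modularity using a
#' seeded greedy multi-level (Louvain) search with restarts, and returns the
#' best Q found together with the achieving partition. Q is always recomputed
#' from the returned partition with [partition_modularity()], so the value and
#' the partition are guaranteed consistent. The search is a heuristic: on
#' small graphs it can (rarely) fall short of the exhaustive optimum.
#'
#' @param net A `binary_network` or 0/1 adjacency matrix with at least 1 edge.
#' @param resolution Resolution parameter; default 1.
#' @param seed Integer seed controlling the stochastic search.
#' @param restarts Number of independent search restarts (best Q kept).
#' @return A `metric_value` list: `name`, `value` (Q), `partition`, `seed`.
#' @export
net_modularity <- function(net, resolution = 1, seed = 1L, restarts = 10L) {
  adj <- as_adjacency(net)
  if (sum(adj) == 0) stop2("modularity undefined for an edgeless network (2m = 0)")
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  best_q <- -Inf
  best_mem <- NULL
  for (i in seq_len(restarts)) {
    mem <- with_seed(derive_seed(seed, "louvain", i), {
      # random vertex permutation varies the greedy pass order across restarts
      perm <- sample.int(igraph::vcount(g))
      gp <- igraph::permute(g, perm)
      cl <- igraph::cluster_louvain(gp, resolution = resolution)
      igraph::membership(cl)[perm]
    })
    q <- partition_modularity(adj, mem, resolution)
    if (q > best_q) { best_q <- q; best_mem <- mem }
  }
  structure(list(name = "modularity", value = best_q,
                 partition = as.integer(best_mem), seed = seed),
            class = "metric_value")
}

#' Transitivity (ratio of triangles to triplets)
#'
#' \eqn{T = \sum_i 2 t_i / \sum_i k_i (k_i - 1)} where \eqn{t_i} is the
#' number of triangles containing node i and \eqn{k_i} its degree. A network
#' with no node of degree >= 2 has no triplets; by convention T = 0 is
#' returned (with a logged note).
#'
#' @param net A `binary_network` or 0/1 adjacency matrix.
#' @param quiet Suppress the degenerate-case note.
#' @return A `metric_value` with the transitivity in [0, 1].
#' @export
net_transitivity <- function(net, quiet = FALSE) {
  adj <- as_adjacency(net)
  k <- rowSums(adj)
  denom <- sum(k * (k - 1))
  if (denom == 0) {
    if (!quiet) message("net_transitivity: no connected triplets; returning 0 by convention")
    val <- 0
  } else {
    val <- sum(diag(adj %*% adj %*% adj)) / denom  # trace(A^3) = sum_i 2 t_i
  }
  structure(list(name = "transitivity", value = val), class = "metric_value")
}

#' Binary shortest-path length matrix (breadth-first search)
#'
#' @param net A `binary_network` or 0/1 adjacency matrix.
#' @return Symmetric integer distance matrix with zero diagonal and `Inf` for
#'   disconnected pairs.
#' @export
shortest_path_lengths <- function(net) {
  adj <- as_adjacency(net)
  n <- nrow(adj)
  nbrs <- lapply(seq_len(n), function(i) which(adj[i, ] == 1))
  d <- matrix(Inf, n, n, dimnames = dimnames(adj))
  diag(d) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    depth <- 0L
    while (length(frontier)) {
      depth <- depth + 1L
      nxt <- unique(unlist(nbrs[frontier], use.names = FALSE))
      nxt <- nxt[!is.finite(d[s, nxt])]
      if (!length(nxt)) break
      d[s, nxt] <- depth
      frontier <- nxt
    }
  }
  d
}

#' Global efficiency of a binary network
#'
#' The average inverse shortest-path length over all ordered node pairs,
#' \eqn{E = \frac{1}{n(n-1)} \sum_{i \ne j} 1/d_{ij}}, with \eqn{1/d_{ij} = 0}
#' for disconnected pairs. E = 1 for a complete graph, 0 for an edgeless one.
#'
#' @param net A `binary_network` or 0/1 adjacency matrix (>= 2 nodes).
#' @return A `metric_value` with the efficiency in [0, 1].
#' @export
net_global_efficiency <- function(net) {
  adj <- as_adjacency(net)
  n <- nrow(adj)
  if (n < 2L) stop2("global efficiency needs at least 2 nodes")
  d <- shortest_path_lengths(adj)
  inv <- 1 / d
  diag(inv) <- 0
  structure(list(name = "global_efficiency", value = sum(inv) / (n * (n - 1))),
            class = "metric_value")
}

#' @export
print.metric_value <- function(x, ...) {
  cat(sprintf("<metric_value> %s = %.6g\n", x$name, x$value))
  invisible(x)
}

#' All three network measures of one binary network
#'
#' @inheritParams net_modularity
#' @return Named numeric vector: modularity, transitivity, global_efficiency.
#' @export
network_metrics <- function(net, resolution = 1, seed = 1L, restarts = 10L) {
  c(modularity = net_modularity(net, resolution, seed, restarts)$value,
    transitivity = net_transitivity(net, quiet = TRUE)$value,
    global_efficiency = net_global_efficiency(net)$value)
}
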