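#' Construct a binary undirected network
#'
#' Validates an adjacency matrix (symmetric, entries 0/1, zero diagonal) and
#' wraps it with node labels. Used directly for synthetic benchmark graphs;
#' thresholded correlation matrices come from [binarize()].
#'
#' @param adjacency Square 0/1 matrix, symmetric with zero diagonal.
#' @param labels Node labels (default: row names or `CH01`, ...).
#' @param threshold Threshold that produced the network, if any.
#' @return A `nirs_network`.
#' @export
nirs_network <- function(adjacency, labels = NULL, threshold = NA_real_) {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency)) abort("Adjacency must be square.")
  if (!all(adjacency %in% c(0, 1))) abort("Adjacency entries must be 0 or 1.")
  if (!isTRUE(all(adjacency == t(adjacency)))) {
    abort("Adjacency must be symmetric (undirected network).")
  }
  if (any(diag(adjacency) != 0)) abort("Self-loops are not allowed.")
  if (is.null(labels)) {
    labels <- rownames(adjacency)
    if (is.null(labels)) labels <- sprintf("CH%02d", seq_len(nrow(adjacency)))
  }
  storage.mode(adjacency) <- "integer"
  dimnames(adjacency) <- list(labels, labels)
  structure(list(labels = labels, adjacency = adjacency,
                 threshold = threshold),
            class = "nirs_network")
}

#' @export
print.nirs_network <- function(x, ...) {
  cat(sprintf("<nirs_network> %d nodes, %d edges%s\n",
              length(x$labels), n_edges(x),
              if (!is.na(x$threshold)) sprintf(" (T = %g)", x$threshold) else ""))
  invisible(x)
}

n_edges <- function(net) sum(net$adjacency) / 2L

#' Binarize a correlation matrix at a threshold
#'
#' Thresholds the absolute correlation: nodes i and j are connected iff
#' `|r(i, j)| >= T` (the boundary value produces an edge; strong negative
#' correlations also produce edges). The diagonal never yields an edge.
#'
#' @param matrix A `nirs_corrmat`, or a plain symmetric correlation matrix.
#' @param threshold Threshold T in (0, 1).
#' @return A `nirs_network`.
#' @examples
#' m <- as_corrmat(matrix(c(1, .5, .2, .5, 1, -.3, .2, -.3, 1), 3, 3))
#' n_edges_at <- function(T) sum(binarize(m, T)$adjacency) / 2
#' n_edges_at(0.275)  # 2 edges: |r| = 0.5 and 0.3
#' n_edges_at(0.5)    # 1 edge (boundary |r| = T included)
#' @export
binarize <- function(matrix, threshold) {
  if (!inherits(matrix, "nirs_corrmat")) matrix <- as_corrmat(matrix)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    abort("`threshold` must be a single value in (0, 1).")
  }
  adj <- (abs(matrix$values) >= threshold) * 1L
  diag(adj) <- 0L
  nirs_network(adj, labels = matrix$labels, threshold = threshold)
}

#' Network clustering coefficient
#'
#' Mean over all N nodes of the local clustering coefficient
#' \eqn{C_i = E_i / (k_i (k_i - 1) / 2)}, where \eqn{k_i} is the degree of
#' node i and \eqn{E_i} the number of edges among its neighbors. Nodes with
#' degree < 2 contribute 0 (the ratio is undefined there).
#'
#' @param net A `nirs_network`.
#' @return C in \[0, 1\] (0 for an empty graph).
#' @export
clustering_coefficient <- function(net) {
  stopifnot(inherits(net, "nirs_network"))
  cpp_graph_metrics(net$adjacency)$C
}

#' Average shortest path length
#'
#' Mean geodesic (breadth-first-search) distance over all unordered pairs of
#' nodes that are connected by some path. For disconnected networks the mean
#' is taken over reachable pairs only; whether every pair was reachable is
#' reported by [network_metrics()]'s `connected` flag.
#'
#' @param net A `nirs_network` with at least one edge.
#' @return L >= 1.
#' @export
average_path_length <- function(net) {
  stopifnot(inherits(net, "nirs_network"))
  if (n_edges(net) == 0) {
    abort("Network has no edges: no finite paths exist.")
  }
  cpp_graph_metrics(net$adjacency)$L
}

#' Average node degree
#'
#' Mean of the node degrees, equal to `2 * E / N` — the density index of the
#' network.
#'
#' @param net A `nirs_network`.
#' @return K_mean in \[0, N - 1\].
#' @export
average_degree <- function(net) {
  stopifnot(inherits(net, "nirs_network"))
  cpp_graph_metrics(net$adjacency)$K_mean
}

#' All characteristic indices of one network
#'
#' Computes the clustering coefficient C, average path length L (over
#' reachable pairs), average node degree K_mean, and connectivity flag in a
#' single pass.
#'
#' @param net A `nirs_network`.
#' @return One-row tibble: `threshold`, `n_nodes`, `n_edges`, `C`, `L`,
#'   `K_mean`, `connected`. `L` is `NA` for an edgeless network.
#' @export
network_metrics <- function(net) {
  stopifnot(inherits(net, "nirs_network"))
  m <- cpp_graph_metrics(net$adjacency)
  tibble::tibble(
    threshold = net$threshold,
    n_nodes = length(net$labels),
    n_edges = n_edges(net),
    C = m$C,
    L = m$L,
    K_mean = m$K_mean,
    connected = m$connected
  )
}

#' Geodesic distance matrix
#'
#' Breadth-first-search shortest-path distances between all node pairs.
#'
#' @param net A `nirs_network`.
#' @return Integer matrix of distances; unreachable pairs are `NA`.
#' @export
distance_matrix <- function(net) {
  stopifnot(inherits(net, "nirs_network"))
  d <- cpp_bfs_distances(net$adjacency)
  d[d < 0] <- NA_integer_
  dimnames(d) <- list(net$labels, net$labels)
  d
}

#' Ring-lattice and Watts-Strogatz benchmark graphs
#'
#' `make_ring_lattice()` places `n` nodes on a ring, each connected to its
#' `k` nearest neighbors (`k/2` on each side). `make_small_world()` then
#' rewires each lattice edge independently with probability `p`: the far
#' endpoint is replaced by a uniformly random node, skipping rewirings that
#' would create a self-loop or duplicate edge. With small `p` this yields the
#' classic small-world regime: clustering close to the lattice's, path length
#' close to a random graph's.
#'
#' @param n Number of nodes.
#' @param k Even number of nearest neighbors per node.
#' @param p Rewiring probability in \[0, 1\].
#' @param seed Optional seed; otherwise the current RNG state is used.
#' @return A `nirs_network`.
#' @export
make_ring_lattice <- function(n, k) {
  if (k %% 2 != 0 || k < 2 || k >= n) {
    abort("`k` must be an even integer with 2 <= k < n.")
  }
  adj <- matrix(0L, n, n)
  for (j in seq_len(k / 2)) {
    for (i in seq_len(n)) {
      tgt <- ((i - 1 + j) %% n) + 1
      adj[i, tgt] <- 1L
      adj[tgt, i] <- 1L
    }
  }
  nirs_network(adj, labels = sprintf("N%02d", seq_len(n)))
}

#' @rdname make_ring_lattice
#' @export
make_small_world <- function(n, k, p, seed = NULL) {
  net <- make_ring_lattice(n, k)
  rewire_one <- function(adj) {
    edges <- which(upper.tri(adj) & adj == 1L, arr.ind = TRUE)
    for (e in seq_len(nrow(edges))) {
      if (runif(1) < p) {
        i <- edges[e, 1]; j <- edges[e, 2]
        new_j <- sample.int(n, 1)
        if (new_j != i && new_j != j && adj[i, new_j] == 0L) {
          adj[i, j] <- adj[j, i] <- 0L
          adj[i, new_j] <- adj[new_j, i] <- 1L
        }
      }
    }
    adj
  }
  adj <- if (is.null(seed)) {
    rewire_one(net$adjacency)
  } else {
    withr::with_seed(seed, rewire_one(net$adjacency))
  }
  nirs_network(adj, labels = net$labels)
}
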