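#' Degree-preserving Markov-chain rewiring
#'
#' Randomizes a network by the standard double-edge-swap Markov chain: each
#' attempt draws two edges (a, b) and (c, d) and replaces them with (a, d)
#' and (c, b) unless that would create a self-loop or a duplicate edge.
#' Rejected proposals still count toward `n_attempts`, so the chain consumes
#' a fixed number of RNG draws and is reproducible across runs given the same
#' seed. Every node keeps its exact degree, making the result a sample from
#' the degree-preserving null model.
#'
#' @param net A `nirs_network` with at least 2 edges.
#' @param n_attempts Number of attempted swaps; default `ceiling(10 * E)`, a
#'   conventional mixing heuristic for the chain.
#' @param seed Optional seed (applied locally); otherwise the current RNG
#'   state is used and advanced.
#' @return A `nirs_network` with the identical degree sequence.
#' @export
rewire_network <- function(net, n_attempts = NULL, seed = NULL) {
  stopifnot(inherits(net, "nirs_network"))
  e <- n_edges(net)
  if (e < 2) abort("Rewiring needs at least 2 edges.")
  if (is.null(n_attempts)) n_attempts <- ceiling(10 * e)
  run <- function() cpp_double_edge_swap(net$adjacency, as.integer(n_attempts))
  adj <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  nirs_network(adj, labels = net$labels, threshold = net$threshold)
}

#' Random reference ensemble for small-world analysis
#'
#' Generates `n_random` independent degree-preserving randomizations of the
#' source network (each a fresh double-edge-swap chain of
#' `ceiling(swap_factor * E)` attempts starting from the source), computes C
#' and L for every member, and reports the ensemble means `C_rand` and
#' `L_rand` used as the random-network reference in the small-worldness
#' measure. Disconnected members are kept, with L computed over reachable
#' pairs, and counted.
#'
#' @param net A `nirs_network` with at least 2 edges.
#' @param n_random Ensemble size (default 100).
#' @param seed Optional seed for the whole ensemble (applied locally).
#' @param swap_factor Attempted swaps per edge for each member (default 10).
#' @return A `nirs_null` list: `n_random`, `C_rand`, `L_rand`,
#'   `per_network` (tibble of per-member C, L, connected),
#'   `n_disconnected`, `n_attempts`, `seed`.
#' @export
null_ensemble <- function(net, n_random = 100, seed = NULL, swap_factor = 10) {
  stopifnot(inherits(net, "nirs_network"))
  if (n_edges(net) < 2) abort("Null ensemble needs at least 2 edges.")
  if (n_random < 1) abort("`n_random` must be >= 1.")
  run <- function() cpp_null_ensemble(net$adjacency, as.integer(n_random),
                                      swap_factor)
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  per <- tibble::tibble(replicate = seq_len(n_random),
                        C = res$C, L = res$L, connected = res$connected)
  structure(list(n_random = n_random,
                 C_rand = mean(res$C),
                 L_rand = mean(res$L),
                 per_network = per,
                 n_disconnected = sum(!res$connected),
                 n_attempts = res$n_attempts,
                 seed = seed),
            class = "nirs_null")
}

#' @export
print.nirs_null <- function(x, ...) {
  cat(sprintf("<nirs_null> %d networks: C_rand = %.4f, L_rand = %.4f (%d disconnected)\n",
              x$n_random, x$C_rand, x$L_rand, x$n_disconnected))
  invisible(x)
}

#' Small-worldness measure
#'
#' \eqn{\sigma = (C / C_{rand}) / (L / L_{rand})}: the clustering ratio of
#' the network to its degree-preserving random reference, divided by the
#' path-length ratio. A network is called small-world when \eqn{\sigma > 1}
#' — more clustered than random while keeping near-random path lengths.
#'
#' @param C,L Clustering coefficient and average path length of the network.
#' @param C_rand,L_rand Reference means from [null_ensemble()] (or a
#'   `nirs_null` object passed as `C_rand`, in which case `L_rand` is taken
#'   from it).
#' @return The scalar sigma.
#' @export
small_worldness <- function(C, L, C_rand, L_rand = NULL) {
  if (inherits(C_rand, "nirs_null")) {
    null <- C_rand
    C_rand <- null$C_rand
    L_rand <- null$L_rand
  }
  vals <- c(C = C, L = L, C_rand = C_rand, L_rand = L_rand)
  if (any(!is.finite(vals))) {
    abort("Non-finite input to small_worldness (graph too sparse for a null reference?).")
  }
  if (C_rand <= 0) abort("C_rand must be positive: the random reference has no triangles (graph too sparse).")
  if (L_rand <= 0 || L <= 0) abort("Path lengths must be positive.")
  (C / C_rand) / (L / L_rand)
}
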