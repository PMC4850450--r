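# Brute-force reference implementations, independent of the package's
# computational path. Deliberately written as plain loops.

# Exhaustive neighbour-pair triangle counting.
oracle_clustering <- function(adj) {
  n <- nrow(adj)
  if (n == 0) return(0)
  total <- 0
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    links <- 0
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        if (adj[nb[a], nb[b]] == 1) links <- links + 1
      }
    }
    total <- total + links / (k * (k - 1) / 2)
  }
  total / n
}

# All-pairs BFS; mean geodesic over reachable unordered pairs.
oracle_apl <- function(adj) {
  n <- nrow(adj)
  dists <- c()
  for (src in seq_len(n)) {
    d <- rep(-1L, n)
    d[src] <- 0L
    queue <- src
    while (length(queue) > 0) {
      u <- queue[1]
      queue <- queue[-1]
      for (v in which(adj[u, ] == 1)) {
        if (d[v] < 0) {
          d[v] <- d[u] + 1L
          queue <- c(queue, v)
        }
      }
    }
    reach <- which(d > 0)
    dists <- c(dists, d[reach[reach > src]])
  }
  if (length(dists) == 0) return(NA_real_)
  mean(dists)
}

oracle_edge_count <- function(adj) sum(adj[upper.tri(adj)])

# Textbook covariance / standard-deviation Pearson formula.
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  num / (sqrt(sum((x - mean(x))^2) / (n - 1)) *
           sqrt(sum((y - mean(y))^2) / (n - 1)))
}

# Closed-form two-sample t statistics.
oracle_t_welch <- function(a, b) {
  (mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
}
oracle_t_pooled <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# Random simple undirected graph as a 0/1 adjacency matrix.
random_adj <- function(n, p) {
  adj <- matrix(0L, n, n)
  up <- upper.tri(adj)
  adj[up] <- as.integer(runif(sum(up)) < p)
  adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
  adj
}
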