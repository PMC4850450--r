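complete_net <- function(n) {
  adj <- matrix(1L, n, n)
  diag(adj) <- 0L
  nirs_network(adj)
}

test_that("binarization applies |r| >= T including the boundary", {
  v <- matrix(c(1, 0.5, 0.2,
                0.5, 1, -0.3,
                0.2, -0.3, 1), 3, 3)
  m <- as_corrmat(v)
  n1 <- binarize(m, 0.275)
  expect_equal(sum(n1$adjacency) / 2, 2)  # edges 1-2 and 2-3
  expect_equal(n1$adjacency[1, 2], 1L)
  expect_equal(n1$adjacency[2, 3], 1L)    # negative correlation counts
  expect_equal(n1$adjacency[1, 3], 0L)
  n2 <- binarize(m, 0.5)
  expect_equal(sum(n2$adjacency) / 2, 1)  # |r| = T is an edge
  expect_equal(n2$adjacency[1, 2], 1L)
  expect_error(binarize(m, 0), "\\(0, 1\\)")
  expect_error(binarize(m, 1), "\\(0, 1\\)")
})

test_that("binarization edge count matches exhaustive comparison on 24x24", {
  set.seed(8)
  v <- cor(matrix(rnorm(60 * 24), ncol = 24))
  net <- binarize(as_corrmat(v), 0.275)
  manual <- 0
  for (i in 1:23) for (j in (i + 1):24) {
    if (abs(v[i, j]) >= 0.275) manual <- manual + 1
  }
  expect_equal(sum(net$adjacency) / 2, manual)
  expect_equal(diag(net$adjacency), rep(0L, 24), ignore_attr = TRUE)
})

test_that("binarization is monotone in the threshold", {
  set.seed(9)
  v <- cor(matrix(rnorm(60 * 12), ncol = 12))
  m <- as_corrmat(v)
  for (pair in list(c(0.2, 0.4), c(0.3, 0.6), c(0.5, 0.9))) {
    lo <- binarize(m, pair[1])$adjacency
    hi <- binarize(m, pair[2])$adjacency
    expect_true(all(hi <= lo))
  }
})

test_that("clustering coefficient: closed-form graphs and brute force", {
  expect_equal(clustering_coefficient(complete_net(4)), 1)
  star <- matrix(0L, 5, 5)
  star[1, 2:5] <- 1L
  star[2:5, 1] <- 1L
  expect_equal(clustering_coefficient(nirs_network(star)), 0)
  set.seed(10)
  for (i in 1:10) {
    adj <- random_adj(10, 0.5)
    expect_equal(clustering_coefficient(nirs_network(adj)),
                 oracle_clustering(adj), tolerance = 1e-12)
  }
})

test_that("average path length: closed-form graphs and BFS oracle", {
  expect_equal(average_path_length(complete_net(5)), 1)
  ring4 <- make_ring_lattice(4, 2)
  expect_equal(average_path_length(ring4), 4 / 3)
  set.seed(11)
  reps <- 0
  while (reps < 10) {
    adj <- random_adj(12, 0.3)
    apl <- oracle_apl(adj)
    if (is.na(apl)) next
    expect_equal(average_path_length(nirs_network(adj)), apl,
                 tolerance = 1e-12)
    reps <- reps + 1
  }
  empty <- nirs_network(matrix(0L, 4, 4))
  expect_error(average_path_length(empty), "no finite paths")
})

test_that("average degree equals 2E/N", {
  expect_equal(average_degree(complete_net(4)), 3)
  expect_equal(average_degree(nirs_network(matrix(0L, 6, 6))), 0)
  set.seed(12)
  for (i in 1:5) {
    adj <- random_adj(15, 0.4)
    expect_equal(average_degree(nirs_network(adj)),
                 2 * oracle_edge_count(adj) / 15)
  }
})

test_that("metrics are invariant under node relabeling", {
  set.seed(13)
  adj <- random_adj(12, 0.4)
  perm <- sample(12)
  net <- nirs_network(adj)
  netp <- nirs_network(adj[perm, perm])
  expect_equal(clustering_coefficient(netp), clustering_coefficient(net))
  expect_equal(average_degree(netp), average_degree(net))
  m <- network_metrics(net)
  mp <- network_metrics(netp)
  expect_equal(mp$L, m$L)
  expect_equal(mp$connected, m$connected)
})

test_that("adding an edge never increases the path length", {
  set.seed(14)
  checked <- 0
  while (checked < 10) {
    adj <- random_adj(10, 0.35)
    net <- nirs_network(adj)
    m <- network_metrics(net)
    if (!m$connected || m$n_edges == 0) next
    absent <- which(adj == 0 & upper.tri(adj), arr.ind = TRUE)
    if (nrow(absent) == 0) next
    pick <- absent[sample(nrow(absent), 1), ]
    adj2 <- adj
    adj2[pick[1], pick[2]] <- adj2[pick[2], pick[1]] <- 1L
    expect_lte(average_path_length(nirs_network(adj2)),
               average_path_length(net))
    checked <- checked + 1
  }
})

test_that("metrics agree with igraph on random graphs", {
  set.seed(15)
  for (i in 1:10) {
    adj <- random_adj(14, 0.35)
    if (oracle_edge_count(adj) == 0) next
    net <- nirs_network(adj)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    expect_equal(clustering_coefficient(net),
                 igraph::transitivity(g, type = "localaverage",
                                      isolates = "zero"),
                 tolerance = 1e-12)
    expect_equal(average_path_length(net),
                 igraph::mean_distance(g, unconnected = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("ring lattice and small-world generators produce valid graphs", {
  rl <- make_ring_lattice(24, 4)
  expect_equal(sum(rl$adjacency) / 2, 48)
  expect_true(all(rowSums(rl$adjacency) == 4))
  expect_equal(clustering_coefficient(rl), 0.5)  # 3(k-2)/(4(k-1)) for k = 4
  ws <- make_small_world(24, 4, 0.1, seed = 1)
  expect_equal(sum(ws$adjacency) / 2, 48)  # rewiring preserves edge count
  expect_identical(ws$adjacency, make_small_world(24, 4, 0.1, seed = 1)$adjacency)
  expect_error(make_ring_lattice(10, 3), "even")
})

test_that("network constructor rejects malformed adjacency", {
  expect_error(nirs_network(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
  expect_error(nirs_network(matrix(c(1, 1, 1, 1), 2, 2)), "Self-loops")
  expect_error(nirs_network(matrix(c(0, 2, 2, 0), 2, 2)), "0 or 1")
})
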