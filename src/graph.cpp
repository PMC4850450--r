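#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Internal helpers operate on adjacency lists (0-based).

static std::vector<std::vector<int>> adj_list(const IntegerMatrix& adj) {
  int n = adj.nrow();
  std::vector<std::vector<int>> nbrs(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && adj(i, j) != 0) nbrs[i].push_back(j);
  return nbrs;
}

// Mean over nodes of (edges among neighbours) / (k(k-1)/2); degree < 2 -> 0.
static double clustering(const std::vector<std::vector<int>>& nbrs,
                         const IntegerMatrix& adj) {
  int n = (int) nbrs.size();
  if (n == 0) return 0.0;
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    int k = (int) nbrs[i].size();
    if (k < 2) continue;
    int links = 0;
    for (int a = 0; a < k; ++a)
      for (int b = a + 1; b < k; ++b)
        if (adj(nbrs[i][a], nbrs[i][b]) != 0) ++links;
    total += (2.0 * links) / ((double) k * (k - 1));
  }
  return total / n;
}

// BFS distances from one source; -1 marks unreachable.
static void bfs(int src, const std::vector<std::vector<int>>& nbrs,
                std::vector<int>& dist) {
  std::fill(dist.begin(), dist.end(), -1);
  dist[src] = 0;
  std::queue<int> q;
  q.push(src);
  while (!q.empty()) {
    int u = q.front(); q.pop();
    for (int v : nbrs[u]) {
      if (dist[v] < 0) { dist[v] = dist[u] + 1; q.push(v); }
    }
  }
}

// Mean geodesic over reachable unordered pairs. `connected` reports whether
// every pair was reachable. Returns NA when no finite path exists at all.
static double path_length(const std::vector<std::vector<int>>& nbrs,
                          bool& connected) {
  int n = (int) nbrs.size();
  long long n_reach = 0;
  double total = 0.0;
  std::vector<int> dist(n);
  for (int i = 0; i < n; ++i) {
    bfs(i, nbrs, dist);
    for (int j = i + 1; j < n; ++j) {
      if (dist[j] > 0) { total += dist[j]; ++n_reach; }
    }
  }
  long long n_pairs = (long long) n * (n - 1) / 2;
  connected = (n_reach == n_pairs && n_pairs > 0);
  if (n_reach == 0) return NA_REAL;
  return total / n_reach;
}

// [[Rcpp::export]]
List cpp_graph_metrics(IntegerMatrix adj) {
  std::vector<std::vector<int>> nbrs = adj_list(adj);
  int n = adj.nrow();
  long long deg_sum = 0;
  for (int i = 0; i < n; ++i) deg_sum += (long long) nbrs[i].size();
  bool connected = false;
  double L = path_length(nbrs, connected);
  return List::create(
    _["C"] = clustering(nbrs, adj),
    _["L"] = L,
    _["K_mean"] = n > 0 ? (double) deg_sum / n : 0.0,
    _["connected"] = connected);
}

// [[Rcpp::export]]
IntegerMatrix cpp_bfs_distances(IntegerMatrix adj) {
  std::vector<std::vector<int>> nbrs = adj_list(adj);
  int n = adj.nrow();
  IntegerMatrix out(n, n);
  std::vector<int> dist(n);
  for (int i = 0; i < n; ++i) {
    bfs(i, nbrs, dist);
    for (int j = 0; j < n; ++j) out(i, j) = dist[j];
  }
  return out;
}

// One Markov-chain double-edge-swap pass over an edge list (0-based, E x 2).
// Each attempt draws two distinct edges (a,b),(c,d) and proposes (a,d),(c,b);
// proposals creating a self-loop or a multi-edge are rejected but still count
// toward n_attempts, so the chain consumes a fixed number of RNG draws.
// Uses R's RNG: results are reproducible under set.seed().
static void swap_chain(std::vector<int>& eu, std::vector<int>& ev,
                       std::vector<signed char>& adj, int n, int n_attempts) {
  int E = (int) eu.size();
  for (int it = 0; it < n_attempts; ++it) {
    int e1 = (int) (unif_rand() * E);
    int e2 = (int) (unif_rand() * E);
    if (e1 >= E) e1 = E - 1;
    if (e2 >= E) e2 = E - 1;
    if (e1 == e2) continue;
    int a = eu[e1], b = ev[e1], c = eu[e2], d = ev[e2];
    if (a == d || c == b) continue;
    if (adj[(size_t) a * n + d] || adj[(size_t) c * n + b]) continue;
    adj[(size_t) a * n + b] = adj[(size_t) b * n + a] = 0;
    adj[(size_t) c * n + d] = adj[(size_t) d * n + c] = 0;
    adj[(size_t) a * n + d] = adj[(size_t) d * n + a] = 1;
    adj[(size_t) c * n + b] = adj[(size_t) b * n + c] = 1;
    ev[e1] = d;
    ev[e2] = b;
  }
}

static void edges_from_adj(const IntegerMatrix& adj, std::vector<int>& eu,
                           std::vector<int>& ev, std::vector<signed char>& flat) {
  int n = adj.nrow();
  flat.assign((size_t) n * n, 0);
  eu.clear(); ev.clear();
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (adj(i, j) != 0) {
        eu.push_back(i); ev.push_back(j);
        flat[(size_t) i * n + j] = flat[(size_t) j * n + i] = 1;
      }
}

// [[Rcpp::export]]
IntegerMatrix cpp_double_edge_swap(IntegerMatrix adj, int n_attempts) {
  int n = adj.nrow();
  std::vector<int> eu, ev;
  std::vector<signed char> flat;
  edges_from_adj(adj, eu, ev, flat);
  swap_chain(eu, ev, flat, n, n_attempts);
  IntegerMatrix out(n, n);
  for (size_t e = 0; e < eu.size(); ++e) {
    out(eu[e], ev[e]) = 1;
    out(ev[e], eu[e]) = 1;
  }
  return out;
}

// Full null ensemble in one call: n_random independent rewirings of `adj`,
// each a fresh chain of ceil(swap_factor * E) attempts from the source graph,
// with C and L computed per member.
// [[Rcpp::export]]
List cpp_null_ensemble(IntegerMatrix adj, int n_random, double swap_factor) {
  int n = adj.nrow();
  std::vector<int> eu0, ev0;
  std::vector<signed char> flat0;
  edges_from_adj(adj, eu0, ev0, flat0);
  int E = (int) eu0.size();
  int n_attempts = (int) std::ceil(swap_factor * E);
  NumericVector Cs(n_random), Ls(n_random);
  LogicalVector conn(n_random);
  for (int r = 0; r < n_random; ++r) {
    std::vector<int> eu = eu0, ev = ev0;
    std::vector<signed char> flat = flat0;
    swap_chain(eu, ev, flat, n, n_attempts);
    IntegerMatrix a(n, n);
    for (size_t e = 0; e < eu.size(); ++e) {
      a(eu[e], ev[e]) = 1;
      a(ev[e], eu[e]) = 1;
    }
    std::vector<std::vector<int>> nbrs = adj_list(a);
    bool c_flag = false;
    Cs[r] = clustering(nbrs, a);
    Ls[r] = path_length(nbrs, c_flag);
    conn[r] = c_flag;
  }
  return List::create(_["C"] = Cs, _["L"] = Ls, _["connected"] = conn,
                      _["n_attempts"] = n_attempts);
}
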