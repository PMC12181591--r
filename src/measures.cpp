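// Graph-measure kernels for binarized correlation networks.
//
// Networks are small (47 nodes by default) but measures are evaluated
// across a 41-point density sweep inside permutation loops, so the
// per-graph cost must stay in the microsecond range. Neighborhoods are
// kept both as adjacency lists (BFS) and as bitsets (triangle counting,
// induced subgraphs).

#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Graph {
  int n;
  int words;
  std::vector<std::vector<int>> adj;
  std::vector<std::vector<uint64_t>> mask;

  explicit Graph(int n_)
      : n(n_), words((n_ + 63) / 64), adj(n_),
        mask(n_, std::vector<uint64_t>((n_ + 63) / 64, 0)) {}

  bool has_edge(int u, int v) const {
    return (mask[u][v >> 6] >> (v & 63)) & 1ULL;
  }
  void add_edge(int u, int v) {
    adj[u].push_back(v);
    adj[v].push_back(u);
    mask[u][v >> 6] |= 1ULL << (v & 63);
    mask[v][u >> 6] |= 1ULL << (u & 63);
  }
};

inline int popcount64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int c = 0;
  while (x) { x &= x - 1; ++c; }
  return c;
#endif
}

// BFS from src; dist must be sized n and is overwritten (-1 = unreached).
void bfs(const Graph& g, int src, std::vector<int>& dist,
         std::vector<int>& queue) {
  std::fill(dist.begin(), dist.end(), -1);
  dist[src] = 0;
  queue.clear();
  queue.push_back(src);
  for (size_t qi = 0; qi < queue.size(); ++qi) {
    int u = queue[qi];
    for (int v : g.adj[u]) {
      if (dist[v] < 0) {
        dist[v] = dist[u] + 1;
        queue.push_back(v);
      }
    }
  }
}

struct GlobalStats {
  double geff;        // mean of 1/d over ordered pairs (0 if unreachable)
  double clustering;  // mean local clustering, 0 for degree < 2
  double pathlen;     // mean d over reachable ordered pairs (NaN if none)
  double unreachable; // count of unreachable ordered pairs
};

inline int ctz64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_ctzll(x);
#else
  int c = 0;
  while (!(x & 1ULL)) { x >>= 1; ++c; }
  return c;
#endif
}

// Single-word fast path (n <= 64): frontier-expansion BFS and triangle
// counting entirely on bitmasks.
GlobalStats global_stats1(const Graph& g) {
  const int n = g.n;
  double inv_sum = 0.0, d_sum = 0.0, cl = 0.0;
  long reach = 0;
  for (int s = 0; s < n; ++s) {
    const uint64_t ms = g.mask[s][0];
    uint64_t visited = (1ULL << s) | ms;
    uint64_t frontier = ms;
    int level = 1;
    while (frontier) {
      int c = popcount64(frontier);
      inv_sum += (double)c / level;
      d_sum += (double)c * level;
      reach += c;
      uint64_t next = 0, f = frontier;
      while (f) {
        int v = ctz64(f);
        f &= f - 1;
        next |= g.mask[v][0];
      }
      frontier = next & ~visited;
      visited |= next;
      ++level;
    }
    int k = popcount64(ms);
    if (k >= 2) {
      long links = 0;
      uint64_t f = ms;
      while (f) {
        int v = ctz64(f);
        f &= f - 1;
        links += popcount64(ms & g.mask[v][0]);
      }
      cl += (double)links / ((double)k * (k - 1));
    }
  }
  GlobalStats st;
  st.geff = n > 1 ? inv_sum / ((double)n * (n - 1)) : 0.0;
  st.clustering = n > 0 ? cl / n : 0.0;
  st.pathlen = reach > 0 ? d_sum / reach : R_NaN;
  st.unreachable = (double)(n * (long)(n - 1) - reach);
  return st;
}

GlobalStats global_stats(const Graph& g) {
  if (g.words == 1) return global_stats1(g);
  const int n = g.n;
  std::vector<int> dist(n), queue;
  queue.reserve(n);
  double inv_sum = 0.0, d_sum = 0.0;
  long reach = 0, unreach = 0;
  for (int s = 0; s < n; ++s) {
    bfs(g, s, dist, queue);
    for (int t = 0; t < n; ++t) {
      if (t == s) continue;
      if (dist[t] > 0) {
        inv_sum += 1.0 / dist[t];
        d_sum += dist[t];
        ++reach;
      } else {
        ++unreach;
      }
    }
  }
  double cl = 0.0;
  for (int i = 0; i < n; ++i) {
    int k = (int)g.adj[i].size();
    if (k < 2) continue;
    long links = 0;  // sum over neighbors j of |N(i) & N(j)| = 2 * triangles
    for (int j : g.adj[i]) {
      for (int w = 0; w < g.words; ++w)
        links += popcount64(g.mask[i][w] & g.mask[j][w]);
    }
    cl += (double)links / ((double)k * (k - 1));
  }
  GlobalStats st;
  st.geff = n > 1 ? inv_sum / ((double)n * (n - 1)) : 0.0;
  st.clustering = n > 0 ? cl / n : 0.0;
  st.pathlen = reach > 0 ? d_sum / reach : R_NaN;
  st.unreachable = (double)unreach;
  return st;
}

// Mean over nodes of the global efficiency of the neighbor-induced
// subgraph; nodes with degree < 2 contribute 0.
double local_efficiency(const Graph& g) {
  const int n = g.n;
  double total = 0.0;
  std::vector<int> dist, queue;
  for (int i = 0; i < n; ++i) {
    const std::vector<int>& nb = g.adj[i];
    int k = (int)nb.size();
    if (k < 2) continue;
    Graph sub(k);
    for (int a = 0; a < k; ++a)
      for (int b = a + 1; b < k; ++b)
        if (g.has_edge(nb[a], nb[b])) sub.add_edge(a, b);
    total += global_stats(sub).geff;
  }
  return n > 0 ? total / n : 0.0;
}

Graph graph_from_edges(const IntegerVector& ei, const IntegerVector& ej,
                       int k, int n) {
  Graph g(n);
  for (int e = 0; e < k; ++e) g.add_edge(ei[e], ej[e]);
  return g;
}

Graph graph_from_adj(const IntegerMatrix& A) {
  int n = A.nrow();
  Graph g(n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (A(i, j) != 0) g.add_edge(i, j);
  return g;
}

// Fast portable RNG for the rewiring loops (xorshift64*), seeded from
// R's RNG once per exported call so set.seed() governs determinism while
// the hot loop avoids R API crossings. Modulo bias is negligible for
// graph-sized ranges.
struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed | 1ULL) {}
  uint64_t next() {
    s ^= s >> 12;
    s ^= s << 25;
    s ^= s >> 27;
    return s * 2685821657736338717ULL;
  }
  long below(long m) { return (long)(next() % (uint64_t)m); }
  bool coin() { return next() & 1024ULL; }
};

inline uint64_t rng_seed_from_r() {
  return (uint64_t)(unif_rand() * 9007199254740992.0);
}

// Degree-preserving randomization by double edge swaps. Edges are stored
// as pairs; each attempt picks two edges and an orientation uniformly and
// applies the swap unless it would create a self-loop or parallel edge.
void edge_swap_rewire(std::vector<std::pair<int, int>>& edges, Graph& g,
                      long attempts, XorShift& rng) {
  long m = (long)edges.size();
  if (m < 2) return;
  for (long it = 0; it < attempts; ++it) {
    long e1 = rng.below(m);
    long e2 = rng.below(m);
    if (e1 == e2) continue;
    int a = edges[e1].first, b = edges[e1].second;
    int c = edges[e2].first, d = edges[e2].second;
    if (rng.coin()) { std::swap(c, d); }
    // propose (a,d) and (c,b)
    if (a == d || c == b) continue;
    if (a == c || b == d) continue;  // shared endpoint: swap is a no-op/loop
    if (g.has_edge(a, d) || g.has_edge(c, b)) continue;
    // remove (a,b) and (c,d) from masks/adjacency
    auto drop = [&g](int u, int v) {
      g.mask[u][v >> 6] &= ~(1ULL << (v & 63));
      g.mask[v][u >> 6] &= ~(1ULL << (u & 63));
      auto& au = g.adj[u];
      au.erase(std::find(au.begin(), au.end(), v));
      auto& av = g.adj[v];
      av.erase(std::find(av.begin(), av.end(), u));
    };
    drop(a, b);
    drop(c, d);
    g.add_edge(a, d);
    g.add_edge(c, b);
    edges[e1] = {a, d};
    edges[e2] = {c, b};
  }
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_adj_stats(IntegerMatrix A, bool with_local_eff = true) {
  Graph g = graph_from_adj(A);
  GlobalStats st = global_stats(g);
  NumericVector out = NumericVector::create(
      _["global_efficiency"] = st.geff, _["clustering"] = st.clustering,
      _["path_length"] = st.pathlen, _["unreachable_pairs"] = st.unreachable,
      _["local_efficiency"] =
          with_local_eff ? local_efficiency(g) : NA_REAL);
  return out;
}

// Measures along a nested density stack. ei/ej are 0-based endpoints of
// the ranked edge list (strongest first); kvec gives the number of edges
// retained at each density (non-decreasing).
// [[Rcpp::export]]
NumericMatrix cpp_curve_stats(IntegerVector ei, IntegerVector ej,
                              IntegerVector kvec, int n,
                              bool with_local_eff = false) {
  int nd = kvec.size();
  NumericMatrix out(nd, 5);
  colnames(out) = CharacterVector::create(
      "global_efficiency", "clustering", "path_length",
      "unreachable_pairs", "local_efficiency");
  Graph g(n);
  int added = 0;
  for (int d = 0; d < nd; ++d) {
    int k = kvec[d];
    if (k > ei.size()) k = ei.size();
    for (; added < k; ++added) g.add_edge(ei[added], ej[added]);
    GlobalStats st = global_stats(g);
    out(d, 0) = st.geff;
    out(d, 1) = st.clustering;
    out(d, 2) = st.pathlen;
    out(d, 3) = st.unreachable;
    out(d, 4) = with_local_eff ? local_efficiency(g) : NA_REAL;
  }
  return out;
}

// Small-world sigma along a nested density stack:
// sigma = (C / mean C_rand) / (L / mean L_rand), the randomized ensemble
// being degree-preserving edge-swap rewirings (swap_factor * m attempted
// swaps each). Runs under R's RNG. Returns NaN where the ratio is
// undefined (e.g. triangle-free randomizations).
// [[Rcpp::export]]
NumericVector cpp_sigma_curve(IntegerVector ei, IntegerVector ej,
                              IntegerVector kvec, int n, int ensemble,
                              double swap_factor = 10.0) {
  int nd = kvec.size();
  NumericVector out(nd);
  XorShift rng(rng_seed_from_r());
  for (int d = 0; d < nd; ++d) {
    int k = kvec[d];
    if (k > ei.size()) k = ei.size();
    Graph g = graph_from_edges(ei, ej, k, n);
    GlobalStats st = global_stats(g);
    double csum = 0.0, lsum = 0.0;
    int lcnt = 0;
    for (int r = 0; r < ensemble; ++r) {
      Graph gr = graph_from_edges(ei, ej, k, n);
      std::vector<std::pair<int, int>> edges(k);
      for (int e = 0; e < k; ++e) edges[e] = {ei[e], ej[e]};
      edge_swap_rewire(edges, gr, (long)(swap_factor * k), rng);
      GlobalStats str = global_stats(gr);
      csum += str.clustering;
      if (R_finite(str.pathlen)) { lsum += str.pathlen; ++lcnt; }
    }
    double cbar = csum / ensemble;
    double lbar = lcnt > 0 ? lsum / lcnt : R_NaN;
    if (ensemble <= 0) {
      out[d] = NA_REAL;
    } else if (cbar <= 0.0 || !R_finite(lbar) || lbar <= 0.0 ||
               !R_finite(st.pathlen)) {
      // rigid or degenerate graphs: ensemble equals the graph itself
      out[d] = (st.clustering == cbar) ? 1.0 : R_NaN;
    } else {
      out[d] = (st.clustering / cbar) / (st.pathlen / lbar);
    }
  }
  return out;
}

// Single degree-preserving rewiring of a binary adjacency matrix
// (exposed for validation of the null model).
// [[Rcpp::export]]
IntegerMatrix cpp_rewire_adj(IntegerMatrix A, double swap_factor = 10.0) {
  Graph g = graph_from_adj(A);
  XorShift rng(rng_seed_from_r());
  std::vector<std::pair<int, int>> edges;
  int n = A.nrow();
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (A(i, j) != 0) edges.push_back({i, j});
  edge_swap_rewire(edges, g, (long)(swap_factor * edges.size()), rng);
  IntegerMatrix out(n, n);
  for (auto& e : edges) {
    out(e.first, e.second) = 1;
    out(e.second, e.first) = 1;
  }
  return out;
}
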