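#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Edges are passed as an m x 2 integer matrix of 0-based node ids.
// All randomness comes from R's RNG (so set.seed() on the R side governs it).

static inline long long edge_key(int a, int b, int n) {
  if (a > b) std::swap(a, b);
  return (long long)a * (long long)n + (long long)b;
}

// Degree-preserving double-edge-swap randomization.
// Runs `n_steps` steps of the swap chain. Each step proposes a uniformly
// chosen pair of edge slots and one of the two rewirings; a proposal that
// would create a self-loop or duplicate edge is rejected and the graph left
// unchanged for that step. Rejected steps consume the step budget: the
// proposal distribution is state-independent and symmetric, so this lazy
// chain has the *uniform* distribution over all simple graphs with the given
// degree sequence as its stationary law (a move-on-every-step variant would
// oversample graphs with many valid swaps).
// [[Rcpp::export]]
List cpp_rewire(IntegerMatrix edges, int n_nodes, double n_steps) {
  int m = edges.nrow();
  std::vector<int> from(m), to(m);
  std::unordered_set<long long> present;
  present.reserve((size_t)(m * 2));
  for (int i = 0; i < m; ++i) {
    from[i] = edges(i, 0);
    to[i]   = edges(i, 1);
    present.insert(edge_key(from[i], to[i], n_nodes));
  }
  double successes = 0.0;
  if (m >= 2) {
    for (double step = 0.0; step < n_steps; step += 1.0) {
      int e1 = (int)(unif_rand() * m);
      int e2 = (int)(unif_rand() * m);
      if (e1 >= m) e1 = m - 1;
      if (e2 >= m) e2 = m - 1;
      if (e1 == e2) continue;
      int a = from[e1], b = to[e1], c = from[e2], d = to[e2];
      // two possible rewirings: (a-c, b-d) or (a-d, b-c)
      int u1, v1, u2, v2;
      if (unif_rand() < 0.5) { u1 = a; v1 = c; u2 = b; v2 = d; }
      else                   { u1 = a; v1 = d; u2 = b; v2 = c; }
      if (u1 == v1 || u2 == v2) continue;            // self-loop
      long long k1 = edge_key(u1, v1, n_nodes);
      long long k2 = edge_key(u2, v2, n_nodes);
      if (k1 == k2) continue;                        // parallel edge pair
      if (present.count(k1) || present.count(k2)) continue; // duplicate
      present.erase(edge_key(a, b, n_nodes));
      present.erase(edge_key(c, d, n_nodes));
      present.insert(k1);
      present.insert(k2);
      from[e1] = u1; to[e1] = v1;
      from[e2] = u2; to[e2] = v2;
      successes += 1.0;
    }
  }
  IntegerMatrix out(m, 2);
  for (int i = 0; i < m; ++i) {
    out(i, 0) = std::min(from[i], to[i]);
    out(i, 1) = std::max(from[i], to[i]);
  }
  return List::create(_["edges"] = out, _["n_success"] = successes);
}

static std::vector<std::vector<int>> build_adj(const IntegerMatrix& edges,
                                               int n_nodes) {
  std::vector<std::vector<int>> adj(n_nodes);
  int m = edges.nrow();
  for (int i = 0; i < m; ++i) {
    adj[edges(i, 0)].push_back(edges(i, 1));
    adj[edges(i, 1)].push_back(edges(i, 0));
  }
  for (int v = 0; v < n_nodes; ++v) std::sort(adj[v].begin(), adj[v].end());
  return adj;
}

static int common_neighbours(const std::vector<int>& a,
                             const std::vector<int>& b, int u, int v) {
  // |N(u) n N(v)| excluding u and v themselves (excluded automatically in a
  // simple graph, but kept explicit for safety)
  int count = 0;
  size_t i = 0, j = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] < b[j]) ++i;
    else if (a[i] > b[j]) ++j;
    else {
      if (a[i] != u && a[i] != v) ++count;
      ++i; ++j;
    }
  }
  return count;
}

// Count links between two gene sets.
// mode 1 (direct): distinct edges with one endpoint in each set; an edge
//   internal to the intersection counts once.
// mode 2 (indirect): distinct length-2 paths a-x-f with a in ags, f in fgs,
//   a != f, intermediate x not an endpoint; each unordered path counted once.
// [[Rcpp::export]]
double cpp_count_links(IntegerMatrix edges, int n_nodes,
                       IntegerVector ags, IntegerVector fgs, int mode) {
  std::vector<char> inA(n_nodes, 0), inF(n_nodes, 0);
  for (int i = 0; i < ags.size(); ++i) inA[ags[i]] = 1;
  for (int i = 0; i < fgs.size(); ++i) inF[fgs[i]] = 1;
  double count = 0.0;
  if (mode == 1) {
    int m = edges.nrow();
    for (int i = 0; i < m; ++i) {
      int u = edges(i, 0), v = edges(i, 1);
      if ((inA[u] && inF[v]) || (inF[u] && inA[v])) count += 1.0;
    }
  } else {
    std::vector<std::vector<int>> adj = build_adj(edges, n_nodes);
    std::unordered_set<long long> seen;
    for (int i = 0; i < ags.size(); ++i) {
      int u = ags[i];
      for (int j = 0; j < fgs.size(); ++j) {
        int v = fgs[j];
        if (u == v) continue;
        long long k = edge_key(u, v, n_nodes);
        if (seen.count(k)) continue;
        seen.insert(k);
        count += common_neighbours(adj[u], adj[v], u, v);
      }
    }
  }
  return count;
}

// Single-gene-vs-reference counts for a batch of genes against one reference
// set, both statistics at once (used by the shared-ensemble context filter).
// Gene g is tested against reference \ {g}; with simple graphs this equals
// counting against the full reference while skipping the u == v pair.
// [[Rcpp::export]]
NumericMatrix cpp_count_single_vs_ref(IntegerMatrix edges, int n_nodes,
                                      IntegerVector genes, IntegerVector ref) {
  std::vector<char> inR(n_nodes, 0);
  for (int i = 0; i < ref.size(); ++i) inR[ref[i]] = 1;
  std::vector<std::vector<int>> adj = build_adj(edges, n_nodes);
  NumericMatrix out(genes.size(), 2);
  for (int i = 0; i < genes.size(); ++i) {
    int g = genes[i];
    double direct = 0.0, indirect = 0.0;
    for (size_t j = 0; j < adj[g].size(); ++j)
      if (inR[adj[g][j]]) direct += 1.0;
    for (int j = 0; j < ref.size(); ++j) {
      int f = ref[j];
      if (f == g) continue;
      indirect += common_neighbours(adj[g], adj[f], g, f);
    }
    out(i, 0) = direct;
    out(i, 1) = indirect;
  }
  return out;
}
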