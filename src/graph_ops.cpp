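#include <Rcpp.h>
#include <queue>
#include <set>
#include <vector>
using namespace Rcpp;

// All-pairs shortest path lengths of an undirected, unweighted graph given
// as a 0/1 adjacency matrix. Unreachable pairs are returned as -1.
// [[Rcpp::export(name = ".graph_distances_cpp")]]
IntegerMatrix graph_distances_cpp(const IntegerMatrix& adj) {
  const int n = adj.nrow();
  std::vector< std::vector<int> > nb(n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (adj(i, j) != 0) { nb[i].push_back(j); nb[j].push_back(i); }
  IntegerMatrix D(n, n);
  std::fill(D.begin(), D.end(), -1);
  std::vector<int> queue_(n);
  for (int s = 0; s < n; ++s) {
    int head = 0, tail = 0;
    queue_[tail++] = s;
    D(s, s) = 0;
    while (head < tail) {
      const int u = queue_[head++];
      const int du = D(s, u);
      for (size_t k = 0; k < nb[u].size(); ++k) {
        const int v = nb[u][k];
        if (D(s, v) < 0) { D(s, v) = du + 1; queue_[tail++] = v; }
      }
    }
  }
  return D;
}

// Degree-preserving rewiring by repeated edge swaps with rejection of
// self-loops and multi-edges (Maslov-Sneppen). Edges are 0-based endpoint
// vectors; n_attempts swap attempts are made using R's RNG, so results are
// reproducible under set.seed().
// [[Rcpp::export(name = ".rewire_edges_cpp")]]
IntegerMatrix rewire_edges_cpp(const IntegerVector& ei,
                               const IntegerVector& ej,
                               const int n_nodes, const int n_attempts) {
  const int m = ei.size();
  std::vector<int> a(ei.begin(), ei.end());
  std::vector<int> b(ej.begin(), ej.end());
  std::set<long long> eset;
  const long long N = n_nodes;
  for (int e = 0; e < m; ++e) {
    const long long lo = std::min(a[e], b[e]);
    const long long hi = std::max(a[e], b[e]);
    eset.insert(lo * N + hi);
  }
  RNGScope scope;
  for (int t = 0; t < n_attempts; ++t) {
    int e1 = (int)(unif_rand() * m); if (e1 >= m) e1 = m - 1;
    int e2 = (int)(unif_rand() * m); if (e2 >= m) e2 = m - 1;
    if (e1 == e2) continue;
    int x1 = a[e1], y1 = b[e1], x2 = a[e2], y2 = b[e2];
    if (unif_rand() < 0.5) std::swap(x2, y2);
    // proposed edges: (x1, y2) and (x2, y1)
    if (x1 == y2 || x2 == y1) continue;             // self-loop
    const long long k1 = (long long)std::min(x1, y2) * N + std::max(x1, y2);
    const long long k2 = (long long)std::min(x2, y1) * N + std::max(x2, y1);
    if (k1 == k2) continue;                          // duplicate proposal
    if (eset.count(k1) || eset.count(k2)) continue;  // multi-edge
    const long long o1 = (long long)std::min(x1, y1) * N + std::max(x1, y1);
    const long long o2 = (long long)std::min(x2, y2) * N + std::max(x2, y2);
    eset.erase(o1); eset.erase(o2);
    eset.insert(k1); eset.insert(k2);
    a[e1] = x1; b[e1] = y2;
    a[e2] = x2; b[e2] = y1;
  }
  IntegerMatrix out(m, 2);
  for (int e = 0; e < m; ++e) { out(e, 0) = a[e]; out(e, 1) = b[e]; }
  return out;
}
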