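#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Raw-count shortest-path edge loads.
//
// For every ordered pair (s, t), t reachable from s, each distinct shortest
// directed s->t path contributes 1 to the load of every edge it traverses
// (no fractional splitting across equal-length alternatives). Per source s a
// BFS yields distances and path counts sigma, and a reverse-order
// accumulation g[v] = 1 + sum over shortest-path-DAG children w of g[w]
// counts, for each v, the (target, path-suffix) pairs starting at v; the
// load contribution of DAG edge (u, v) from source s is sigma[u] * g[v].
// Complexity O(n * m); counts are doubles to avoid integer overflow.
//
// [[Rcpp::export]]
NumericVector edge_loads_cpp(int n, IntegerMatrix edges) {
  int m = edges.nrow();
  NumericVector load(m);
  if (m == 0) return load;
  std::vector<int> deg(n, 0);
  for (int e = 0; e < m; e++) deg[edges(e, 0) - 1]++;
  std::vector<int> ptr(n + 1, 0);
  for (int i = 0; i < n; i++) ptr[i + 1] = ptr[i] + deg[i];
  std::vector<int> adj(m), eid(m), pos(ptr.begin(), ptr.end() - 1);
  for (int e = 0; e < m; e++) {
    int u = edges(e, 0) - 1;
    adj[pos[u]] = edges(e, 1) - 1;
    eid[pos[u]] = e;
    pos[u]++;
  }
  std::vector<int> dist(n), order(n);
  std::vector<double> sigma(n), g(n);
  for (int s = 0; s < n; s++) {
    std::fill(dist.begin(), dist.end(), -1);
    std::fill(sigma.begin(), sigma.end(), 0.0);
    int head = 0, tail = 0;
    dist[s] = 0; sigma[s] = 1.0; order[tail++] = s;
    while (head < tail) {
      int u = order[head++];
      for (int p = ptr[u]; p < ptr[u + 1]; p++) {
        int v = adj[p];
        if (dist[v] < 0) { dist[v] = dist[u] + 1; order[tail++] = v; }
        if (dist[v] == dist[u] + 1) sigma[v] += sigma[u];
      }
    }
    for (int i = tail - 1; i >= 0; i--) {
      int v = order[i];
      double gv = 1.0;
      for (int p = ptr[v]; p < ptr[v + 1]; p++) {
        int w = adj[p];
        if (dist[w] == dist[v] + 1) gv += g[w];
      }
      g[v] = gv;
    }
    for (int i = 0; i < tail; i++) {
      int u = order[i];
      for (int p = ptr[u]; p < ptr[u + 1]; p++) {
        int v = adj[p];
        if (dist[v] == dist[u] + 1) load[eid[p]] += sigma[u] * g[v];
      }
    }
  }
  return load;
}
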