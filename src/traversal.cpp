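#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Per-node shortest-path traversal counts over a set of ordered (source,
// target) pairs on an unweighted digraph in CSR form (0-based).
//
// For every ordered pair (s, t) with at least one directed path, every
// shortest s->t path increments the counter of each of its interior nodes
// by one (endpoints never counted). Counting uses the standard
// sigma/suffix decomposition: sigma[v] = number of shortest s->v paths,
// g[v] = number of shortest-path suffixes from v ending at a target of s,
// so v's contribution for source s is sigma[v] * g[v].
//
// pairs are supplied grouped: sources[i] with target set targets[i].
// Returns per-node counts plus the number of pair paths (all, and those of
// length >= 2, i.e. having interior nodes) and the grand total of interior
// traversals.
// [[Rcpp::export(name = ".sp_traversal")]]
List sp_traversal(int n, IntegerVector ptr, IntegerVector idx,
                  IntegerVector sources, List targets) {
  NumericVector counts(n);
  double n_paths = 0.0, n_paths_interior = 0.0;
  std::vector<int> dist(n), order(n);
  std::vector<double> sigma(n), g(n);
  std::vector<char> in_t(n, 0);

  for (int i = 0; i < sources.size(); ++i) {
    int s = sources[i];
    IntegerVector tg = targets[i];
    for (int j = 0; j < tg.size(); ++j) in_t[tg[j]] = 1;

    std::fill(dist.begin(), dist.end(), -1);
    int head = 0, tail = 0;
    dist[s] = 0; sigma[s] = 1.0; order[tail++] = s;
    while (head < tail) {
      int v = order[head++];
      for (int e = ptr[v]; e < ptr[v + 1]; ++e) {
        int w = idx[e];
        if (dist[w] < 0) {
          dist[w] = dist[v] + 1;
          sigma[w] = 0.0;
          order[tail++] = w;
        }
        if (dist[w] == dist[v] + 1) sigma[w] += sigma[v];
      }
    }
    // suffix counts, reverse BFS order
    for (int k = tail - 1; k >= 0; --k) {
      int v = order[k];
      double acc = 0.0;
      for (int e = ptr[v]; e < ptr[v + 1]; ++e) {
        int w = idx[e];
        if (dist[w] == dist[v] + 1)
          acc += (in_t[w] ? 1.0 : 0.0) + g[w];
      }
      g[v] = acc;
    }
    for (int k = 1; k < tail; ++k) {  // skip s itself
      int v = order[k];
      counts[v] += sigma[v] * g[v];
      if (in_t[v] && v != s) {
        n_paths += sigma[v];
        if (dist[v] >= 2) n_paths_interior += sigma[v];
      }
    }
    for (int j = 0; j < tg.size(); ++j) in_t[tg[j]] = 0;
  }
  double total = 0.0;
  for (int v = 0; v < n; ++v) total += counts[v];
  return List::create(_["counts"] = counts, _["n_paths"] = n_paths,
                      _["n_paths_interior"] = n_paths_interior,
                      _["total_traversals"] = total);
}
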