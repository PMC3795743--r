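#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Exhaustive DFS over per-ray boundary indices with the |k_i - k_j| <= delta
// neighbour constraint. Rays are visited in breadth-first order from ray 0 so
// every ray after the first is constrained by at least one already-assigned
// neighbour; infeasible prefixes are pruned, and a lower bound from per-ray
// minima prunes cost-dominated branches (strictly, so cost ties survive and
// the first — lexicographically largest — optimum is kept).
// [[Rcpp::export]]
List bf_surface_cpp(NumericMatrix cost, List adj, int delta) {
  const int R = cost.nrow();
  const int Z = cost.ncol();

  // BFS vertex order
  std::vector<int> order;
  order.reserve(R);
  std::vector<char> seen(R, 0);
  std::queue<int> q;
  q.push(0);
  seen[0] = 1;
  while (!q.empty()) {
    int v = q.front(); q.pop();
    order.push_back(v);
    IntegerVector nb = adj[v];
    for (int i = 0; i < nb.size(); ++i) {
      int u = nb[i] - 1;  // adjacency list is 1-based
      if (!seen[u]) { seen[u] = 1; q.push(u); }
    }
  }
  if ((int)order.size() != R)
    stop("template adjacency is not connected");

  std::vector<int> pos(R);  // ray -> position in DFS order
  for (int i = 0; i < R; ++i) pos[order[i]] = i;

  // for each DFS position, the positions (< i) of already-assigned neighbours
  std::vector< std::vector<int> > earlier(R);
  for (int i = 0; i < R; ++i) {
    int v = order[i];
    IntegerVector nb = adj[v];
    for (int j = 0; j < nb.size(); ++j) {
      int u = nb[j] - 1;
      if (pos[u] < i) earlier[i].push_back(pos[u]);
    }
  }

  // suffix lower bound from per-ray minima (in DFS order)
  std::vector<double> ray_min(R);
  for (int v = 0; v < R; ++v) {
    double m = cost(v, 0);
    for (int z = 1; z < Z; ++z) if (cost(v, z) < m) m = cost(v, z);
    ray_min[v] = m;
  }
  std::vector<double> suffix(R + 1, 0.0);
  for (int i = R - 1; i >= 0; --i)
    suffix[i] = suffix[i + 1] + ray_min[order[i]];

  std::vector<int> k(R, -1);       // assignment by DFS position
  std::vector<int> best_k;
  double best = R_PosInf;
  const double eps = 1e-12;

  // iterative DFS with explicit stack of (depth, candidate z)
  std::vector<int> z_at(R, Z);     // next candidate (descending) per depth
  std::vector<double> partial(R + 1, 0.0);
  int depth = 0;
  z_at[0] = Z;
  while (depth >= 0) {
    if (depth == R) {
      if (partial[R] < best - eps) {
        best = partial[R];
        best_k = k;
      }
      --depth;
      continue;
    }
    bool advanced = false;
    int v = order[depth];
    while (z_at[depth] > 0) {
      int z = --z_at[depth];       // try Z-1 .. 0, high first
      bool ok = true;
      for (size_t j = 0; j < earlier[depth].size(); ++j) {
        int d = k[earlier[depth][j]] - z;
        if (d > delta || d < -delta) { ok = false; break; }
      }
      if (!ok) continue;
      double c = partial[depth] + cost(v, z);
      if (c + suffix[depth + 1] > best + eps) continue;  // keep ties
      k[depth] = z;
      partial[depth + 1] = c;
      ++depth;
      if (depth < R) z_at[depth] = Z;
      advanced = true;
      break;
    }
    if (!advanced && z_at[depth] == 0) --depth;
  }

  if (best_k.empty()) stop("no feasible assignment found");

  IntegerVector kout(R);
  for (int i = 0; i < R; ++i) kout[order[i]] = best_k[i] + 1;  // 1-based
  return List::create(_["k"] = kout, _["total_cost"] = best);
}
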