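#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Union-find with path compression + union by size.
static int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

// Accumulate threshold-free network-based statistic scores.
//
// For each threshold h in `thresholds`, edges with t > h form a
// suprathreshold graph; every suprathreshold edge receives
// extent(component)^E * h^H * dh, where extent is the number of edges in
// its connected component. Scores are accumulated over the whole ladder.
//
// t:      per-edge t statistic (one hypothesis; only t > h contributes)
// ei, ej: 0-based endpoint node indices per edge
// t_ref:  when >= 0, the ladder is the data-driven one: n_lev levels
//         evenly spaced over (0, t_ref]; the suprathreshold test is then
//         the cross-multiplied `t * n_lev > t_ref * k`, which is exact at
//         the knife edge t == t_ref (the maximum t never survives its own
//         top level) and reproducible across implementations.
// [[Rcpp::export]]
NumericVector tfnbs_score_cpp(NumericVector t, IntegerVector ei,
                              IntegerVector ej, int n_nodes,
                              NumericVector thresholds, double E, double H,
                              double dh, double t_ref = -1.0,
                              int n_lev = 0) {
  const int m = t.size();
  const bool relative = t_ref >= 0.0;
  if (ei.size() != m || ej.size() != m)
    stop("edge index vectors must match t length");
  if (!relative && thresholds.size() == 0)
    stop("threshold ladder is empty");
  const int n_thr = relative ? n_lev : (int)thresholds.size();
  NumericVector score(m);

  // Per threshold: union-find over the suprathreshold edges, then one
  // extent^E evaluation per component (memoized by root), not per edge.
  std::vector<int> parent(n_nodes);
  std::vector<int> extent(n_nodes);
  std::vector<double> powext(n_nodes);
  std::vector<int> active;
  active.reserve(m);

  for (int k = 0; k < n_thr; ++k) {
    const double h = relative ? t_ref * (k + 1) / n_lev : thresholds[k];
    active.clear();
    if (relative) {
      const double lhs_scale = (double)n_lev, rhs = t_ref * (k + 1);
      for (int e = 0; e < m; ++e)
        if (t[e] * lhs_scale > rhs) active.push_back(e);
    } else {
      for (int e = 0; e < m; ++e)
        if (t[e] > h) active.push_back(e);
    }
    if (active.empty()) continue;
    for (int v = 0; v < n_nodes; ++v) parent[v] = v;
    for (size_t a = 0; a < active.size(); ++a) {
      int e = active[a];
      int ri = uf_find(parent, ei[e]);
      int rj = uf_find(parent, ej[e]);
      if (ri != rj) parent[ri] = rj;
    }
    std::fill(extent.begin(), extent.end(), 0);
    for (size_t a = 0; a < active.size(); ++a)
      extent[uf_find(parent, ei[active[a]])] += 1;
    const double hH = std::pow(h, H) * (relative ? t_ref / n_lev : dh);
    for (int v = 0; v < n_nodes; ++v)
      if (extent[v] > 0)
        powext[v] = (E == 1.0 ? (double)extent[v]
                              : std::pow((double)extent[v], E)) * hH;
    for (size_t a = 0; a < active.size(); ++a) {
      int e = active[a];
      score[e] += powext[uf_find(parent, ei[e])];
    }
  }
  return score;
}

// Maximum TFNBS score over edges for a batch of permuted t-statistic
// matrices: tmat is (n_perm x m). Returns the per-permutation maximum for
// the direction t > h (callers pass -t for the opposite hypothesis).
// With a fixed threshold ladder (`thresholds`/`dh`), the same ladder is
// applied to every row. With relative = true the ladder of each row is
// n_steps levels evenly spaced over (0, max t of that row]; the score is
// then the same function of every t-map, which keeps the permutation
// distribution exchangeable with the observed map's score.
// [[Rcpp::export]]
NumericVector tfnbs_max_scores_cpp(NumericMatrix tmat, IntegerVector ei,
                                   IntegerVector ej, int n_nodes,
                                   NumericVector thresholds, double E,
                                   double H, double dh, bool relative,
                                   int n_steps) {
  const int B = tmat.nrow();
  NumericVector out(B);
  for (int b = 0; b < B; ++b) {
    NumericVector t = tmat(b, _);
    NumericVector s;
    if (relative) {
      double tmax = *std::max_element(t.begin(), t.end());
      if (!(tmax > 0)) { out[b] = 0.0; continue; }
      s = tfnbs_score_cpp(t, ei, ej, n_nodes, NumericVector(0), E, H, 0.0,
                          tmax, n_steps);
    } else {
      s = tfnbs_score_cpp(t, ei, ej, n_nodes, thresholds, E, H, dh);
    }
    double mx = 0.0;
    for (int e = 0; e < s.size(); ++e) if (s[e] > mx) mx = s[e];
    out[b] = mx;
  }
  return out;
}
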