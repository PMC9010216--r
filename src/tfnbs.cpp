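#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Union-find with path halving.
static int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[rb] = ra;
}

// Connected-component labels (1-based, compacted) for the graph whose
// edges are (ei, ej), node ids 1..n_nodes. Components are defined over
// the edge set: two edges share a component iff they are connected
// through shared nodes.
// [[Rcpp::export]]
IntegerVector edge_components_cpp(IntegerVector ei, IntegerVector ej,
                                  int n_nodes) {
  int m = ei.size();
  std::vector<int> parent(n_nodes + 1);
  for (int v = 0; v <= n_nodes; ++v) parent[v] = v;
  for (int e = 0; e < m; ++e) uf_union(parent, ei[e], ej[e]);
  std::vector<int> label(n_nodes + 1, 0);
  int next = 0;
  IntegerVector out(m);
  for (int e = 0; e < m; ++e) {
    int r = uf_find(parent, ei[e]);
    if (label[r] == 0) label[r] = ++next;
    out[e] = label[r];
  }
  return out;
}

// Threshold-free network-based-statistic scores.
//
// For thresholds T_k = k * dT, k = 1..ceil(max(s)/dT), every edge with
// statistic s >= T_k contributes extent^E * T_k^H * dT to its score,
// where extent is the edge count of the connected component containing
// it among the supra-threshold edges at T_k. A 1e-9 tolerance guards the
// s >= T comparison against decimal-grid rounding (k * 0.1 is not exact
// in binary floating point).
// [[Rcpp::export]]
NumericVector tfnbs_scores_cpp(IntegerVector ei, IntegerVector ej,
                               NumericVector s, int n_nodes,
                               double dT, double E, double H) {
  const double tol = 1e-9;
  int m = ei.size();
  NumericVector score(m);
  double smax = 0.0;
  for (int e = 0; e < m; ++e) if (s[e] > smax) smax = s[e];
  if (smax <= 0.0 || dT <= 0.0) return score;
  int kmax = (int)std::ceil(smax / dT - tol);

  std::vector<int> parent(n_nodes + 1);
  std::vector<int> extent(n_nodes + 1);
  std::vector<int> active;
  active.reserve(m);

  for (int k = 1; k <= kmax; ++k) {
    double T = k * dT;
    active.clear();
    for (int e = 0; e < m; ++e) {
      if (s[e] >= T - tol) active.push_back(e);
    }
    if (active.empty()) break;
    for (size_t a = 0; a < active.size(); ++a) {
      int e = active[a];
      parent[ei[e]] = ei[e];
      parent[ej[e]] = ej[e];
    }
    for (size_t a = 0; a < active.size(); ++a) {
      int e = active[a];
      uf_union(parent, ei[e], ej[e]);
    }
    for (size_t a = 0; a < active.size(); ++a) {
      extent[uf_find(parent, ei[active[a]])] = 0;
    }
    for (size_t a = 0; a < active.size(); ++a) {
      extent[uf_find(parent, ei[active[a]])] += 1;
    }
    double th = std::pow(T, H) * dT;
    for (size_t a = 0; a < active.size(); ++a) {
      int e = active[a];
      int ext = extent[uf_find(parent, ei[e])];
      score[e] += std::pow((double)ext, E) * th;
    }
  }
  return score;
}
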