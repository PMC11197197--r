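#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Neighbor joining with deterministic tie-breaking: the pair minimizing Q
// wins; residual ties go to the lexicographically smallest pair of original
// leaf indices. Negative branch lengths are clamped to zero.
// Node ids: 0..n-1 leaves, then internal nodes in join order. The tree ends
// in a trifurcation ("final"). For n <= 32 taxa each join also reports the
// bipartition induced by the new internal edge as a leaf bitmask,
// canonicalized to the side not containing leaf 0.
// [[Rcpp::export(name = ".nj_core")]]
List nj_core(NumericMatrix D) {
  const int n = D.nrow();
  if (n < 3) stop("neighbor joining needs at least 3 taxa");
  if (n > 32) stop("neighbor joining supports at most 32 taxa");
  const uint32_t full = (n == 32) ? 0xFFFFFFFFu : ((1u << n) - 1u);
  std::vector<int> node(n), minleaf(n);
  std::vector<uint32_t> mask(n);
  std::vector<std::vector<double>> d(n, std::vector<double>(n));
  for (int i = 0; i < n; ++i) {
    node[i] = i; minleaf[i] = i; mask[i] = 1u << i;
    for (int j = 0; j < n; ++j) d[i][j] = D(i, j);
  }
  int m = n, next_id = n;
  std::vector<int> ja, jb; std::vector<double> la, lb; std::vector<double> bmask;
  while (m > 3) {
    std::vector<double> r(m, 0.0);
    for (int i = 0; i < m; ++i)
      for (int j = 0; j < m; ++j) r[i] += d[i][j];
    double bestQ = R_PosInf; int bi = -1, bj = -1; int bl1 = -1, bl2 = -1;
    for (int i = 0; i < m; ++i)
      for (int j = i + 1; j < m; ++j) {
        double Q = (m - 2) * d[i][j] - r[i] - r[j];
        int l1 = std::min(minleaf[i], minleaf[j]);
        int l2 = std::max(minleaf[i], minleaf[j]);
        bool better = false;
        if (Q < bestQ - 1e-12) better = true;
        else if (Q <= bestQ + 1e-12) {
          if (l1 < bl1 || (l1 == bl1 && l2 < bl2)) better = true;
        }
        if (better) { bestQ = Q; bi = i; bj = j; bl1 = l1; bl2 = l2; }
      }
    double dij = d[bi][bj];
    double li = 0.5 * dij + (r[bi] - r[bj]) / (2.0 * (m - 2));
    double lj = dij - li;
    if (li < 0) li = 0; if (lj < 0) lj = 0;
    ja.push_back(node[bi]); jb.push_back(node[bj]);
    la.push_back(li); lb.push_back(lj);
    uint32_t mk = mask[bi] | mask[bj];
    uint32_t canon = (mk & 1u) ? (full & ~mk) : mk;
    bmask.push_back((double)canon);
    // merge bj into bi as the new cluster, drop bj
    std::vector<double> dn(m);
    for (int k2 = 0; k2 < m; ++k2)
      if (k2 != bi && k2 != bj)
        dn[k2] = 0.5 * (d[bi][k2] + d[bj][k2] - dij);
    node[bi] = next_id++;
    minleaf[bi] = std::min(minleaf[bi], minleaf[bj]);
    mask[bi] = mk;
    for (int k2 = 0; k2 < m; ++k2) {
      if (k2 == bi || k2 == bj) continue;
      d[bi][k2] = d[k2][bi] = dn[k2];
    }
    d[bi][bi] = 0.0;
    // compact: move last into bj
    int last = m - 1;
    if (bj != last) {
      node[bj] = node[last]; minleaf[bj] = minleaf[last]; mask[bj] = mask[last];
      for (int k2 = 0; k2 < m; ++k2) { d[bj][k2] = d[last][k2]; d[k2][bj] = d[k2][last]; }
      d[bj][bj] = 0.0;
    }
    node.resize(last); minleaf.resize(last); mask.resize(last);
    d.resize(last);
    for (auto &row : d) row.resize(last);
    --m;
  }
  // final trifurcation among remaining 3 clusters
  double x = 0.5 * (d[0][1] + d[0][2] - d[1][2]);
  double y = 0.5 * (d[0][1] + d[1][2] - d[0][2]);
  double z = 0.5 * (d[0][2] + d[1][2] - d[0][1]);
  if (x < 0) x = 0; if (y < 0) y = 0; if (z < 0) z = 0;
  return List::create(
    _["join_a"] = wrap(ja), _["join_b"] = wrap(jb),
    _["len_a"] = wrap(la), _["len_b"] = wrap(lb),
    _["masks"] = wrap(bmask),
    _["final_nodes"] = IntegerVector::create(node[0], node[1], node[2]),
    _["final_lens"] = NumericVector::create(x, y, z));
}
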