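#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Deficiency |C| - l - s for a batch of random reaction networks given as
// edge-indicator rows over a fixed list of complex pairs. Complexes count
// only when incident to a sampled reaction; s is the rank of the sampled
// stoichiometric vectors (entries are small integers, so double-precision
// elimination with a fixed pivot tolerance is exact).
// [[Rcpp::export]]
IntegerVector batch_deficiency(LogicalMatrix edges, IntegerVector pair_src,
                               IntegerVector pair_dst, IntegerMatrix cx) {
  const int nn = edges.nrow(), np = edges.ncol();
  const int m = cx.nrow(), d = cx.ncol();
  IntegerVector out(nn);
  std::vector<int> parent(m);
  std::vector<char> present(m);
  std::vector<double> G;
  for (int w = 0; w < nn; w++) {
    for (int i = 0; i < m; i++) { parent[i] = i; present[i] = 0; }
    G.clear();
    int nedges = 0;
    for (int e = 0; e < np; e++) {
      if (!edges(w, e)) continue;
      nedges++;
      int a = pair_src[e] - 1, b = pair_dst[e] - 1;
      present[a] = present[b] = 1;
      int ra = a, rb = b;
      while (parent[ra] != ra) ra = parent[ra];
      while (parent[rb] != rb) rb = parent[rb];
      if (ra != rb) parent[ra] = rb;
      for (int i = 0; i < d; i++) G.push_back((double)(cx(b, i) - cx(a, i)));
    }
    if (nedges == 0) { out[w] = 0; continue; }
    int ncx = 0, l = 0;
    for (int i = 0; i < m; i++) {
      if (!present[i]) continue;
      ncx++;
      int r = i; while (parent[r] != r) r = parent[r];
      if (r == i) l++;  // root of a present component (roots stay present)
    }
    // roots may have been unioned into absent nodes? no: unions only touch
    // endpoints of edges, which are present, so roots are present.
    // rank of G (nedges x d) by Gaussian elimination
    int rank = 0;
    int rows = nedges;
    for (int col = 0; col < d && rank < rows; col++) {
      int piv = -1;
      double best = 1e-9;
      for (int rr = rank; rr < rows; rr++) {
        double v = std::fabs(G[rr * d + col]);
        if (v > best) { best = v; piv = rr; }
      }
      if (piv < 0) continue;
      for (int i = 0; i < d; i++) std::swap(G[rank * d + i], G[piv * d + i]);
      for (int rr = 0; rr < rows; rr++) {
        if (rr == rank || std::fabs(G[rr * d + col]) < 1e-12) continue;
        double f = G[rr * d + col] / G[rank * d + col];
        for (int i = 0; i < d; i++) G[rr * d + i] -= f * G[rank * d + i];
      }
      rank++;
    }
    out[w] = ncx - l - rank;
  }
  return out;
}
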