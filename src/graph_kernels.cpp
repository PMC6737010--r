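#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// All-pairs shortest path lengths (Floyd-Warshall) on an edge-length
// matrix; absent edges are Inf, diagonal forced to 0.
// [[Rcpp::export(name = ".fw_distances_cpp")]]
NumericMatrix fw_distances_cpp(NumericMatrix len) {
  int n = len.nrow();
  NumericMatrix d = clone(len);
  for (int i = 0; i < n; ++i) d(i, i) = 0.0;
  for (int k = 0; k < n; ++k) {
    for (int i = 0; i < n; ++i) {
      double dik = d(i, k);
      if (!R_finite(dik)) continue;
      for (int j = 0; j < n; ++j) {
        double alt = dik + d(k, j);
        if (alt < d(i, j)) d(i, j) = alt;
      }
    }
  }
  return d;
}

// One Louvain move phase: greedy local moves over the supplied node order
// (1-based permutation), repeated until no move improves Q. Self-loops on
// the diagonal (from aggregation) stay with their node and cancel out of
// every gain. Returns 1-based community labels.
// [[Rcpp::export(name = ".louvain_move_phase_cpp")]]
IntegerVector louvain_move_phase_cpp(NumericMatrix A, IntegerVector order) {
  int n = A.nrow();
  std::vector<double> k(n, 0.0);
  double S = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) k[i] += A(i, j);
    S += k[i];
  }
  std::vector<int> comm(n), touched;
  std::vector<double> tot(k), lcomm(n, 0.0);
  for (int i = 0; i < n; ++i) comm[i] = i;
  touched.reserve(n);
  bool improved = true;
  while (improved) {
    improved = false;
    for (int oi = 0; oi < n; ++oi) {
      int i = order[oi] - 1;
      int a = comm[i];
      tot[a] -= k[i];
      touched.clear();
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        double w = A(i, j);
        if (w > 0.0) {
          int c = comm[j];
          if (lcomm[c] == 0.0) touched.push_back(c);
          lcomm[c] += w;
        }
      }
      double stay = 2.0 * lcomm[a] / S - 2.0 * k[i] * tot[a] / (S * S);
      double best_gain = stay;
      int best = a;
      for (size_t t = 0; t < touched.size(); ++t) {
        int c = touched[t];
        if (c == a) continue;
        double g = 2.0 * lcomm[c] / S - 2.0 * k[i] * tot[c] / (S * S);
        if (g > best_gain + 1e-12) { best_gain = g; best = c; }
      }
      if (best != a) { comm[i] = best; improved = true; }
      tot[comm[i]] += k[i];
      for (size_t t = 0; t < touched.size(); ++t) lcomm[touched[t]] = 0.0;
      lcomm[a] = 0.0;
    }
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = comm[i] + 1;
  return out;
}
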