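#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Multichannel DTW with the classic DP recurrence (steps (i-1,j), (i,j-1),
// (i-1,j-1)), Euclidean local cost across channels, no warping window.
// Tracks, lexicographically, the minimal aggregate cost and among
// minimal-cost paths the minimal path length, so the length-normalized
// dissimilarity (cost / path length) is well defined and deterministic.
static double dtw_pair(const NumericMatrix& a, const NumericMatrix& b,
                       bool normalize) {
  const int n = a.nrow(), m = b.nrow(), d = a.ncol();
  std::vector<double> C((size_t)n * m);
  std::vector<int> L((size_t)n * m);
  const double eps = 1e-12;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double loc = 0.0;
      for (int c = 0; c < d; ++c) {
        double diff = a(i, c) - b(j, c);
        loc += diff * diff;
      }
      loc = std::sqrt(loc);
      size_t ij = (size_t)i * m + j;
      if (i == 0 && j == 0) {
        C[ij] = loc; L[ij] = 1;
      } else {
        double bc = R_PosInf; int bl = 0;
        auto consider = [&](double cc, int ll) {
          if (!R_FINITE(bc)) { bc = cc; bl = ll; return; }
          double tol = eps * (1.0 + bc);
          if (cc < bc - tol) { bc = cc; bl = ll; }
          else if (std::abs(cc - bc) <= tol && ll < bl) { bc = cc; bl = ll; }
        };
        if (i > 0 && j > 0) consider(C[ij - m - 1], L[ij - m - 1]);
        if (i > 0) consider(C[ij - m], L[ij - m]);
        if (j > 0) consider(C[ij - 1], L[ij - 1]);
        C[ij] = bc + loc; L[ij] = bl + 1;
      }
    }
  }
  size_t last = (size_t)n * m - 1;
  return normalize ? C[last] / (double)L[last] : C[last];
}

// [[Rcpp::export(name = ".dtw_dist_cpp")]]
double dtw_dist_cpp(NumericMatrix a, NumericMatrix b, bool normalize) {
  if (a.ncol() != b.ncol())
    stop("channel count mismatch: %d vs %d", a.ncol(), b.ncol());
  return dtw_pair(a, b, normalize);
}

// [[Rcpp::export(name = ".dtw_matrix_cpp")]]
NumericMatrix dtw_matrix_cpp(List subs, bool normalize) {
  const int n = subs.size();
  std::vector<NumericMatrix> mats;
  mats.reserve(n);
  for (int i = 0; i < n; ++i) mats.push_back(as<NumericMatrix>(subs[i]));
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double v = dtw_pair(mats[i], mats[j], normalize);
      D(i, j) = v;
      D(j, i) = v;
    }
  }
  return D;
}
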