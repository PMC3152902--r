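#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
using namespace Rcpp;

// Best-scoring contiguous run of a score vector.
// Ties broken by smallest start, then smallest end, via first-occurrence
// minimum prefix sums. Returns (sum, start, end) with 0-based half-open
// interval; sum <= 0 reported as sum with start = end = -1.
static void best_segment(const std::vector<double>& x, int lo, int hi,
                         double& best, int& bi, int& bj) {
  best = 0.0; bi = -1; bj = -1;
  double minpre = 0.0, pre = 0.0;
  int minidx = lo;  // prefix index: interval starts at minidx
  for (int j = lo; j < hi; ++j) {
    pre += x[j];
    double s = pre - minpre;
    if (s > best || (s == best && bi >= 0 && minidx < bi)) {
      best = s; bi = minidx; bj = j + 1;
    }
    if (pre < minpre) { minpre = pre; minidx = j + 1; }
  }
}

// All maximal positive-scoring segments (Ruzzo-Tompa semantics) via
// recursive extraction of the best segment and splitting around it.
// [[Rcpp::export]]
IntegerMatrix cpp_maximal_segments(NumericVector xr) {
  int n = xr.size();
  std::vector<double> x(xr.begin(), xr.end());
  std::vector<std::array<int, 2> > stack;
  std::vector<std::array<double, 3> > out;  // start, end, score
  stack.push_back({0, n});
  while (!stack.empty()) {
    std::array<int, 2> iv = stack.back(); stack.pop_back();
    if (iv[1] - iv[0] <= 0) continue;
    double best; int bi, bj;
    best_segment(x, iv[0], iv[1], best, bi, bj);
    if (best <= 0.0 || bi < 0) continue;
    out.push_back({(double)bi, (double)bj, best});
    stack.push_back({iv[0], bi});
    stack.push_back({bj, iv[1]});
  }
  // sort by start
  std::sort(out.begin(), out.end(),
            [](const std::array<double, 3>& a, const std::array<double, 3>& b) {
              return a[0] < b[0];
            });
  IntegerMatrix res(out.size(), 3);
  for (size_t i = 0; i < out.size(); ++i) {
    res(i, 0) = (int)out[i][0];
    res(i, 1) = (int)out[i][1];
    res(i, 2) = (int)out[i][2];
  }
  colnames(res) = CharacterVector::create("start", "end", "score");
  return res;
}

// Permutation null for the detector. `values` is a sites x pairs integer
// matrix of per-site scores (+1 match, -B mismatch, NA = site skipped for
// that pair). For each of n_perm shared column shuffles (R RNG), returns the
// per-pair maximum contiguous-run score (Kadane over the permuted order,
// skipping NAs), as an n_perm x pairs matrix.
// [[Rcpp::export]]
NumericMatrix cpp_perm_pair_max(IntegerMatrix values, int n_perm) {
  int S = values.nrow(), P = values.ncol();
  NumericMatrix out(n_perm, P);
  std::vector<int> perm(S);
  for (int r = 0; r < n_perm; ++r) {
    for (int i = 0; i < S; ++i) perm[i] = i;
    // Fisher-Yates with R's RNG, matching sample.int semantics closely
    for (int i = S - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    for (int p = 0; p < P; ++p) {
      const int* col = &values(0, p);
      double cur = 0.0, best = 0.0;
      for (int i = 0; i < S; ++i) {
        int v = col[perm[i]];
        if (v == NA_INTEGER) continue;
        cur += v;
        if (cur < 0.0) cur = 0.0;
        else if (cur > best) best = cur;
      }
      out(r, p) = best;
    }
  }
  return out;
}
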