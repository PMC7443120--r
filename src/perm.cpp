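// Label-swapping permutation engine for carrier-frequency association
// tests. Each locus (or gene) is reduced to the set of carrier samples;
// under each permutation of case/control labels (preserving group sizes)
// the Pearson chi-square of every carrier 2x2 table is recomputed, giving
// pointwise empirical p values and, via the per-permutation maximum over
// loci, max(T) family-wise corrected p values. Uses R's RNG so results are
// reproducible with set.seed().

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double chisq_2x2(double a, double k, double n1, double n0) {
  // rows: (case carriers a, case non-carriers), (control carriers,
  // control non-carriers); margins n1, n0, k, N-k
  double N = n1 + n0;
  double b = n1 - a, c = k - a, d = n0 - (k - a);
  double den = n1 * n0 * k * (N - k);
  if (den <= 0) return 0.0;
  double num = a * d - b * c;
  return N * num * num / den;
}

// [[Rcpp::export]]
List cpp_perm_carrier_test(List sets, IntegerVector is_case, int n_perm,
                           bool one_sided = false) {
  int N = is_case.size();
  int n1 = 0;
  for (int i = 0; i < N; ++i) n1 += is_case[i];
  double n0 = N - n1;
  int S = sets.size();

  std::vector<std::vector<int>> cs(S);
  std::vector<double> kk(S);
  for (int s = 0; s < S; ++s) {
    IntegerVector v = sets[s];
    cs[s].assign(v.begin(), v.end());
    for (size_t j = 0; j < cs[s].size(); ++j) cs[s][j] -= 1;  // 0-based
    kk[s] = cs[s].size();
  }

  // observed statistics
  NumericVector obs(S);
  for (int s = 0; s < S; ++s) {
    double a = 0;
    for (size_t j = 0; j < cs[s].size(); ++j) a += is_case[cs[s][j]];
    double st = chisq_2x2(a, kk[s], n1, n0);
    if (one_sided && a / (double)n1 <= (kk[s] - a) / n0) st = 0.0;
    obs[s] = st;
  }

  std::vector<double> thr(S);
  for (int s = 0; s < S; ++s) thr[s] = obs[s] - 1e-9;

  IntegerVector point(S), maxcnt(S);
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  std::vector<char> flag(N, 0);

  GetRNGstate();
  for (int p = 0; p < n_perm; ++p) {
    // partial Fisher-Yates: first n1 entries of idx become the case labels
    for (int i = 0; i < n1; ++i) {
      int j = i + (int)(unif_rand() * (N - i));
      if (j >= N) j = N - 1;
      std::swap(idx[i], idx[j]);
    }
    for (int i = 0; i < n1; ++i) flag[idx[i]] = 1;
    double mx = 0.0;
    for (int s = 0; s < S; ++s) {
      double a = 0;
      const std::vector<int>& v = cs[s];
      for (size_t j = 0; j < v.size(); ++j) a += flag[v[j]];
      double st = chisq_2x2(a, kk[s], n1, n0);
      if (one_sided && a / (double)n1 <= (kk[s] - a) / n0) st = 0.0;
      if (st >= thr[s]) point[s]++;
      if (st > mx) mx = st;
    }
    for (int s = 0; s < S; ++s)
      if (mx >= thr[s]) maxcnt[s]++;
    for (int i = 0; i < n1; ++i) flag[idx[i]] = 0;
  }
  PutRNGstate();

  return List::create(_["obs"] = obs, _["point"] = point,
                      _["maxcnt"] = maxcnt, _["n_perm"] = n_perm);
}
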