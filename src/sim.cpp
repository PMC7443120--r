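// Marker-level signal simulation kernel. Given the per-marker copy number
// and the deterministic LRR baseline (state mean shift plus GC wave), draws
// the genotype-driven BAF and the Gaussian LRR noise. Uses R's RNG so a
// profile is reproducible with set.seed().

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Marsaglia polar Gaussian on top of R's uniform stream (cheaper than the
// inversion method behind norm_rand, still reproducible with set.seed)
struct PolarGauss {
  double spare;
  bool has_spare;
  PolarGauss() : spare(0), has_spare(false) {}
  double operator()() {
    if (has_spare) { has_spare = false; return spare; }
    double u, v, s;
    do {
      u = 2.0 * unif_rand() - 1.0;
      v = 2.0 * unif_rand() - 1.0;
      s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    double f = std::sqrt(-2.0 * std::log(s) / s);
    spare = v * f;
    has_spare = true;
    return u * f;
  }
};

// [[Rcpp::export]]
List cpp_simulate_signal(IntegerVector cn, NumericVector lrr_base,
                         double lrr_sd, double baf_sd) {
  int n = cn.size();
  NumericVector lrr(n), baf(n);
  PolarGauss gauss;
  GetRNGstate();
  for (int i = 0; i < n; ++i) {
    int c = cn[i];
    double p = 0.05 + 0.9 * unif_rand();  // population B allele frequency
    double x;
    if (c == 0) {
      x = unif_rand();  // no signal: BAF is noise
    } else {
      int b = 0;
      for (int j = 0; j < c; ++j) b += (unif_rand() < p);
      x = (double)b / c;
      if (baf_sd > 0) {
        x += baf_sd * gauss();
        if (x < 0) x = 0; else if (x > 1) x = 1;
      }
    }
    baf[i] = x;
    lrr[i] = lrr_base[i] + (lrr_sd > 0 ? lrr_sd * gauss() : 0.0);
  }
  PutRNGstate();
  return List::create(_["lrr"] = lrr, _["baf"] = baf);
}
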