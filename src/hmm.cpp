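// Hidden-Markov CNV segmentation kernels: per-state emission log-likelihoods
// for LRR/BAF signal, Viterbi decoding over the five copy states
// {0,1,2,3,4}, and extraction of non-diploid runs into calls with a
// log-likelihood-ratio confidence (called state vs diploid).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const int NSTATE = 5;

struct BafModel {
  // per state: component means/weights plus a uniform outlier weight
  std::vector<std::vector<double>> means;
  std::vector<std::vector<double>> weights;
  std::vector<double> unif;
  double sd;
  // precomputed log emissions in the homozygous bands (BAF within 3 sd of
  // 0 or 1): every state has a cluster there, so the shared Gaussian factor
  // cancels across states and only the cluster weights matter
  double hom_cut;
  double hom0[NSTATE], hom1[NSTATE];
};

static BafModel unpack_baf(const List& baf_mix) {
  BafModel m;
  List mu = baf_mix["means"], w = baf_mix["weights"];
  NumericVector u = baf_mix["unif"];
  m.sd = as<double>(baf_mix["baf_sd"]);
  for (int s = 0; s < NSTATE; ++s) {
    NumericVector ms = mu[s], ws = w[s];
    m.means.push_back(std::vector<double>(ms.begin(), ms.end()));
    m.weights.push_back(std::vector<double>(ws.begin(), ws.end()));
    m.unif.push_back(u[s]);
  }
  m.hom_cut = 3.0 * m.sd;
  for (int s = 0; s < NSTATE; ++s) {
    double w0 = 0, w1 = 0;
    for (size_t c = 0; c < m.means[s].size(); ++c) {
      if (m.means[s][c] == 0.0) w0 = m.weights[s][c];
      if (m.means[s][c] == 1.0) w1 = m.weights[s][c];
    }
    m.hom0[s] = std::log(w0 + m.unif[s]);
    m.hom1[s] = std::log(w1 + m.unif[s]);
  }
  return m;
}

// log mixture density of one BAF value under one state; components further
// than 8 sd from the value contribute nothing and are skipped
static inline double baf_logdens_state(double x, const BafModel& m, int s) {
  if (x <= m.hom_cut) return m.hom0[s];
  if (x >= 1.0 - m.hom_cut) return m.hom1[s];
  const std::vector<double>& mu = m.means[s];
  const std::vector<double>& w = m.weights[s];
  double inv2 = 1.0 / (2.0 * m.sd * m.sd);
  double norm = 1.0 / (m.sd * 2.5066282746310002);
  double cut = 8.0 * m.sd;
  double dens = m.unif[s];  // uniform outlier component, density 1 on [0,1]
  for (size_t c = 0; c < mu.size(); ++c) {
    double d = x - mu[c];
    if (d < -cut || d > cut) continue;
    dens += w[c] * norm * std::exp(-d * d * inv2);
  }
  if (dens < 1e-300) dens = 1e-300;
  return std::log(dens);
}

// n x 5 matrix of per-marker BAF log densities
static void fill_baf_ll(const double* baf, int n, const BafModel& m,
                        std::vector<double>& out) {
  for (int i = 0; i < n; ++i)
    for (int s = 0; s < NSTATE; ++s)
      out[(size_t)i * NSTATE + s] = baf_logdens_state(baf[i], m, s);
}

// [[Rcpp::export]]
NumericMatrix cpp_emission_ll(NumericVector lrr, NumericVector baf,
                              NumericVector lrr_means, double lrr_sd,
                              List baf_mix) {
  int n = lrr.size();
  BafModel bm = unpack_baf(baf_mix);
  NumericMatrix out(n, NSTATE);
  double logsd = std::log(lrr_sd);
  double inv2 = 1.0 / (2.0 * lrr_sd * lrr_sd);
  for (int i = 0; i < n; ++i) {
    for (int s = 0; s < NSTATE; ++s) {
      double d = lrr[i] - lrr_means[s];
      out(i, s) = -logsd - d * d * inv2 + baf_logdens_state(baf[i], bm, s);
    }
  }
  return out;
}

// Viterbi over one block; ll is row-major n x 5, path filled with 0..4
static void viterbi_block(const double* ll, int n, const double* log_init,
                          const double* log_trans, int* path) {
  std::vector<double> delta(NSTATE), ndelta(NSTATE);
  std::vector<int> back((size_t)n * NSTATE);
  for (int s = 0; s < NSTATE; ++s) delta[s] = log_init[s] + ll[s];
  for (int t = 1; t < n; ++t) {
    const double* e = ll + (size_t)t * NSTATE;
    for (int s = 0; s < NSTATE; ++s) {
      double best = delta[0] + log_trans[0 * NSTATE + s];
      int arg = 0;
      for (int r = 1; r < NSTATE; ++r) {
        double v = delta[r] + log_trans[r * NSTATE + s];
        if (v > best) { best = v; arg = r; }
      }
      ndelta[s] = best + e[s];
      back[(size_t)t * NSTATE + s] = arg;
    }
    delta = ndelta;
  }
  int best = 0;
  for (int s = 1; s < NSTATE; ++s) if (delta[s] > delta[best]) best = s;
  path[n - 1] = best;
  for (int t = n - 1; t > 0; --t)
    path[t - 1] = back[(size_t)t * NSTATE + path[t]];
}

// [[Rcpp::export]]
IntegerVector cpp_viterbi(NumericMatrix ll, NumericVector log_init,
                          NumericMatrix log_trans) {
  int n = ll.nrow();
  std::vector<double> llr((size_t)n * NSTATE);
  for (int i = 0; i < n; ++i)
    for (int s = 0; s < NSTATE; ++s) llr[(size_t)i * NSTATE + s] = ll(i, s);
  std::vector<double> lt(NSTATE * NSTATE);
  for (int r = 0; r < NSTATE; ++r)
    for (int s = 0; s < NSTATE; ++s) lt[r * NSTATE + s] = log_trans(r, s);
  std::vector<int> path(n);
  viterbi_block(llr.data(), n, REAL(log_init), lt.data(), path.data());
  return IntegerVector(path.begin(), path.end());
}

struct CallerParams {
  std::vector<double> lrr_means;
  double lrr_sd;
  std::vector<double> log_init;
  std::vector<double> log_trans;
};

static CallerParams unpack_caller(const List& p) {
  CallerParams cp;
  NumericVector lm = p["lrr_means"], li = p["log_init"];
  NumericMatrix lt = p["log_trans"];
  cp.lrr_means.assign(lm.begin(), lm.end());
  cp.lrr_sd = as<double>(p["lrr_sd"]);
  cp.log_init.assign(li.begin(), li.end());
  cp.log_trans.resize(NSTATE * NSTATE);
  for (int r = 0; r < NSTATE; ++r)
    for (int s = 0; s < NSTATE; ++s)
      cp.log_trans[r * NSTATE + s] = lt(r, s);
  return cp;
}

// Segment one sample for several caller parameterisations sharing the BAF
// model. blocks holds 0-based start offsets of each chromosome block plus a
// terminal n. Returns, per caller, a matrix with columns (start_idx,
// end_idx, state, n_markers, confidence); marker indices are 1-based into
// the full profile.
static List call_sample(const double* lrr, const double* baf, int n,
                        const IntegerVector& blocks,
                        const std::vector<CallerParams>& callers,
                        const BafModel& bm,
                        std::vector<double>& baf_ll,
                        std::vector<double>& ll,
                        std::vector<int>& path) {
  fill_baf_ll(baf, n, bm, baf_ll);
  List out(callers.size());
  for (size_t c = 0; c < callers.size(); ++c) {
    const CallerParams& cp = callers[c];
    double logsd = std::log(cp.lrr_sd);
    double inv2 = 1.0 / (2.0 * cp.lrr_sd * cp.lrr_sd);
    for (int i = 0; i < n; ++i) {
      double x = lrr[i];
      double* row = &ll[(size_t)i * NSTATE];
      const double* brow = &baf_ll[(size_t)i * NSTATE];
      for (int s = 0; s < NSTATE; ++s) {
        double d = x - cp.lrr_means[s];
        row[s] = -logsd - d * d * inv2 + brow[s];
      }
    }
    std::vector<double> starts, ends, states, nm, conf;
    int nb = blocks.size() - 1;
    for (int b = 0; b < nb; ++b) {
      int off = blocks[b], len = blocks[b + 1] - blocks[b];
      if (len < 2) continue;  // caller skips chromosomes with < 2 markers
      viterbi_block(&ll[(size_t)off * NSTATE], len, cp.log_init.data(),
                    cp.log_trans.data(), path.data());
      int t = 0;
      while (t < len) {
        int s = path[t];
        if (s == 2) { ++t; continue; }
        int t0 = t;
        double cf = 0.0;
        while (t < len && path[t] == s) {
          const double* row = &ll[(size_t)(off + t) * NSTATE];
          cf += row[s] - row[2];
          ++t;
        }
        starts.push_back(off + t0 + 1);
        ends.push_back(off + t);
        states.push_back(s);
        nm.push_back(t - t0);
        conf.push_back(cf);
      }
    }
    NumericMatrix calls(starts.size(), 5);
    for (size_t i = 0; i < starts.size(); ++i) {
      calls(i, 0) = starts[i]; calls(i, 1) = ends[i]; calls(i, 2) = states[i];
      calls(i, 3) = nm[i]; calls(i, 4) = conf[i];
    }
    out[c] = calls;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_hmm_sample(NumericVector lrr, NumericVector baf,
                    IntegerVector blocks, List callers, List baf_mix) {
  int n = lrr.size();
  BafModel bm = unpack_baf(baf_mix);
  std::vector<CallerParams> cps;
  for (int i = 0; i < callers.size(); ++i)
    cps.push_back(unpack_caller(callers[i]));
  std::vector<double> baf_ll((size_t)n * NSTATE), ll((size_t)n * NSTATE);
  std::vector<int> path(n);
  return call_sample(REAL(lrr), REAL(baf), n, blocks, cps, bm,
                     baf_ll, ll, path);
}

// Batch over a chunk of samples (columns of lrr/baf matrices). Returns one
// matrix per caller with columns (sample, start_idx, end_idx, state,
// n_markers, confidence), sample being the 1-based column index.
// [[Rcpp::export]]
List cpp_hmm_batch(NumericMatrix lrr, NumericMatrix baf,
                   IntegerVector blocks, List callers, List baf_mix) {
  int n = lrr.nrow(), ns = lrr.ncol();
  BafModel bm = unpack_baf(baf_mix);
  std::vector<CallerParams> cps;
  for (int i = 0; i < callers.size(); ++i)
    cps.push_back(unpack_caller(callers[i]));
  std::vector<double> baf_ll((size_t)n * NSTATE), ll((size_t)n * NSTATE);
  std::vector<int> path(n);
  std::vector<std::vector<double>> rows(callers.size());
  for (int j = 0; j < ns; ++j) {
    List res = call_sample(&lrr(0, j), &baf(0, j), n, blocks, cps, bm,
                           baf_ll, ll, path);
    for (int c = 0; c < callers.size(); ++c) {
      NumericMatrix m = res[c];
      for (int i = 0; i < m.nrow(); ++i) {
        rows[c].push_back(j + 1);
        for (int k = 0; k < 5; ++k) rows[c].push_back(m(i, k));
      }
    }
  }
  List out(callers.size());
  for (int c = 0; c < callers.size(); ++c) {
    int nr = rows[c].size() / 6;
    NumericMatrix m(nr, 6);
    for (int i = 0; i < nr; ++i)
      for (int k = 0; k < 6; ++k) m(i, k) = rows[c][(size_t)i * 6 + k];
    out[c] = m;
  }
  return out;
}
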