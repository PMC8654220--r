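#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Counter-based uniform generator. Every draw is a pure function of
// (seed, person id, process stream, calendar year), so scenario runs that
// share a master seed are coupled by construction: an individual untouched
// by an intervention sees exactly the same random inputs in every scenario.
static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline double cb_u(uint64_t seed, uint64_t id, uint64_t stream, uint64_t year) {
  uint64_t h = splitmix64(seed ^ 0xA24BAED4963EE407ULL);
  h = splitmix64(h ^ splitmix64(id * 0x9FB21C651E98DF25ULL));
  h = splitmix64(h ^ splitmix64(stream * 0xD6E8FEB86659FD93ULL));
  h = splitmix64(h ^ splitmix64(year * 0xC2B2AE3D27D4EB4FULL));
  // 53-bit mantissa, strictly inside (0, 1)
  return ((h >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

// [[Rcpp::export]]
NumericVector cb_runif_cpp(double seed, IntegerVector id, int stream, int year) {
  R_xlen_t n = id.size();
  NumericVector out(n);
  uint64_t s = (uint64_t)seed, st = (uint64_t)(int64_t)stream,
           yr = (uint64_t)(int64_t)(year + 100000);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = cb_u(s, (uint64_t)id[i], st, yr);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cb_runif_mat_cpp(double seed, IntegerVector id, IntegerVector streams,
                               int year) {
  R_xlen_t n = id.size();
  int k = streams.size();
  NumericMatrix out(n, k);
  uint64_t s = (uint64_t)seed, yr = (uint64_t)(int64_t)(year + 100000);
  for (int j = 0; j < k; ++j) {
    uint64_t st = (uint64_t)(int64_t)streams[j];
    for (R_xlen_t i = 0; i < n; ++i)
      out(i, j) = cb_u(s, (uint64_t)id[i], st, yr);
  }
  return out;
}

// Sequential hierarchical update of the 8 HUI3 attributes. Attributes are
// visited in the configured order; each proportional-odds model sees the
// person covariates, its own lagged level, and the already-updated levels of
// earlier attributes. Sampling uses the cumulative-logit inverse transform:
// category = 1 + #[ u > P(Y <= k) ].
// models: list of length A, each with fields
//   beta (length P), lag_coef (double), conc (length A, coefficient on
//   (new level - 1) of already-updated attributes; entries for later
//   attributes must be 0), cutpoints (increasing, length K-1).
// [[Rcpp::export]]
IntegerMatrix hui3_update_cpp(NumericMatrix X, IntegerMatrix lag, List models,
                              NumericMatrix U) {
  R_xlen_t n = X.nrow();
  int P = X.ncol(), A = models.size();
  IntegerMatrix out(n, A);

  std::vector<NumericVector> beta(A), conc(A), cuts(A);
  std::vector<double> lagc(A);
  for (int a = 0; a < A; ++a) {
    List m = models[a];
    beta[a] = as<NumericVector>(m["beta"]);
    conc[a] = as<NumericVector>(m["conc"]);
    cuts[a] = as<NumericVector>(m["cutpoints"]);
    lagc[a] = as<double>(m["lag_coef"]);
    if (beta[a].size() != P) stop("beta length mismatch for attribute %d", a + 1);
  }

  // contiguous per-attribute coefficient copies (row-wise access to the
  // column-major inputs is cache-hostile at population scale)
  std::vector<std::vector<double>> bet(A), cnc(A), cts(A);
  for (int a = 0; a < A; ++a) {
    bet[a].assign(beta[a].begin(), beta[a].end());
    cnc[a].assign(conc[a].begin(), conc[a].end());
    cts[a].assign(cuts[a].begin(), cuts[a].end());
  }
  std::vector<double> xrow(P), lp(A);
  for (R_xlen_t i = 0; i < n; ++i) {
    for (int p = 0; p < P; ++p) xrow[p] = X(i, p);
    for (int a = 0; a < A; ++a) lp[a] = lagc[a] * (lag(i, a) - 1.0);
    for (int p = 0; p < P; ++p) {
      double x = xrow[p];
      if (x != 0.0)
        for (int a = 0; a < A; ++a) lp[a] += bet[a][p] * x;
    }
    for (int a = 0; a < A; ++a) {
      double l = lp[a];
      const std::vector<double> &cc = cnc[a];
      for (int bb = 0; bb < a; ++bb)
        if (cc[bb] != 0.0) l += cc[bb] * (out(i, bb) - 1.0);
      const std::vector<double> &ct = cts[a];
      double u = U(i, a);
      int cat = 1;
      for (size_t k = 0; k < ct.size(); ++k) {
        // cumulative logits increase in k; stop at the first that covers u
        double pk = 1.0 / (1.0 + std::exp(-(ct[k] - l)));
        if (u > pk) ++cat; else break;
      }
      out(i, a) = cat;
    }
  }
  return out;
}
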