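#include <Rcpp.h>
using namespace Rcpp;

// Exact pmf of the number of maximal success runs of length >= k in n
// Bernoulli trials with success probability q (a "success" is a foodless
// step, q = 1 - pe). Markov chain embedding over states (r, g): r is the
// current run length capped at k, g the number of qualifying runs so far.
// A failure resets r to 0; the k-th consecutive success increments g;
// further successes leave g unchanged (a run counts once however long).
// [[Rcpp::export(name = ".runCountPmfC")]]
NumericVector runCountPmfC(int n, int k, double pe) {
  const double q = 1.0 - pe, p = pe;
  const int gmax = (n + 1) / (k + 1);
  const int R = k + 1, G = gmax + 1;
  std::vector<double> M(R * G, 0.0), W(R * G, 0.0);
  M[0] = 1.0; // r = 0, g = 0
  for (int t = 0; t < n; ++t) {
    std::fill(W.begin(), W.end(), 0.0);
    for (int g = 0; g < G; ++g) {
      const double* col = &M[(size_t)g * R];
      double* wcol = &W[(size_t)g * R];
      double tot = 0.0;
      for (int r = 0; r < R; ++r) tot += col[r];
      if (tot == 0.0) continue;
      wcol[0] += p * tot;                      // failure: run resets
      for (int r = 0; r + 1 < k; ++r)          // success below k-1: grow
        wcol[r + 1] += q * col[r];
      if (g + 1 < G)                           // k-th success: count run
        W[(size_t)(g + 1) * R + k] += q * col[k - 1];
      else                                     // unreachable at g = gmax;
        wcol[k] += q * col[k - 1];             // kept for mass conservation
      wcol[k] += q * col[k];                   // run already counted
    }
    std::swap(M, W);
  }
  NumericVector pmf(G);
  for (int g = 0; g < G; ++g) {
    double s = 0.0;
    for (int r = 0; r < R; ++r) s += M[(size_t)g * R + r];
    pmf[g] = s;
  }
  return pmf;
}
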