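#include <Rcpp.h>
using namespace Rcpp;

// Ordered-pair template match counts for sample entropy.
// Templates of length m and m-1 are both anchored at the N-m starting
// positions 0..N-m-1 (Richman-Moorman convention), so c_m <= c_{m-1}.
// Chebyshev distance with tolerance r; pairs (l, s), l != s, counted in
// both orders.  Counts returned as doubles: (N-m)^2 overflows 32-bit
// integers for whole-record inputs.
// [[Rcpp::export]]
NumericVector cpp_count_matches(NumericVector y, int m, double r) {
  const int N = y.size();
  if (N <= m + 1) stop("series length must exceed m + 1");
  const int T = N - m;  // number of template positions
  double cm = 0.0, cm1 = 0.0;
  for (int l = 0; l < T - 1; ++l) {
    for (int s = l + 1; s < T; ++s) {
      double d = 0.0;
      bool ok = true;
      for (int i = 0; i < m - 1; ++i) {
        double ad = std::fabs(y[l + i] - y[s + i]);
        if (ad > d) d = ad;
        if (d > r) { ok = false; break; }
      }
      if (!ok) continue;
      cm1 += 2.0;
      if (std::fabs(y[l + m - 1] - y[s + m - 1]) <= r) cm += 2.0;
    }
  }
  return NumericVector::create(_["c_m"] = cm, _["c_m_minus_1"] = cm1);
}
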