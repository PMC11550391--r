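#include <Rcpp.h>
using namespace Rcpp;

// Propagate a set of decoupled first-order modes, plus at most one Jordan
// (repeated-pole) pair, across a sequence of sub-intervals on which the
// (delayed, zero-order-held) input is constant, and read the modal output
// at flagged event times.
//
// Mode i:        x_i' = -a_i x_i + u(t),  output contribution r_i * x_i
// Jordan pair:   x2'  = -aj x2 + u(t);  x1' = -aj x1 + x2
//                output contribution w1 * x1 + w2 * x2
//
// Over a sub-interval of length d with constant input u the updates are
// exact (scalar exponentials); expm1 keeps (1 - e^{-ad})/a accurate for
// small a*d.
//
// delta, v : lengths and input values of the M sub-intervals
// samp     : 0-based indices into the M+1 event times at which output
//            samples fall (non-decreasing)
// x0       : initial modal state, length = n_modes (+2 if Jordan pair),
//            simple modes first, then (x1, x2)
// [[Rcpp::export]]
NumericVector sim_events(NumericVector delta, NumericVector v,
                         IntegerVector samp,
                         NumericVector a, NumericVector r,
                         double aj, double w1, double w2, bool has_jordan,
                         NumericVector x0) {
  const int M = delta.size();
  const int N = samp.size();
  const int nm = a.size();
  NumericVector y(N);
  std::vector<double> x(nm, 0.0);
  double x1 = 0.0, x2 = 0.0;
  for (int i = 0; i < nm; ++i) x[i] = x0[i];
  if (has_jordan) { x1 = x0[nm]; x2 = x0[nm + 1]; }

  int si = 0;
  for (int e = 0; e <= M; ++e) {
    if (si < N && samp[si] == e) {
      double out = 0.0;
      for (int i = 0; i < nm; ++i) out += r[i] * x[i];
      if (has_jordan) out += w1 * x1 + w2 * x2;
      while (si < N && samp[si] == e) y[si++] = out;
    }
    if (e == M) break;
    const double d = delta[e], u = v[e];
    if (d <= 0.0) continue;
    for (int i = 0; i < nm; ++i) {
      const double E = std::exp(-a[i] * d);
      const double g = -std::expm1(-a[i] * d) / a[i];  // (1-E)/a
      x[i] = E * x[i] + u * g;
    }
    if (has_jordan) {
      const double E = std::exp(-aj * d);
      const double g = -std::expm1(-aj * d) / aj;
      const double x1n = E * x1 + d * E * x2 + (u / aj) * (g - d * E);
      const double x2n = E * x2 + u * g;
      x1 = x1n; x2 = x2n;
    }
  }
  return y;
}
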