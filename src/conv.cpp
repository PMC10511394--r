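#include <Rcpp.h>
using namespace Rcpp;

// Discrete hereditary integral with midpoint kernel weights.
//
// d: (n-1) x m matrix of elastic hat-stress increments between consecutive
//    samples (column = stress component);
// q: (n-1) x m matrix of kernel weights, q(k, j) = Q_j((k + 1/2) dt);
// s0: m fully relaxed initial values.
// Returns the n x m convolved 2nd Piola-Kirchhoff components.
// [[Rcpp::export(name = ".conv_hereditary")]]
NumericMatrix conv_hereditary(NumericMatrix d, NumericMatrix q,
                              NumericVector s0) {
  const int n1 = d.nrow(), m = d.ncol();
  if (q.nrow() != n1 || q.ncol() != m || s0.size() != m)
    stop("inconsistent convolution inputs");
  NumericMatrix out(n1 + 1, m);
  for (int j = 0; j < m; ++j) {
    const double* dj = &d(0, j);
    const double* qj = &q(0, j);
    out(0, j) = s0[j];
    for (int i = 1; i <= n1; ++i) {
      double acc = 0.0;
      for (int k = 0; k < i; ++k) acc += qj[i - 1 - k] * dj[k];
      out(i, j) = s0[j] + acc;
    }
  }
  return out;
}
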