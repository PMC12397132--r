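#include <Rcpp.h>

// First-order recursive filter y[i] = w[i] + g * y[i-1], y[0] = w[0].
// Hot path of the exponential-integrator convolution used by the 2TCM
// forward model; called thousands of times per parametric volume.
// [[Rcpp::export(name = ".rec_filter")]]
Rcpp::NumericVector rec_filter(Rcpp::NumericVector w, double g) {
  R_xlen_t n = w.size();
  Rcpp::NumericVector y(n);
  double acc = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    acc = w[i] + g * acc;
    y[i] = acc;
  }
  return y;
}
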