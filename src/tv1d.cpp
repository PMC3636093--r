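#include <Rcpp.h>
using namespace Rcpp;

// Exact 1-D total-variation denoising:
//   minimise 0.5 * sum_i (x_i - y_i)^2 + lambda * sum_i |x_{i+1} - x_i|
// Direct O(n) single-pass algorithm (Condat-style tube walk). The solution
// is the unique minimiser of a strictly convex objective; optimality is
// certified in the test suite through the KKT conditions.
// [[Rcpp::export(name = ".tv1d_denoise")]]
NumericVector tv1d_denoise(NumericVector y, double lambda) {
  int width = y.size();
  NumericVector out(width);
  if (width == 0) return out;
  if (width == 1 || lambda <= 0.0) {
    for (int i = 0; i < width; ++i) out[i] = y[i];
    return out;
  }
  const double twolambda = 2.0 * lambda;
  const double minlambda = -lambda;
  int k = 0, k0 = 0, kminus = 0, kplus = 0;
  double umin = lambda, umax = minlambda;
  double vmin = y[0] - lambda, vmax = y[0] + lambda;
  for (;;) {
    while (k == width - 1) {
      if (umin < 0.0) {            // negative jump necessary
        do out[k0++] = vmin; while (k0 <= kminus);
        k = k0; kminus = k;
        vmin = y[kminus];
        umin = lambda;
        umax = vmin + umin - vmax;
      } else if (umax > 0.0) {     // positive jump necessary
        do out[k0++] = vmax; while (k0 <= kplus);
        k = k0; kplus = k;
        vmax = y[kplus];
        umax = minlambda;
        umin = vmax + umax - vmin;
      } else {                     // remainder is constant
        vmin += umin / (k - k0 + 1);
        do out[k0++] = vmin; while (k0 <= k);
        return out;
      }
    }
    umin += y[k + 1] - vmin;
    if (umin < minlambda) {        // negative jump
      do out[k0++] = vmin; while (k0 <= kminus);
      k = k0; kminus = k; kplus = k;
      vmin = y[k0];
      vmax = vmin + twolambda;
      umin = lambda; umax = minlambda;
    } else {
      umax += y[k + 1] - vmax;
      if (umax > lambda) {         // positive jump
        do out[k0++] = vmax; while (k0 <= kplus);
        k = k0; kminus = k; kplus = k;
        vmax = y[k0];
        vmin = vmax - twolambda;
        umin = lambda; umax = minlambda;
      } else {                     // no jump yet: extend the segment
        ++k;
        if (umin >= lambda) {      // update of vmin
          kminus = k;
          vmin += (umin - lambda) / (kminus - k0 + 1);
          umin = lambda;
        }
        if (umax <= minlambda) {   // update of vmax
          kplus = k;
          vmax += (umax + lambda) / (kplus - k0 + 1);
          umax = minlambda;
        }
      }
    }
  }
}
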