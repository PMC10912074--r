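#include <Rcpp.h>
using namespace Rcpp;

// Convolution of exp(-theta*t) with a piecewise-linear input defined on
// knots t[0..m-1] (t[0] = 0). Inputs are per-segment quantities:
//   dt[j]    = t[j+1] - t[j]
//   a[j]     = Cp(t[j])            (segment left value)
//   b[j]     = segment slope
// Returns F(t[k]) = int_0^{t(k)} exp(-theta*(t(k)-s)) Cp(s) ds at all knots.
// For theta == 0 this is the running integral of Cp.
// [[Rcpp::export(name = ".cpp_conv_exp")]]
NumericVector cpp_conv_exp(double theta, NumericVector dt, NumericVector a,
                           NumericVector b) {
  int m = dt.size();
  NumericVector F(m + 1);
  F[0] = 0.0;
  for (int j = 0; j < m; ++j) {
    double d = dt[j];
    double x = theta * d;
    double E, L;
    if (x < 1e-4) {
      // series expansion avoids cancellation in (d - (1-E)/theta)/theta
      E = std::exp(-x);
      double q1 = d * (1.0 - x / 2.0 + x * x / 6.0);        // (1-E)/theta
      double q2 = d * d * (0.5 - x / 6.0 + x * x / 24.0);   // (d - q1)/theta
      L = a[j] * q1 + b[j] * q2;
    } else {
      E = std::exp(-x);
      double q1 = (1.0 - E) / theta;
      L = a[j] * q1 + b[j] * (d - q1) / theta;
    }
    F[j + 1] = F[j] * E + L;
  }
  return F;
}

// Convolution of t*exp(-theta*t) with the same piecewise-linear input:
//   H(t) = int_0^t (t - s) exp(-theta*(t-s)) Cp(s) ds
// Needs F from cpp_conv_exp at the same theta. Used for the degenerate
// (repeated-eigenvalue) two-tissue solution.
// [[Rcpp::export(name = ".cpp_conv_texp")]]
NumericVector cpp_conv_texp(double theta, NumericVector dt, NumericVector a,
                            NumericVector b, NumericVector F) {
  int m = dt.size();
  NumericVector H(m + 1);
  H[0] = 0.0;
  for (int j = 0; j < m; ++j) {
    double d = dt[j];
    double x = theta * d;
    double E = std::exp(-x);
    double J1, J2; // int_0^d s e^{-theta s} ds, int_0^d s^2 e^{-theta s} ds
    if (x < 1e-3) {
      J1 = d * d * (0.5 - x / 3.0 + x * x / 8.0);
      J2 = d * d * d * (1.0 / 3.0 - x / 4.0 + x * x / 10.0);
    } else {
      J1 = (1.0 - E * (1.0 + x)) / (theta * theta);
      J2 = (2.0 - E * (x * x + 2.0 * x + 2.0)) / (theta * theta * theta);
    }
    double LH = (a[j] + b[j] * d) * J1 - b[j] * J2;
    H[j + 1] = E * (H[j] + d * F[j]) + LH;
  }
  return H;
}
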