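// Closed-loop (parallel-mode) NARX recursion.
//
// The recursion is inherently sequential, and closed-loop training needs
// it inside the residual function of a Levenberg-Marquardt loop with a
// numerical Jacobian, i.e. tens of thousands of trajectory evaluations
// per fit - the one hot loop in the package that justifies compiled code.

#include <Rcpp.h>
using namespace Rcpp;

// W: H x (Nx*Tx + Ny*Ty) effective hidden weights (feedback block already
// negated), row-major access via Rcpp matrix; X: n x Nx normalized
// envelopes; Yinit: n x Ny with the first `burn` rows holding the seed.
// Returns the full n x Ny normalized trajectory.
// ylo/yhi clamp the emitted predictions (normalized units) - the
// decoder's joint-limit guard; pass -Inf/Inf to disable.
// [[Rcpp::export(name = ".narx_simulate_cpp")]]
NumericMatrix narx_simulate_cpp(NumericMatrix W, NumericVector b1,
                                NumericMatrix C, NumericVector b2,
                                NumericMatrix X, NumericMatrix Yinit,
                                int m, int Tx, int Ty, int burn,
                                double ylo, double yhi) {
  const int n = X.nrow(), Nx = X.ncol();
  const int H = W.nrow();
  const int Ny = C.nrow();
  NumericMatrix Y(n, Ny);
  for (int t = 0; t < burn; ++t)
    for (int j = 0; j < Ny; ++j) Y(t, j) = Yinit(t, j);

  std::vector<double> z(Nx * Tx + Ny * Ty);
  std::vector<double> u(H);
  for (int t = burn; t < n; ++t) {
    int c = 0;
    for (int k = 0; k < Tx; ++k)
      for (int i = 0; i < Nx; ++i) z[c++] = X(t - m - k, i);
    for (int k = 0; k < Ty; ++k)
      for (int j = 0; j < Ny; ++j) z[c++] = Y(t - m - k, j);
    for (int h = 0; h < H; ++h) {
      double acc = b1[h];
      for (int q = 0; q < c; ++q) acc += W(h, q) * z[q];
      u[h] = std::tanh(acc);
    }
    for (int j = 0; j < Ny; ++j) {
      double acc = b2[j];
      for (int h = 0; h < H; ++h) acc += C(j, h) * u[h];
      if (acc < ylo) acc = ylo; else if (acc > yhi) acc = yhi;
      Y(t, j) = acc;
    }
  }
  return Y;
}
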