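#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Cyclic coordinate descent for the Lasso
//   min_x  1/2 ||A x - y||^2 + lambda ||x||_1
// in Gram form: G = A'A (n x n), c = A'y.  The running vector Gx = G x is
// maintained incrementally so each coordinate update is O(n).  Convergence is
// declared when the largest coordinate change in a full sweep falls below
// `tol_change`; the R wrapper verifies the KKT residual independently and
// tightens tol_change if needed.
// [[Rcpp::export]]
List lasso_cd_gram(NumericMatrix G, NumericVector c, double lambda,
                   NumericVector x0, double tol_change, int max_iter) {
  const int n = c.size();
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> Gx(n, 0.0);
  for (int j = 0; j < n; ++j) {
    if (x[j] != 0.0) {
      const double xj = x[j];
      for (int i = 0; i < n; ++i) Gx[i] += G(i, j) * xj;
    }
  }
  int sweeps = 0;
  double maxdel = R_PosInf;
  while (sweeps < max_iter) {
    ++sweeps;
    maxdel = 0.0;
    for (int j = 0; j < n; ++j) {
      const double gjj = G(j, j);
      if (gjj <= 0.0) continue;  // all-zero column: coefficient stays 0
      const double zj = x[j] - (Gx[j] - c[j]) / gjj;
      const double t = lambda / gjj;
      double xnew = 0.0;
      if (zj > t) xnew = zj - t;
      else if (zj < -t) xnew = zj + t;
      const double d = xnew - x[j];
      if (d != 0.0) {
        x[j] = xnew;
        for (int i = 0; i < n; ++i) Gx[i] += G(i, j) * d;
        const double ad = std::fabs(d);
        if (ad > maxdel) maxdel = ad;
      }
    }
    if (maxdel < tol_change) break;
  }
  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["sweeps"] = sweeps,
                      _["max_delta"] = maxdel);
}
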