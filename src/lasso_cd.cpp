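#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent for the l1-penalized least-squares problem
//   min_w ||y - X w||_2^2 + lambda * ||w||_1
// expressed through the Gram matrix G = X'X and the correlation vector
// b = X'y.  Sweeps cycle over coordinates; convergence is declared when the
// largest absolute coefficient change within a sweep falls below tol.
//
// [[Rcpp::export(name = ".lassoCD")]]
List lassoCD(NumericMatrix G, NumericVector b, double lambda,
             double tol, int maxSweeps, NumericVector w0) {
  int p = b.size();
  NumericVector w = clone(w0);
  double thr = lambda / 2.0;
  double maxChange = R_PosInf;
  int sweeps = 0;
  while (sweeps < maxSweeps && maxChange >= tol) {
    maxChange = 0.0;
    for (int j = 0; j < p; ++j) {
      double gj = G(j, j);
      if (gj <= 0.0) { w[j] = 0.0; continue; }
      // partial residual correlation for coordinate j
      double cj = b[j];
      for (int k = 0; k < p; ++k)
        if (k != j) cj -= G(j, k) * w[k];
      double wnew = 0.0;
      if (cj > thr) wnew = (cj - thr) / gj;
      else if (cj < -thr) wnew = (cj + thr) / gj;
      double d = std::fabs(wnew - w[j]);
      if (d > maxChange) maxChange = d;
      w[j] = wnew;
    }
    ++sweeps;
  }
  return List::create(_["w"] = w, _["sweeps"] = sweeps,
                      _["maxChange"] = maxChange,
                      _["converged"] = maxChange < tol);
}
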