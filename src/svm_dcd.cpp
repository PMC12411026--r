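#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Dual coordinate descent for the L2-regularized L1-loss (hinge) linear SVM:
//   min_w 0.5 ||w||^2 + C sum_i max(0, 1 - y_i w.x_i)
// solved in the dual with box constraints 0 <= alpha_i <= C (Hsieh et al.,
// ICML 2008). The bias is handled by an augmented constant feature appended
// in R. A fixed cyclic sweep order makes the solver fully deterministic.
// [[Rcpp::export]]
List svm_dcd_fit(NumericMatrix X, NumericVector y, double C,
                 int max_epochs, double tol) {
  const int n = X.nrow(), p = X.ncol();
  NumericVector alpha(n), w(p), qii(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < p; ++j) s += X(i, j) * X(i, j);
    qii[i] = s;
  }
  int epoch = 0;
  bool converged = false;
  for (; epoch < max_epochs; ++epoch) {
    double max_pg = 0.0;
    for (int i = 0; i < n; ++i) {
      if (qii[i] <= 0.0) continue;
      double g = 0.0;
      for (int j = 0; j < p; ++j) g += w[j] * X(i, j);
      g = y[i] * g - 1.0;
      double pg = g;
      if (alpha[i] <= 0.0 && g > 0.0) pg = 0.0;
      else if (alpha[i] >= C && g < 0.0) pg = 0.0;
      if (std::fabs(pg) > max_pg) max_pg = std::fabs(pg);
      if (std::fabs(pg) > 1e-12) {
        double old = alpha[i];
        double na = old - g / qii[i];
        if (na < 0.0) na = 0.0; else if (na > C) na = C;
        alpha[i] = na;
        double d = (na - old) * y[i];
        if (d != 0.0) for (int j = 0; j < p; ++j) w[j] += d * X(i, j);
      }
    }
    if (max_pg < tol) { converged = true; break; }
  }
  return List::create(_["w"] = w, _["alpha"] = alpha,
                      _["epochs"] = epoch + 1, _["converged"] = converged);
}
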