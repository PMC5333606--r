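#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Dual coordinate descent for the linear-kernel C-SVM (hinge loss), the
// algorithm of Hsieh et al. (2008) as used by LIBLINEAR. The bias is handled
// by augmenting each observation with a constant unit feature, so it is
// (weakly) regularized; at the cohort sizes used here this is numerically
// indistinguishable from an unregularized intercept. Deterministic: the
// per-epoch coordinate order comes from an internal xorshift generator with
// a fixed seed, so results do not depend on (or disturb) R's RNG state.
//
// X: n x p predictor matrix (standardize beforehand; linear SVMs are
// scale-sensitive), y: labels in {-1, +1}, cost: the C parameter.
// [[Rcpp::export(rng = false)]]
List svc_linear_dcd(const NumericMatrix& X, const NumericVector& y,
                    double cost, double eps = 1e-4, int max_epochs = 2000) {
  const int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("length(y) must equal nrow(X)");
  const int pb = p + 1;  // augmented bias feature

  std::vector<double> w(pb, 0.0), alpha(n, 0.0), Qii(n);
  for (int i = 0; i < n; ++i) {
    double q = 1.0;  // bias feature
    for (int j = 0; j < p; ++j) q += X(i, j) * X(i, j);
    Qii[i] = q;
  }

  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  unsigned long long rng = 88172645463325252ULL;  // fixed xorshift64 state

  int epoch = 0;
  bool converged = false;
  for (; epoch < max_epochs; ++epoch) {
    // Fisher-Yates with the internal generator
    for (int i = n - 1; i > 0; --i) {
      rng ^= rng << 13; rng ^= rng >> 7; rng ^= rng << 17;
      const int j = static_cast<int>(rng % static_cast<unsigned long long>(i + 1));
      std::swap(idx[i], idx[j]);
    }
    double maxpg = 0.0;
    for (int t = 0; t < n; ++t) {
      const int i = idx[t];
      double g = w[p];  // bias feature contribution
      for (int j = 0; j < p; ++j) g += w[j] * X(i, j);
      g = y[i] * g - 1.0;
      // projected gradient for the box constraint [0, C]
      double pg = g;
      if (alpha[i] <= 0.0 && g > 0.0) pg = 0.0;
      if (alpha[i] >= cost && g < 0.0) pg = 0.0;
      if (std::fabs(pg) > maxpg) maxpg = std::fabs(pg);
      if (pg != 0.0) {
        const double old = alpha[i];
        double a = old - g / Qii[i];
        if (a < 0.0) a = 0.0;
        if (a > cost) a = cost;
        alpha[i] = a;
        const double step = (a - old) * y[i];
        for (int j = 0; j < p; ++j) w[j] += step * X(i, j);
        w[p] += step;
      }
    }
    if (maxpg < eps) { converged = true; break; }
  }

  NumericVector wout(p);
  for (int j = 0; j < p; ++j) wout[j] = w[j];
  return List::create(_["w"] = wout, _["b"] = w[p],
                      _["epochs"] = epoch + 1, _["converged"] = converged);
}
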