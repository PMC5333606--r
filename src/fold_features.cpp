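#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// One pass over all subjects x pairs: residual Z-scores against the fitted
// per-pair baselines, thresholded on |w| > thr. Returns each subject's link
// density (links over all possible pairs) and the surviving links as edge
// index vectors, without materializing the dense weight matrix. Degenerate
// pairs and pairs with missing values never link.
// [[Rcpp::export(rng = false)]]
List fold_network_features(const NumericMatrix& F, const IntegerVector& kidx,
                           const IntegerVector& lidx, const NumericVector& a,
                           const NumericVector& b, const NumericVector& s,
                           const LogicalVector& degen, const double thr) {
  const int n = F.nrow();
  const int np = kidx.size();
  const int nf = F.ncol();
  const double np_all = static_cast<double>(nf) * (nf - 1) / 2.0;
  NumericVector density(n);
  List ki(n), li(n);
  std::vector<int> ebuf_k, ebuf_l;
  ebuf_k.reserve(np); ebuf_l.reserve(np);
  for (int i = 0; i < n; ++i) {
    ebuf_k.clear(); ebuf_l.clear();
    for (int p = 0; p < np; ++p) {
      if (degen[p]) continue;
      const double w =
          (F(i, lidx[p] - 1) - a[p] - b[p] * F(i, kidx[p] - 1)) / s[p];
      if (!std::isfinite(w)) continue;
      if (std::fabs(w) > thr) {
        ebuf_k.push_back(kidx[p]);
        ebuf_l.push_back(lidx[p]);
      }
    }
    density[i] = ebuf_k.size() / np_all;
    ki[i] = IntegerVector(ebuf_k.begin(), ebuf_k.end());
    li[i] = IntegerVector(ebuf_l.begin(), ebuf_l.end());
  }
  return List::create(_["density"] = density, _["ki"] = ki, _["li"] = li);
}
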