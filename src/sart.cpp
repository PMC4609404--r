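// One SART sweep over all views: for each view, a simultaneous update of
// the image from that view's rays with row-sum/column-sum normalization,
// relaxation and a nonnegativity clamp. Operates on the system matrix in
// CSR layout (rows = rays, view-major) so a view is a contiguous row
// block.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// [[Rcpp::export]]
NumericVector cpp_sart_sweep(const IntegerVector &row_ptr,
                             const IntegerVector &col_idx,
                             const NumericVector &vals,
                             const NumericVector &l_hat, int n_views,
                             int n_det, int n2, double relax,
                             NumericVector mu) {
  NumericVector out = clone(mu);
  double *o = REAL(out);
  const int *rp = INTEGER(row_ptr);
  const int *ci = INTEGER(col_idx);
  const double *vx = REAL(vals);
  const double *lh = REAL(l_hat);
  std::vector<double> colsum(n2, 0.0), upd(n2, 0.0);
  for (int v = 0; v < n_views; ++v) {
    const int r0 = v * n_det, r1 = (v + 1) * n_det;
    for (int i = r0; i < r1; ++i) {
      double fp = 0.0, rs = 0.0;
      for (int t = rp[i]; t < rp[i + 1]; ++t) {
        fp += vx[t] * o[ci[t]];
        rs += vx[t];
      }
      if (rs <= 0) continue;
      const double corr = (lh[i] - fp) / rs;
      for (int t = rp[i]; t < rp[i + 1]; ++t) {
        upd[ci[t]] += vx[t] * corr;
        colsum[ci[t]] += vx[t];
      }
    }
    for (int i = r0; i < r1; ++i) {
      for (int t = rp[i]; t < rp[i + 1]; ++t) {
        const int j = ci[t];
        if (colsum[j] > 0) {
          o[j] += relax * upd[j] / colsum[j];
          if (o[j] < 0) o[j] = 0;
          colsum[j] = 0;  // apply once per view, reset for the next
          upd[j] = 0;
        }
      }
    }
  }
  return out;
}
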