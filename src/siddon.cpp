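// Ray-driven fan-beam projector: exact ray/pixel intersection lengths
// (Siddon-style parametric traversal).
//
// Conventions (shared with the R side):
//   * image origin at the grid centre; pixel (row r, col c), 1-based,
//     row 1 at the TOP; vectorised row-major: j = (r-1)*N + c;
//   * pixel (r,c) spans x in [x0+(c-1)*px, x0+c*px],
//     y in [ytop-r*px, ytop-(r-1)*px], with x0 = -N*px/2, ytop = N*px/2;
//   * view angle theta_v = (v-1)*step in degrees, source at
//     S = Rs*(cos t, sin t), flat detector centred at -Rd*(cos t, sin t)
//     along e_perp = (-sin t, cos t), element k centred at
//     u_k = (k-(nd+1)/2)*du, du = span/nd;
//   * ray index i = (v-1)*nd + k (view-major).

#include <RcppArmadillo.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct RayHits {
  std::vector<int> j;       // 1-based pixel index
  std::vector<double> len;  // intersection length
};

// Trace the segment S -> P across the N x N grid with pixel size px.
void trace_segment(double sx, double sy, double px_, double py_,
                   int N, double px, RayHits &out) {
  out.j.clear();
  out.len.clear();
  const double dx = px_ - sx, dy = py_ - sy;
  const double L = std::sqrt(dx * dx + dy * dy);
  if (L <= 0) return;
  const double half = 0.5 * N * px;
  const double eps = 1e-12 * std::max(1.0, half);

  // clip the parametric range to the grid bounding box
  double a0 = 0.0, a1 = 1.0;
  if (std::abs(dx) < eps * 1e-3) {
    if (sx <= -half || sx >= half) return;
  } else {
    double t1 = (-half - sx) / dx, t2 = (half - sx) / dx;
    if (t1 > t2) std::swap(t1, t2);
    a0 = std::max(a0, t1);
    a1 = std::min(a1, t2);
  }
  if (std::abs(dy) < eps * 1e-3) {
    if (sy <= -half || sy >= half) return;
  } else {
    double t1 = (-half - sy) / dy, t2 = (half - sy) / dy;
    if (t1 > t2) std::swap(t1, t2);
    a0 = std::max(a0, t1);
    a1 = std::min(a1, t2);
  }
  if (a1 <= a0) return;

  // crossing parameters with the pixel grid lines
  std::vector<double> alphas;
  alphas.reserve(2 * N + 4);
  alphas.push_back(a0);
  alphas.push_back(a1);
  if (std::abs(dx) >= eps * 1e-3) {
    for (int m = 0; m <= N; ++m) {
      double xm = -half + m * px;
      double t = (xm - sx) / dx;
      if (t > a0 && t < a1) alphas.push_back(t);
    }
  }
  if (std::abs(dy) >= eps * 1e-3) {
    for (int m = 0; m <= N; ++m) {
      double ym = -half + m * px;
      double t = (ym - sy) / dy;
      if (t > a0 && t < a1) alphas.push_back(t);
    }
  }
  std::sort(alphas.begin(), alphas.end());

  for (size_t s = 0; s + 1 < alphas.size(); ++s) {
    double ta = alphas[s], tb = alphas[s + 1];
    double seg = (tb - ta) * L;
    if (seg <= eps) continue;
    double tm = 0.5 * (ta + tb);
    double xm = sx + tm * dx, ym = sy + tm * dy;
    int c = (int)std::floor((xm + half) / px);  // 0-based column
    int r = (int)std::floor((half - ym) / px);  // 0-based row (top = 0)
    if (c < 0 || c >= N || r < 0 || r >= N) continue;
    int j = r * N + c + 1;  // 1-based row-major
    out.j.push_back(j);
    out.len.push_back(seg);
  }
}

inline void ray_endpoints(int v, int k, double step_deg, int nd,
                          double Rs, double Rd, double span,
                          double &sx, double &sy, double &px_, double &py_) {
  const double t = (v - 1) * step_deg * M_PI / 180.0;
  const double ct = std::cos(t), st = std::sin(t);
  sx = Rs * ct;
  sy = Rs * st;
  const double du = span / nd;
  const double u = (k - 0.5 * (nd + 1)) * du;
  px_ = -Rd * ct - u * st;
  py_ = -Rd * st + u * ct;
}

}  // namespace

// [[Rcpp::export]]
List cpp_trace_ray(int view, int detector, int n_views, double step_deg,
                   int nd, int N, double px, double Rs, double Rd,
                   double span) {
  double sx, sy, ex, ey;
  ray_endpoints(view, detector, step_deg, nd, Rs, Rd, span, sx, sy, ex, ey);
  RayHits h;
  trace_segment(sx, sy, ex, ey, N, px, h);
  return List::create(_["j"] = wrap(h.j), _["a"] = wrap(h.len));
}

// All rays of the scan, as sparse triplets (ray i, pixel j, length a),
// both indices 1-based, rays view-major.
// [[Rcpp::export]]
List cpp_system_triplets(int n_views, double step_deg, int nd, int N,
                         double px, double Rs, double Rd, double span) {
  std::vector<int> ri, cj;
  std::vector<double> xx;
  const size_t guess = (size_t)n_views * nd * (size_t)(2 * N);
  ri.reserve(guess);
  cj.reserve(guess);
  xx.reserve(guess);
  RayHits h;
  for (int v = 1; v <= n_views; ++v) {
    for (int k = 1; k <= nd; ++k) {
      double sx, sy, ex, ey;
      ray_endpoints(v, k, step_deg, nd, Rs, Rd, span, sx, sy, ex, ey);
      trace_segment(sx, sy, ex, ey, N, px, h);
      int i = (v - 1) * nd + k;
      for (size_t m = 0; m < h.j.size(); ++m) {
        ri.push_back(i);
        cj.push_back(h.j[m]);
        xx.push_back(h.len[m]);
      }
    }
  }
  return List::create(_["i"] = wrap(ri), _["j"] = wrap(cj),
                      _["x"] = wrap(xx));
}
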