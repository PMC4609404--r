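// Sparse-coding and dictionary-learning kernels: Gram-based batch
// orthogonal matching pursuit (incremental Cholesky) and K-SVD atom
// updates.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uvec;

namespace {

// Reusable OMP workspace (avoids per-signal allocations).
struct OmpWork {
  int K, L;
  vec corr;          // current correlations D'(x - D alpha)
  mat R;             // L x L upper-triangular Cholesky of G[A,A]
  mat GA;            // K x L selected Gram columns
  vec cA, beta, w;   // projections / coefficients on the active set
  std::vector<int> atoms;
  std::vector<char> used;
  OmpWork(int K_, int L_)
      : K(K_), L(L_), corr(K_), R(L_, L_), GA(K_, L_), cA(L_), beta(L_),
        w(L_), used(K_) {}
};

// OMP for one signal in the Gram formulation: G = D'D, c0 = D'x,
// x2 = x'x. Greedy max-|correlation| selection with least-squares refit
// on the active set via an incrementally grown Cholesky factor; stops at
// L atoms or when the residual norm falls below tol. Never reselects.
void omp_one(const mat &G, const vec &c0, double x2, double tol,
             OmpWork &ws) {
  ws.atoms.clear();
  std::fill(ws.used.begin(), ws.used.end(), 0);
  ws.corr = c0;
  double res2 = x2;
  const double tol2 = tol * tol;
  int m = 0;
  while (m < ws.L) {
    if (res2 <= tol2) break;
    int best = -1;
    double bv = 1e-14;
    for (int k = 0; k < ws.K; ++k) {
      double a = std::abs(ws.corr(k));
      if (!ws.used[k] && a > bv) {
        bv = a;
        best = k;
      }
    }
    if (best < 0) break;
    ws.used[best] = 1;
    // grow the Cholesky factor of G[A,A]
    double gkk = G(best, best);
    if (m > 0) {
      for (int r = 0; r < m; ++r) ws.w(r) = G(ws.atoms[r], best);
      // solve R(0:m,0:m)' z = w  (forward substitution)
      for (int r = 0; r < m; ++r) {
        double s = ws.w(r);
        for (int t = 0; t < r; ++t) s -= ws.R(t, r) * ws.w(t);
        ws.w(r) = s / ws.R(r, r);
      }
      double wn = 0;
      for (int r = 0; r < m; ++r) {
        ws.R(r, m) = ws.w(r);
        wn += ws.w(r) * ws.w(r);
      }
      gkk -= wn;
    }
    if (gkk <= 1e-12) {  // numerically dependent atom: stop
      ws.used[best] = 1;
      break;
    }
    ws.R(m, m) = std::sqrt(gkk);
    ws.atoms.push_back(best);
    ws.GA.col(m) = G.col(best);
    ws.cA(m) = c0(best);
    ++m;
    // beta = (G[A,A])^-1 c0[A] via the Cholesky factor
    for (int r = 0; r < m; ++r) {
      double s = ws.cA(r);
      for (int t = 0; t < r; ++t) s -= ws.R(t, r) * ws.beta(t);
      ws.beta(r) = s / ws.R(r, r);
    }
    double fit = 0;
    for (int r = m - 1; r >= 0; --r) {
      double s = ws.beta(r);
      for (int t = r + 1; t < m; ++t) s -= ws.R(r, t) * ws.beta(t);
      ws.beta(r) = s / ws.R(r, r);
    }
    for (int r = 0; r < m; ++r) fit += ws.beta(r) * ws.cA(r);
    res2 = x2 - fit;
    if (m < ws.L && res2 > tol2) {
      ws.corr = c0 - ws.GA.cols(0, m - 1) * ws.beta.subvec(0, m - 1);
    }
  }
}

}  // namespace

// Batch OMP over the columns of X. Returns triplets (atom k, signal s,
// coefficient), 1-based, suitable for Matrix::sparseMatrix.
// [[Rcpp::export]]
List cpp_batch_omp(const arma::mat &D, const arma::mat &X, int L,
                   double rel_tol) {
  const int S = X.n_cols;
  const int K = D.n_cols;
  mat G = D.t() * D;
  mat C0 = D.t() * X;  // K x S
  std::vector<int> ai, si;
  std::vector<double> cx;
  ai.reserve((size_t)S * L);
  si.reserve((size_t)S * L);
  cx.reserve((size_t)S * L);
  OmpWork ws(K, L);
  for (int s = 0; s < S; ++s) {
    double x2 = arma::dot(X.col(s), X.col(s));
    omp_one(G, C0.col(s), x2, rel_tol * std::sqrt(x2), ws);
    for (size_t t = 0; t < ws.atoms.size(); ++t) {
      ai.push_back(ws.atoms[t] + 1);
      si.push_back(s + 1);
      cx.push_back(ws.beta(t));
    }
  }
  return List::create(_["i"] = wrap(ai), _["j"] = wrap(si),
                      _["x"] = wrap(cx));
}

// K-SVD: alternate batch-OMP coding with a dictionary-update stage of
// `n_sweeps` atom-by-atom rank-1 passes (SVD of the residual restricted
// to each atom's support; the atom's coefficients are refreshed
// simultaneously). Between iterations the dictionary is cleared:
// near-duplicate atoms (mutual coherence > purge_coherence, the
// duplicate's coefficients handed to its twin) and unused atoms are
// re-seeded from the principal direction of the residuals of the
// worst-represented signals. Deterministic given D0 and X.
// [[Rcpp::export]]
List cpp_ksvd(const arma::mat &X, const arma::mat &D0, int L, int n_iters,
              double rel_tol, int n_sweeps, double purge_coherence) {
  mat D = D0;
  const int K = D.n_cols;
  const int S = X.n_cols;
  const int topj = std::min(40, S);  // residual block used for re-seeding
  std::vector<double> objective;
  objective.reserve(n_iters);
  mat A(K, S);
  OmpWork ws(K, L);

  for (int it = 0; it < n_iters; ++it) {
    // sparse coding
    mat G = D.t() * D;
    mat C0 = D.t() * X;
    A.zeros();
    for (int s = 0; s < S; ++s) {
      double x2 = arma::dot(X.col(s), X.col(s));
      omp_one(G, C0.col(s), x2, rel_tol * std::sqrt(x2), ws);
      for (size_t t = 0; t < ws.atoms.size(); ++t) {
        A(ws.atoms[t], s) = ws.beta(t);
      }
    }

    // dictionary-update stage: n_sweeps atom-by-atom passes over a
    // maintained residual
    for (int sw = 0; sw < n_sweeps; ++sw) {
      mat R = X - D * A;
      for (int k = 0; k < K; ++k) {
        uvec I = arma::find(arma::abs(A.row(k)) > 0);
        if (I.n_elem == 0) continue;  // handled by the clearing step
        uvec rk{(arma::uword)k};
        mat Ek = R.cols(I) + D.col(k) * A.submat(rk, I);
        mat U, V;
        vec sv;
        bool ok = arma::svd_econ(U, sv, V, Ek);
        if (!ok || U.n_cols == 0 || sv(0) <= 1e-14) continue;
        vec dnew = U.col(0);
        arma::rowvec anew = sv(0) * V.col(0).t();
        R.cols(I) = Ek - dnew * anew;
        D.col(k) = dnew;
        A.submat(rk, I) = anew;
      }
    }
    objective.push_back(arma::accu(arma::square(X - D * A)));

    // dictionary clearing (between iterations only)
    if (it + 1 < n_iters) {
      mat Gd = arma::abs(D.t() * D);
      Gd.diag().zeros();
      mat R = X - D * A;
      vec rn = arma::sum(arma::square(R), 0).t();
      vec use = arma::conv_to<vec>::from(arma::sum(arma::abs(A) > 0, 1));
      for (int k = 0; k < K; ++k) {
        int twin = -1;
        double best = purge_coherence;
        for (int j = 0; j < k; ++j) {
          if (Gd(j, k) > best) {
            best = Gd(j, k);
            twin = j;
          }
        }
        if (twin < 0 && use(k) > 0) continue;
        if (twin >= 0) {
          double sgn = arma::dot(D.col(twin), D.col(k)) >= 0 ? 1.0 : -1.0;
          A.row(twin) += sgn * A.row(k);
          A.row(k).zeros();
        }
        // re-seed from the principal residual direction of the worst
        // signals (those dominated by a missing dictionary direction)
        uvec ord = arma::sort_index(rn, "descend");
        uvec wj = ord.head(topj);
        mat U, V;
        vec sv;
        bool ok = arma::svd_econ(U, sv, V, R.cols(wj), "left");
        if (ok && U.n_cols > 0 && sv.n_elem > 0 && sv(0) > 1e-12) {
          D.col(k) = U.col(0);
          rn.elem(wj).zeros();  // spread multiple re-seeds across signals
          Gd.col(k) = arma::abs(D.t() * D.col(k));
          Gd.row(k) = Gd.col(k).t();
          Gd(k, k) = 0;
        }
      }
    }
  }
  return List::create(_["D"] = wrap(D), _["objective"] = wrap(objective));
}
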