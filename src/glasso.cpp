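// Graphical lasso by block coordinate descent (W-update form):
// maximize log det(Theta) - tr(S Theta) - lam * sum_{i!=j} |Theta_ij|
// The diagonal is unpenalized unless penalize_diag is set, in which case
// lam is added to the working covariance diagonal.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static inline double soft_thr(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// cyclic coordinate descent for  min_b 1/2 b'Vb - u'b + lam ||b||_1
static void lasso_cd(const mat& V, const vec& u, double lam, vec& b,
                     double tol, int maxit) {
  const uword m = b.n_elem;
  for (int it = 0; it < maxit; ++it) {
    double dmax = 0.0;
    for (uword j = 0; j < m; ++j) {
      const double bj_old = b(j);
      double r = u(j) - dot(V.col(j), b) + V(j, j) * bj_old;
      const double bj = soft_thr(r, lam) / V(j, j);
      if (bj != bj_old) {
        b(j) = bj;
        const double d = std::abs(bj - bj_old);
        if (d > dmax) dmax = d;
      }
    }
    if (dmax < tol) break;
  }
}

// One glasso solve with warm-started working covariance W and coefficient
// matrix B (column j holds the lasso coefficients of variable j on the rest;
// B has a structural zero diagonal).  status: 0 ok, 1 max_iter, 2 singular.
static int glasso_solve(const mat& S, double lam, double tol, int maxit,
                        bool penalize_diag, mat& W, mat& B, mat& Theta,
                        double& last_gap, int& n_iter) {
  const uword p = S.n_rows;
  if (p == 1) {
    W = S;
    Theta.set_size(1, 1);
    Theta(0, 0) = 1.0 / S(0, 0);
    n_iter = 0;
    return 0;
  }

  // convergence threshold on the average absolute change of W off-diagonals
  double mean_off = 0.0;
  for (uword i = 0; i < p; ++i)
    for (uword j = i + 1; j < p; ++j) mean_off += std::abs(S(i, j));
  mean_off /= (p * (p - 1)) / 2.0;
  const double thr = tol * std::max(mean_off, 1e-12);

  const double inner_tol = std::min(tol * 1e-2, 1e-7);
  const int inner_maxit = 10000;

  // working covariance: start from S (diagonal fixed at S_ii [+ lam])
  for (uword j = 0; j < p; ++j) {
    W(j, j) = S(j, j) + (penalize_diag ? lam : 0.0);
  }

  uvec all = regspace<uvec>(0, p - 1);
  int it = 0;
  double gap = datum::inf;
  for (it = 0; it < maxit; ++it) {
    double dmax = 0.0;
    for (uword j = 0; j < p; ++j) {
      uvec others = find(all != j);
      mat V = W.submat(others, others);
      vec u = S.col(j);
      u = u.elem(others);
      vec b = B.col(j);
      b = b.elem(others);
      lasso_cd(V, u, lam, b, inner_tol, inner_maxit);
      vec w12 = V * b;
      for (uword k = 0; k < others.n_elem; ++k) {
        const uword i = others(k);
        const double d = std::abs(W(i, j) - w12(k));
        if (d > dmax) dmax = d;
        W(i, j) = w12(k);
        W(j, i) = w12(k);
        B(i, j) = b(k);
      }
      if (!W.is_finite()) return 2;
    }
    gap = dmax;
    if (dmax < thr) { ++it; break; }
  }
  last_gap = gap;
  n_iter = it;

  // recover Theta from W and B
  Theta.zeros(p, p);
  for (uword j = 0; j < p; ++j) {
    double quad = 0.0;
    for (uword i = 0; i < p; ++i)
      if (i != j) quad += W(i, j) * B(i, j);
    const double denom = W(j, j) - quad;
    if (!(denom > 0.0) || !std::isfinite(denom)) return 2;
    Theta(j, j) = 1.0 / denom;
    for (uword i = 0; i < p; ++i)
      if (i != j) Theta(i, j) = -B(i, j) / denom;
  }
  Theta = 0.5 * (Theta + Theta.t());
  if (gap >= thr && maxit > 0) return 1;
  return 0;
}

// [[Rcpp::export]]
Rcpp::List glasso_cpp(const arma::mat& S, double lam, double tol, int maxit,
                      bool penalize_diag) {
  mat W = S, B(S.n_rows, S.n_cols, fill::zeros), Theta;
  double gap = 0.0;
  int iter = 0;
  int status = glasso_solve(S, lam, tol, maxit, penalize_diag, W, B, Theta,
                            gap, iter);
  return Rcpp::List::create(Rcpp::Named("theta") = Theta,
                            Rcpp::Named("w") = W,
                            Rcpp::Named("status") = status,
                            Rcpp::Named("iter") = iter,
                            Rcpp::Named("gap") = gap);
}

// Path over a decreasing lambda grid with warm starts.
// [[Rcpp::export]]
Rcpp::List glasso_path_cpp(const arma::mat& S, const arma::vec& lambdas,
                           double tol, int maxit, bool penalize_diag) {
  const uword p = S.n_rows, K = lambdas.n_elem;
  mat W = S, B(p, p, fill::zeros), Theta;
  Rcpp::List thetas(K);
  Rcpp::IntegerVector status(K);
  Rcpp::NumericVector gaps(K);
  for (uword k = 0; k < K; ++k) {
    double gap = 0.0;
    int iter = 0;
    // reset the working state if the previous lambda failed
    if (k > 0 && status(k - 1) != 0) {
      W = S;
      B.zeros();
    }
    int st = glasso_solve(S, lambdas(k), tol, maxit, penalize_diag, W, B,
                          Theta, gap, iter);
    status(k) = st;
    gaps(k) = gap;
    if (st == 2) {
      thetas[k] = Rcpp::NumericMatrix(0, 0);
    } else {
      thetas[k] = Rcpp::wrap(Theta);
    }
  }
  return Rcpp::List::create(Rcpp::Named("thetas") = thetas,
                            Rcpp::Named("status") = status,
                            Rcpp::Named("gaps") = gaps);
}
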