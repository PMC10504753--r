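// Graphical lasso by block coordinate descent (Friedman-style W updates)
// with an elementwise penalty matrix, plus an EBIC path selector.
// The elementwise penalty doubles as the device for pattern-constrained
// ML refits: a very large penalty on an entry forces it to exact zero.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft(double x, double lam) {
  if (x > lam) return x - lam;
  if (x < -lam) return x + lam;
  return 0.0;
}

// One full solve. W and B are warm-start in/out:
//   W approximates the estimated covariance, B(k,j) the lasso coefficient
//   of variable k in the column-j subproblem.
// Returns the number of outer sweeps used (negative if not converged).
static int glasso_core(const mat& S, const mat& Lambda, double thr,
                       int maxit, mat& W, mat& B) {
  const uword p = S.n_rows;
  const int inner_max = 200;
  const double thr_in = thr / 10.0;

  // diagonal is fixed by the stationarity condition W_jj = S_jj + Lambda_jj
  for (uword j = 0; j < p; ++j) W(j, j) = S(j, j) + Lambda(j, j);

  int it;
  for (it = 1; it <= maxit; ++it) {
    double dmax = 0.0;
    for (uword j = 0; j < p; ++j) {
      // coordinate descent on the column-j lasso subproblem
      for (int in_it = 0; in_it < inner_max; ++in_it) {
        double dbeta = 0.0;
        for (uword k = 0; k < p; ++k) {
          if (k == j) continue;
          double r = S(k, j);
          for (uword l = 0; l < p; ++l) {
            if (l == j || l == k) continue;
            r -= W(k, l) * B(l, j);
          }
          double bnew = soft(r, Lambda(k, j)) / W(k, k);
          double d = std::abs(bnew - B(k, j));
          if (d > dbeta) dbeta = d;
          B(k, j) = bnew;
        }
        if (dbeta < thr_in) break;
      }
      // w12 = W11 * beta
      for (uword k = 0; k < p; ++k) {
        if (k == j) continue;
        double w = 0.0;
        for (uword l = 0; l < p; ++l) {
          if (l == j) continue;
          w += W(k, l) * B(l, j);
        }
        double d = std::abs(w - W(k, j));
        if (d > dmax) dmax = d;
        W(k, j) = w;
        W(j, k) = w;
      }
    }
    if (dmax < thr) return it;
  }
  return -maxit;
}

// Recover the precision matrix from (W, B).
static mat theta_from_wb(const mat& W, const mat& B) {
  const uword p = W.n_rows;
  mat Theta(p, p, fill::zeros);
  for (uword j = 0; j < p; ++j) {
    double denom = W(j, j);
    for (uword k = 0; k < p; ++k) {
      if (k != j) denom -= W(k, j) * B(k, j);
    }
    Theta(j, j) = 1.0 / denom;
  }
  for (uword j = 0; j < p; ++j) {
    for (uword k = 0; k < p; ++k) {
      if (k == j) continue;
      Theta(k, j) = -B(k, j) * Theta(j, j);
    }
  }
  // symmetrize, preserving exact zeros of the penalized solution
  for (uword j = 0; j < p; ++j) {
    for (uword k = j + 1; k < p; ++k) {
      if (Theta(k, j) == 0.0 && Theta(j, k) == 0.0) continue;
      double v = 0.5 * (Theta(k, j) + Theta(j, k));
      Theta(k, j) = v;
      Theta(j, k) = v;
    }
  }
  return Theta;
}

static double avg_abs_offdiag(const mat& S) {
  const uword p = S.n_rows;
  double s = 0.0;
  for (uword j = 0; j < p; ++j)
    for (uword k = 0; k < p; ++k)
      if (k != j) s += std::abs(S(k, j));
  double denom = (double)(p * (p - 1));
  return denom > 0 ? s / denom : 0.0;
}

// Gaussian log-likelihood at Theta given sample correlation S and n rows.
static double ggm_loglik(const mat& Theta, const mat& S, double n) {
  double ld, sign;
  log_det(ld, sign, Theta);
  double tr = accu(S % Theta);
  double p = (double)S.n_rows;
  return 0.5 * n * (ld - tr - p * std::log(2.0 * M_PI));
}

// [[Rcpp::export]]
Rcpp::List glasso_cpp(const arma::mat& S, const arma::mat& Lambda,
                      double tol, int maxit,
                      Rcpp::Nullable<Rcpp::NumericMatrix> W_init = R_NilValue,
                      Rcpp::Nullable<Rcpp::NumericMatrix> B_init = R_NilValue) {
  const uword p = S.n_rows;
  mat W = W_init.isNotNull() ? mat(Rcpp::as<mat>(W_init.get())) : mat(S);
  mat B = B_init.isNotNull() ? mat(Rcpp::as<mat>(B_init.get()))
                             : mat(p, p, fill::zeros);
  double base = avg_abs_offdiag(S);
  double thr = tol * (base > 0 ? base : 1.0);
  int it = glasso_core(S, Lambda, thr, maxit, W, B);
  mat Theta = theta_from_wb(W, B);
  return Rcpp::List::create(
      Rcpp::Named("theta") = Theta, Rcpp::Named("w") = W,
      Rcpp::Named("beta") = B, Rcpp::Named("iters") = std::abs(it),
      Rcpp::Named("converged") = it > 0);
}

// Count strictly nonzero upper-triangle entries of Theta.
static int edge_count(const mat& Theta, double eps) {
  const uword p = Theta.n_rows;
  int e = 0;
  for (uword j = 0; j < p; ++j)
    for (uword k = j + 1; k < p; ++k)
      if (std::abs(Theta(k, j)) > eps) ++e;
  return e;
}

// Fit the glasso path over a decreasing lambda grid with warm starts,
// score each fit by EBIC and return the selected precision matrix.
// When refit = true, the EBIC log-likelihood is recomputed from an
// unpenalized ML fit constrained to the selected sparsity pattern
// (implemented as a glasso solve with a prohibitive penalty on the
// zero entries and none on the active ones).
// [[Rcpp::export]]
Rcpp::List ebic_glasso_cpp(const arma::mat& S, double n,
                           const arma::vec& lambdas, double gamma,
                           bool refit, double tol, int maxit) {
  const uword p = S.n_rows;
  const uword nl = lambdas.n_elem;
  const double eps = 1e-10;
  const double big = 1e6;

  double base = avg_abs_offdiag(S);
  double thr = tol * (base > 0 ? base : 1.0);

  mat W = S, B(p, p, fill::zeros);
  mat Wr = S, Br(p, p, fill::zeros); // scratch for refits

  vec ebic_v(nl), loglik_v(nl);
  ivec edges_v(nl);
  Rcpp::LogicalVector conv_v(nl);
  double best = datum::inf;
  int best_i = -1;
  mat theta_best;

  for (uword i = 0; i < nl; ++i) {
    mat Lambda(p, p);
    Lambda.fill(lambdas(i));
    Lambda.diag().zeros(); // penalize only off-diagonal entries
    int it = glasso_core(S, Lambda, thr, maxit, W, B);
    conv_v[i] = it > 0;
    mat Theta = theta_from_wb(W, B);
    int E = edge_count(Theta, eps);
    double ll;
    if (refit) {
      // constrain to the pattern of Theta; free diagonal
      mat Lc(p, p, fill::zeros);
      for (uword j = 0; j < p; ++j)
        for (uword k = 0; k < p; ++k)
          if (k != j && std::abs(Theta(k, j)) <= eps) Lc(k, j) = big;
      Wr = W;
      Br = B;
      glasso_core(S, Lc, thr, maxit, Wr, Br);
      ll = ggm_loglik(theta_from_wb(Wr, Br), S, n);
    } else {
      ll = ggm_loglik(Theta, S, n);
    }
    double score = -2.0 * ll + E * std::log(n) +
                   4.0 * gamma * E * std::log((double)p);
    loglik_v(i) = ll;
    ebic_v(i) = score;
    edges_v(i) = E;
    // strict < keeps the earlier (larger-lambda, sparser) fit on ties
    if (score < best) {
      best = score;
      best_i = (int)i;
      theta_best = Theta;
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("theta") = theta_best,
      Rcpp::Named("lambda_index") = best_i + 1,
      Rcpp::Named("lambda") = lambdas(best_i),
      Rcpp::Named("ebic") = ebic_v, Rcpp::Named("loglik") = loglik_v,
      Rcpp::Named("edges") = edges_v, Rcpp::Named("converged") = conv_v);
}
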