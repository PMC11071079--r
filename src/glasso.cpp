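// Graphical lasso by block coordinate descent (Friedman-style), with an
// L1 penalty on off-diagonal precision entries only. Solves, for each
// penalty value, max_K  log det K - tr(SK) - lambda * sum_{i != j} |k_ij|.
// Warm starts are carried along a decreasing lambda path.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double soft_threshold(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// Lasso sub-problem for one column: min_b 1/2 b'W11 b - s12'b + lambda|b|_1
static void lasso_cd(const mat& W11, const vec& s12, vec& beta,
                     double lambda, double tol, int maxit) {
  const uword q = s12.n_elem;
  for (int it = 0; it < maxit; ++it) {
    double dmax = 0.0;
    for (uword k = 0; k < q; ++k) {
      double r = s12(k);
      for (uword l = 0; l < q; ++l)
        if (l != k) r -= W11(k, l) * beta(l);
      double bnew = soft_threshold(r, lambda) / W11(k, k);
      double d = std::fabs(bnew - beta(k));
      if (d > dmax) dmax = d;
      beta(k) = bnew;
    }
    if (dmax < tol) break;
  }
}

// [[Rcpp::export(name = ".glasso_path_cpp")]]
Rcpp::List glasso_path_cpp(const arma::mat& S, const arma::vec& lambdas,
                           double tol = 1e-6, int maxit = 10000) {
  const uword p = S.n_rows;
  const uword nlam = lambdas.n_elem;

  mat W = S;                 // working covariance; diagonal is never penalized
  mat Beta(p, p, fill::zeros);
  uvec all = regspace<uvec>(0, p - 1);

  Rcpp::List Ks(nlam);
  Rcpp::IntegerVector n_edges(nlam);
  Rcpp::LogicalVector converged(nlam);
  Rcpp::NumericVector gaps(nlam);

  // scale for the convergence test, as in the reference algorithm
  double offsum = 0.0;
  for (uword i = 0; i < p; ++i)
    for (uword j = 0; j < p; ++j)
      if (i != j) offsum += std::fabs(S(i, j));
  double thr = tol * (offsum > 0 ? offsum / (p * (p - 1)) : 1.0);

  for (uword m = 0; m < nlam; ++m) {
    double lambda = lambdas(m);
    bool conv = false;
    for (int sweep = 0; sweep < maxit; ++sweep) {
      double dmax = 0.0;
      for (uword j = 0; j < p; ++j) {
        uvec idx = find(all != j);
        mat W11 = W.submat(idx, idx);
        vec s12 = S.col(j);
        s12 = s12.elem(idx);
        vec beta = Beta.col(j);
        beta = beta.elem(idx);
        lasso_cd(W11, s12, beta, lambda, tol * 0.1, maxit);
        vec w12 = W11 * beta;
        for (uword k = 0; k < idx.n_elem; ++k) {
          double d = std::fabs(W(idx(k), j) - w12(k));
          if (d > dmax) dmax = d;
          W(idx(k), j) = w12(k);
          W(j, idx(k)) = w12(k);
          Beta(idx(k), j) = beta(k);
        }
      }
      if (dmax < thr) { conv = true; break; }
    }

    // recover the precision matrix from W and the regression coefficients
    mat K(p, p, fill::zeros);
    for (uword j = 0; j < p; ++j) {
      uvec idx = find(all != j);
      vec beta = Beta.col(j);
      beta = beta.elem(idx);
      vec w12 = W.col(j);
      w12 = w12.elem(idx);
      double kjj = 1.0 / (W(j, j) - dot(w12, beta));
      K(j, j) = kjj;
      for (uword k = 0; k < idx.n_elem; ++k)
        K(idx(k), j) = -beta(k) * kjj;
    }
    // symmetrize, preserving exact zeros from the soft threshold
    int E = 0;
    for (uword i = 0; i < p; ++i) {
      for (uword j = i + 1; j < p; ++j) {
        if (Beta(i, j) == 0.0 && Beta(j, i) == 0.0) {
          K(i, j) = 0.0; K(j, i) = 0.0;
        } else {
          double v = 0.5 * (K(i, j) + K(j, i));
          K(i, j) = v; K(j, i) = v;
          ++E;
        }
      }
    }

    // duality gap estimate: tr(SK) - p + lambda * ||K||_1,off
    double l1off = 0.0;
    for (uword i = 0; i < p; ++i)
      for (uword j = 0; j < p; ++j)
        if (i != j) l1off += std::fabs(K(i, j));
    double gap = trace(S * K) - (double)p + lambda * l1off;

    Ks[m] = Rcpp::wrap(K);
    n_edges[m] = E;
    converged[m] = conv;
    gaps[m] = gap;
  }

  return Rcpp::List::create(Rcpp::Named("precision") = Ks,
                            Rcpp::Named("n_edges") = n_edges,
                            Rcpp::Named("converged") = converged,
                            Rcpp::Named("gap") = gaps);
}
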