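// Group-lasso penalized logistic regression along a penalty sequence.
//
// Minimizes (1/n) * sum_i [ log(1 + exp(eta_i)) - y_i * eta_i ]
//           + lambda * sum_g w_g * ||beta_g||_2,
// eta = b0 + X beta, intercept unpenalized. Solved by FISTA (accelerated
// proximal gradient) with backtracking line search and gradient-based
// momentum restart; warm starts across the lambda sequence. Convergence is
// declared on the KKT residual of the penalized stationarity conditions,
// the same quantity the R-level audit recomputes independently.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double smooth_loss(const vec& eta, const vec& y, double n) {
  double s = 0.0;
  for (uword i = 0; i < eta.n_elem; ++i) {
    double e = eta[i];
    double l = (e > 30.0) ? e : std::log1p(std::exp(e));
    s += l - y[i] * e;
  }
  return s / n;
}

static vec sigmoid(const vec& eta) {
  return 1.0 / (1.0 + exp(-eta));
}

// group soft-threshold: z per group scaled toward zero by t*lambda*w_g
static void group_prox(vec& b, const uvec& grp, const vec& thr,
                       unsigned G) {
  vec nrm(G, fill::zeros);
  for (uword j = 0; j < b.n_elem; ++j) nrm[grp[j]] += b[j] * b[j];
  nrm = sqrt(nrm);
  vec scale(G);
  for (unsigned g = 0; g < G; ++g) {
    scale[g] = (nrm[g] > thr[g]) ? (1.0 - thr[g] / nrm[g]) : 0.0;
  }
  for (uword j = 0; j < b.n_elem; ++j) b[j] *= scale[grp[j]];
}

// KKT residual: max over groups of stationarity violation, plus intercept
static double kkt_residual(const mat& X, const vec& y, const vec& beta,
                           double b0, const uvec& grp, const vec& w,
                           double lambda, unsigned G) {
  double n = (double)X.n_rows;
  vec eta = b0 + X * beta;
  vec r = (sigmoid(eta) - y) / n;
  vec grad = X.t() * r;
  double viol = std::abs(accu(r));  // intercept stationarity
  for (unsigned g = 0; g < G; ++g) {
    uvec idx = find(grp == g);
    vec gg = grad.elem(idx);
    vec bg = beta.elem(idx);
    double bn = norm(bg, 2);
    if (bn > 0) {
      viol = std::max(viol, norm(gg + lambda * w[g] * bg / bn, 2));
    } else {
      viol = std::max(viol, std::max(0.0, norm(gg, 2) - lambda * w[g]));
    }
  }
  return viol;
}

// [[Rcpp::export]]
Rcpp::List grplasso_path_cpp(const arma::mat& X, const arma::vec& y,
                             const arma::uvec& grp, const arma::vec& w,
                             const arma::vec& lambda,
                             arma::vec beta, double b0,
                             double tol, int maxit) {
  const double n = (double)X.n_rows;
  const unsigned p = X.n_cols, G = w.n_elem, L = lambda.n_elem;
  mat beta_out(p, L);
  vec b0_out(L), kkt_out(L);
  ivec iters(L);

  double step = 1.0;  // inverse Lipschitz estimate, adapted by backtracking

  for (unsigned l = 0; l < L; ++l) {
    double lam = lambda[l];
    vec bz = beta;              // momentum point (coefficients)
    double bz0 = b0;
    double t_mom = 1.0;
    vec beta_prev = beta;
    double b0_prev = b0;
    double kkt = datum::inf;
    int it = 0;

    for (it = 0; it < maxit; ++it) {
      vec eta = bz0 + X * bz;
      vec r = (sigmoid(eta) - y) / n;
      vec grad = X.t() * r;
      double grad0 = accu(r);
      double f_z = smooth_loss(eta, y, n);

      // backtracking from the current step estimate
      step *= 1.1;
      vec bn; double bn0;
      for (;;) {
        bn = bz - step * grad;
        bn0 = bz0 - step * grad0;
        vec thr = step * lam * w;
        group_prox(bn, grp, thr, G);
        vec diff = bn - bz;
        double d0 = bn0 - bz0;
        double quad = f_z + dot(grad, diff) + grad0 * d0 +
          (dot(diff, diff) + d0 * d0) / (2.0 * step);
        double f_new = smooth_loss(bn0 + X * bn, y, n);
        if (f_new <= quad + 1e-12 * std::abs(quad) + 1e-300) break;
        step *= 0.5;
        if (step < 1e-14) break;
      }

      // gradient-based restart of the momentum sequence
      if (dot(bz - bn, bn - beta_prev) + (bz0 - bn0) * (bn0 - b0_prev) > 0) {
        t_mom = 1.0;
        bz = bn; bz0 = bn0;
        beta_prev = bn; b0_prev = bn0;
      } else {
        double t_next = 0.5 * (1.0 + std::sqrt(1.0 + 4.0 * t_mom * t_mom));
        double mom = (t_mom - 1.0) / t_next;
        bz = bn + mom * (bn - beta_prev);
        bz0 = bn0 + mom * (bn0 - b0_prev);
        t_mom = t_next;
        beta_prev = bn; b0_prev = bn0;
      }

      if (it % 5 == 4 || it == maxit - 1) {
        kkt = kkt_residual(X, y, beta_prev, b0_prev, grp, w, lam, G);
        if (kkt < tol) break;
      }
    }
    beta = beta_prev; b0 = b0_prev;
    if (!std::isfinite(kkt) || kkt >= tol) {
      kkt = kkt_residual(X, y, beta, b0, grp, w, lam, G);
    }
    beta_out.col(l) = beta;
    b0_out[l] = b0;
    kkt_out[l] = kkt;
    iters[l] = it + 1;
  }

  return Rcpp::List::create(
    Rcpp::Named("beta") = beta_out,
    Rcpp::Named("intercept") = b0_out,
    Rcpp::Named("kkt") = kkt_out,
    Rcpp::Named("iters") = iters);
}
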