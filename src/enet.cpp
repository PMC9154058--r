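// Elastic-net penalized logistic and multinomial regression by accelerated
// proximal gradient descent (FISTA with function-value restart). The L1 part
// of the penalty is handled by soft-thresholding, so coefficients reach
// exact zeros; the intercept(s) are never penalized.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

static inline double softplus(double m) {
  // log(1 + exp(m)) without overflow
  return (m > 0.0) ? m + std::log1p(std::exp(-m)) : std::log1p(std::exp(m));
}

// full objective: mean logistic loss + lambda*((1-a)/2 ||w||^2 + a ||w||_1)
static double objective_binary(const mat& X, const vec& y, const vec& w,
                               double b, double lambda, double l1) {
  vec m = b + X * w;
  double loss = 0.0;
  for (uword i = 0; i < m.n_elem; ++i) loss += softplus(m[i]) - y[i] * m[i];
  loss /= (double)m.n_elem;
  double pen = lambda * ((1.0 - l1) * 0.5 * dot(w, w) + l1 * norm(w, 1));
  return loss + pen;
}

// [[Rcpp::export]]
Rcpp::List enet_logistic_fista(const arma::mat& X, const arma::vec& y,
                               double lambda, double l1_ratio,
                               arma::vec w, double b,
                               double lip, double tol, int max_iter) {
  const double n = (double)X.n_rows;
  const double step = 1.0 / lip;
  const double thr = step * lambda * l1_ratio;
  const double ridge = lambda * (1.0 - l1_ratio);

  vec wz = w; double bz = b;        // momentum point
  double t = 1.0;
  double obj = objective_binary(X, y, w, b, lambda, l1_ratio);
  double obj_prev = obj;
  int it = 0;
  bool converged = false;

  for (it = 1; it <= max_iter; ++it) {
    vec m = bz + X * wz;
    vec p(m.n_elem);
    for (uword i = 0; i < m.n_elem; ++i) p[i] = 1.0 / (1.0 + std::exp(-m[i]));
    vec r = (p - y) / n;
    vec gw = X.t() * r + ridge * wz;
    double gb = accu(r);

    vec w_new = wz - step * gw;
    for (uword j = 0; j < w_new.n_elem; ++j) w_new[j] = soft(w_new[j], thr);
    double b_new = bz - step * gb;

    double obj_new = objective_binary(X, y, w_new, b_new, lambda, l1_ratio);
    if (obj_new > obj) {
      // restart momentum from the last accepted iterate
      wz = w; bz = b; t = 1.0;
      m = bz + X * wz;
      for (uword i = 0; i < m.n_elem; ++i) p[i] = 1.0 / (1.0 + std::exp(-m[i]));
      r = (p - y) / n;
      gw = X.t() * r + ridge * wz;
      gb = accu(r);
      w_new = wz - step * gw;
      for (uword j = 0; j < w_new.n_elem; ++j) w_new[j] = soft(w_new[j], thr);
      b_new = bz - step * gb;
      obj_new = objective_binary(X, y, w_new, b_new, lambda, l1_ratio);
    }

    double t_new = 0.5 * (1.0 + std::sqrt(1.0 + 4.0 * t * t));
    double mom = (t - 1.0) / t_new;
    wz = w_new + mom * (w_new - w);
    bz = b_new + mom * (b_new - b);
    t = t_new;
    w = w_new; b = b_new;
    obj_prev = obj; obj = obj_new;

    if (std::abs(obj_prev - obj) <= tol * std::max(1.0, std::abs(obj))) {
      converged = true;
      break;
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("w") = w, Rcpp::Named("b") = b,
    Rcpp::Named("objective") = obj, Rcpp::Named("iterations") = it,
    Rcpp::Named("converged") = converged);
}

// softmax rows of M in place, returns per-row log-sum-exp for the loss
static mat softmax_rows(const mat& M) {
  mat P = M;
  for (uword i = 0; i < P.n_rows; ++i) {
    double mx = P.row(i).max();
    P.row(i) = exp(P.row(i) - mx);
    P.row(i) /= accu(P.row(i));
  }
  return P;
}

static double objective_multinom(const mat& X, const uvec& yidx, const mat& W,
                                 const rowvec& b, double lambda, double l1) {
  const double n = (double)X.n_rows;
  mat M = X * W;
  M.each_row() += b;
  double loss = 0.0;
  for (uword i = 0; i < M.n_rows; ++i) {
    double mx = M.row(i).max();
    double lse = mx + std::log(accu(exp(M.row(i) - mx)));
    loss += lse - M(i, yidx[i]);
  }
  loss /= n;
  double pen = lambda * ((1.0 - l1) * 0.5 * accu(W % W) +
                         l1 * accu(abs(W)));
  return loss + pen;
}

// [[Rcpp::export]]
Rcpp::List enet_multinomial_fista(const arma::mat& X, const arma::uvec& yidx,
                                  int n_class, double lambda, double l1_ratio,
                                  arma::mat W, arma::rowvec b,
                                  double lip, double tol, int max_iter) {
  const double n = (double)X.n_rows;
  const double step = 1.0 / lip;
  const double thr = step * lambda * l1_ratio;
  const double ridge = lambda * (1.0 - l1_ratio);

  mat Y(X.n_rows, n_class, fill::zeros);
  for (uword i = 0; i < yidx.n_elem; ++i) Y(i, yidx[i]) = 1.0;

  mat Wz = W; rowvec bz = b;
  double t = 1.0;
  double obj = objective_multinom(X, yidx, W, b, lambda, l1_ratio);
  double obj_prev = obj;
  int it = 0;
  bool converged = false;

  auto prox_step = [&](const mat& Wp, const rowvec& bp, mat& W_new,
                       rowvec& b_new) {
    mat M = X * Wp;
    M.each_row() += bp;
    mat P = softmax_rows(M);
    mat R = (P - Y) / n;
    mat GW = X.t() * R + ridge * Wp;
    rowvec gb = sum(R, 0);
    W_new = Wp - step * GW;
    for (uword j = 0; j < W_new.n_elem; ++j) W_new[j] = soft(W_new[j], thr);
    b_new = bp - step * gb;
  };

  for (it = 1; it <= max_iter; ++it) {
    mat W_new; rowvec b_new;
    prox_step(Wz, bz, W_new, b_new);
    double obj_new = objective_multinom(X, yidx, W_new, b_new, lambda, l1_ratio);
    if (obj_new > obj) {
      Wz = W; bz = b; t = 1.0;
      prox_step(Wz, bz, W_new, b_new);
      obj_new = objective_multinom(X, yidx, W_new, b_new, lambda, l1_ratio);
    }
    double t_new = 0.5 * (1.0 + std::sqrt(1.0 + 4.0 * t * t));
    double mom = (t - 1.0) / t_new;
    Wz = W_new + mom * (W_new - W);
    bz = b_new + mom * (b_new - b);
    t = t_new;
    W = W_new; b = b_new;
    obj_prev = obj; obj = obj_new;
    if (std::abs(obj_prev - obj) <= tol * std::max(1.0, std::abs(obj))) {
      converged = true;
      break;
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("W") = W, Rcpp::Named("b") = b,
    Rcpp::Named("objective") = obj, Rcpp::Named("iterations") = it,
    Rcpp::Named("converged") = converged);
}

// squared spectral norm of [1 | X] by power iteration, for the Lipschitz
// constant of the logistic/softmax gradient
// [[Rcpp::export]]
double aug_spectral_norm_sq(const arma::mat& X, int iters) {
  vec v(X.n_cols + 1, fill::ones);
  v /= norm(v);
  double lam = 1.0;
  for (int k = 0; k < iters; ++k) {
    // u = A v with A = [1 X]
    vec u = v[0] + X * v.subvec(1, X.n_cols);
    // v' = A^T u
    vec v2(X.n_cols + 1);
    v2[0] = accu(u);
    v2.subvec(1, X.n_cols) = X.t() * u;
    lam = norm(v2);
    if (lam <= 0) return 0.0;
    v = v2 / lam;
  }
  return lam;  // ||A^T A v|| -> largest eigenvalue of A^T A = smax^2
}
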