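#include <RcppArmadillo.h>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double LOG2PI = 1.8378770664093454836;

// Pairwise Euclidean distances between rows of coords.
// [[Rcpp::export]]
arma::mat dist_matrix_cpp(const arma::mat& coords) {
  const uword n = coords.n_rows;
  mat D(n, n, fill::zeros);
  for (uword i = 0; i < n; ++i) {
    for (uword j = i + 1; j < n; ++j) {
      double d = norm(coords.row(i) - coords.row(j), 2);
      D(i, j) = d;
      D(j, i) = d;
    }
  }
  return D;
}

// Exponential covariance sigma2 * exp(-D / l) evaluated on a distance matrix.
// [[Rcpp::export]]
arma::mat exp_kernel_cpp(const arma::mat& D, double sigma2, double l) {
  return sigma2 * exp(-D / l);
}

static Rcpp::List fail_result(uword p) {
  return Rcpp::List::create(Rcpp::Named("loglik") = R_NegInf,
                            Rcpp::Named("beta") = vec(p, fill::zeros),
                            Rcpp::Named("logdet") = R_NegInf,
                            Rcpp::Named("rss") = R_PosInf);
}

// Profile Gaussian log-likelihood of y ~ N(X beta, sigma2*exp(-D/l) + tau2*I),
// beta profiled out by generalized least squares (dense Cholesky). Also
// returns the covariance log-determinant and the whitened residual sum of
// squares so callers can profile out an overall variance scale.
// [[Rcpp::export]]
Rcpp::List gp_loglik_exact_cpp(const arma::vec& y, const arma::mat& X,
                               const arma::mat& D, double sigma2,
                               double tau2, double l) {
  const uword n = y.n_elem;
  mat Sigma = sigma2 * exp(-D / l);
  Sigma.diag() += tau2;
  mat L;
  if (!chol(L, Sigma, "lower")) return fail_result(X.n_cols);
  vec yt = solve(trimatl(L), y);
  mat Xt = solve(trimatl(L), X);
  vec beta;
  if (!solve(beta, Xt.t() * Xt, Xt.t() * yt)) return fail_result(X.n_cols);
  vec e = yt - Xt * beta;
  double logdet = 2.0 * sum(log(L.diag()));
  double rss = dot(e, e);
  double ll = -0.5 * (n * LOG2PI + logdet + rss);
  return Rcpp::List::create(Rcpp::Named("loglik") = ll,
                            Rcpp::Named("beta") = beta,
                            Rcpp::Named("logdet") = logdet,
                            Rcpp::Named("rss") = rss);
}

// Precompute the distances a Vecchia factorization needs for repeated
// likelihood evaluations: dn(i, r) = distance from ordered point i to its
// r-th conditioning neighbor, dnn(.,.,i) = distances among the neighbors.
// nn_idx is 1-based into the ordered points; nn_count gives the number of
// neighbors actually used per point.
// [[Rcpp::export]]
Rcpp::List vecchia_dists_cpp(const arma::mat& coords,
                             const arma::imat& nn_idx,
                             const arma::ivec& nn_count) {
  const uword n = coords.n_rows;
  const uword m = nn_idx.n_cols;
  mat dn(n, m, fill::zeros);
  cube dnn(m, m, n, fill::zeros);
  for (uword i = 0; i < n; ++i) {
    const int k = nn_count(i);
    for (int r = 0; r < k; ++r) {
      const uword jr = nn_idx(i, r) - 1;
      dn(i, r) = norm(coords.row(i) - coords.row(jr), 2);
      for (int c = r + 1; c < k; ++c) {
        const uword jc = nn_idx(i, c) - 1;
        double d = norm(coords.row(jr) - coords.row(jc), 2);
        dnn(r, c, i) = d;
        dnn(c, r, i) = d;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dn") = dn, Rcpp::Named("dnn") = dnn);
}

// In-place lower Cholesky of a k x k matrix stored column-major in a raw
// buffer; returns false if not positive definite.
static bool chol_inplace(double* A, int k) {
  for (int j = 0; j < k; ++j) {
    double d = A[j + j * k];
    for (int r = 0; r < j; ++r) d -= A[j + r * k] * A[j + r * k];
    if (d <= 0.0) return false;
    d = std::sqrt(d);
    A[j + j * k] = d;
    for (int i = j + 1; i < k; ++i) {
      double s = A[i + j * k];
      for (int r = 0; r < j; ++r) s -= A[i + r * k] * A[j + r * k];
      A[i + j * k] = s / d;
    }
  }
  return true;
}

// Vecchia (nearest-neighbor GP) profile log-likelihood. y, X, and the
// neighbor structures must all be in the same (pre-applied) ordering.
// Distances enter as integer codes into dvals, the vector of distinct
// neighbor distances (few on a regular grid), so each evaluation
// exponentiates only the distinct values. Allocation-free inner loop:
// this is the hot path of per-gene fitting.
// [[Rcpp::export]]
Rcpp::List gp_loglik_nn_cpp(const arma::vec& y, const arma::mat& X,
                            const arma::vec& dvals,
                            const Rcpp::IntegerMatrix& cn_code,
                            const Rcpp::IntegerVector& cnn_code,
                            const arma::imat& nn_idx, const arma::ivec& nn_count,
                            double sigma2, double tau2, double l) {
  const uword n = y.n_elem;
  const uword p = X.n_cols;
  const uword m = nn_idx.n_cols;
  vec yt(n);
  mat Xt(n, p);
  std::vector<double> Cbuf(m * m), cn(m), a(m);
  const double inv_l = 1.0 / l;
  std::vector<double> expv(dvals.n_elem);
  for (uword u = 0; u < dvals.n_elem; ++u)
    expv[u] = sigma2 * std::exp(-dvals(u) * inv_l);
  const int* cnn = cnn_code.begin();
  const uword mm = m * m;
  double logdetsum = 0.0;
  for (uword i = 0; i < n; ++i) {
    const int k = nn_count(i);
    double di;
    if (k == 0) {
      di = sigma2 + tau2;
      if (di <= 0.0) return fail_result(p);
      const double sdi = std::sqrt(di);
      yt(i) = y(i) / sdi;
      for (uword c = 0; c < p; ++c) Xt(i, c) = X(i, c) / sdi;
    } else {
      // C = sigma2 * exp(-dnn / l) + tau2 I, cn = sigma2 * exp(-dn / l)
      const int* cnn_i = cnn + i * mm;
      for (int r = 0; r < k; ++r) {
        cn[r] = expv[cn_code(i, r)];
        Cbuf[r + r * k] = sigma2 + tau2;
        for (int c = r + 1; c < k; ++c) {
          Cbuf[c + r * k] = expv[cnn_i[r + c * m]];
        }
      }
      if (!chol_inplace(Cbuf.data(), k)) return fail_result(p);
      // a1 = L^{-1} cn (forward solve), di = sigma2 + tau2 - ||a1||^2
      double qf = 0.0;
      for (int r = 0; r < k; ++r) {
        double s = cn[r];
        for (int c = 0; c < r; ++c) s -= Cbuf[r + c * k] * a[c];
        a[r] = s / Cbuf[r + r * k];
        qf += a[r] * a[r];
      }
      di = sigma2 + tau2 - qf;
      if (di <= 0.0) return fail_result(p);
      // a <- L^{-T} a1 = C^{-1} cn (back solve)
      for (int r = k - 1; r >= 0; --r) {
        double s = a[r];
        for (int c = r + 1; c < k; ++c) s -= Cbuf[c + r * k] * a[c];
        a[r] = s / Cbuf[r + r * k];
      }
      double ym = 0.0;
      const double sdi = std::sqrt(di);
      for (uword c = 0; c < p; ++c) Xt(i, c) = X(i, c);
      for (int r = 0; r < k; ++r) {
        const uword j = nn_idx(i, r) - 1;
        ym += a[r] * y(j);
        for (uword c = 0; c < p; ++c) Xt(i, c) -= a[r] * X(j, c);
      }
      yt(i) = (y(i) - ym) / sdi;
      for (uword c = 0; c < p; ++c) Xt(i, c) /= sdi;
    }
    logdetsum += std::log(di);
  }
  vec beta;
  if (!solve(beta, Xt.t() * Xt, Xt.t() * yt)) return fail_result(p);
  vec e = yt - Xt * beta;
  double rss = dot(e, e);
  double ll = -0.5 * (n * LOG2PI + logdetsum + rss);
  return Rcpp::List::create(Rcpp::Named("loglik") = ll,
                            Rcpp::Named("beta") = beta,
                            Rcpp::Named("logdet") = logdetsum,
                            Rcpp::Named("rss") = rss);
}
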