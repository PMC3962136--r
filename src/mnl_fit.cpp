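#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Multinomial-logit log-likelihood for design X (n x d, intercept included),
// outcome y in 0..K-1 with baseline class K-1, coefficients B (d x (K-1)).
static double mnl_loglik(const mat& X, const ivec& y, const mat& B) {
  const uword n = X.n_rows, m = B.n_cols;
  mat eta = X * B;                       // n x m
  double ll = 0.0;
  for (uword i = 0; i < n; ++i) {
    double mx = 0.0;
    for (uword k = 0; k < m; ++k) mx = std::max(mx, eta(i, k));
    double s = std::exp(-mx);            // baseline term exp(0 - mx)
    for (uword k = 0; k < m; ++k) s += std::exp(eta(i, k) - mx);
    double lse = mx + std::log(s);
    double e = (y[i] < (int)m) ? eta(i, (uword)y[i]) : 0.0;
    ll += e - lse;
  }
  return ll;
}

// Class probabilities for non-baseline classes, n x m (baseline = 1 - rowsum).
static mat mnl_probs(const mat& X, const mat& B) {
  const uword n = X.n_rows, m = B.n_cols;
  mat eta = X * B;
  mat P(n, m);
  for (uword i = 0; i < n; ++i) {
    double mx = 0.0;
    for (uword k = 0; k < m; ++k) mx = std::max(mx, eta(i, k));
    double s = std::exp(-mx);
    for (uword k = 0; k < m; ++k) {
      P(i, k) = std::exp(eta(i, k) - mx);
      s += P(i, k);
    }
    for (uword k = 0; k < m; ++k) P(i, k) /= s;
  }
  return P;
}

// Newton-Raphson MLE with step halving and a box cap on |coefficients|.
// Convergence: relative log-lik change < tol, or max |gradient| < gtol.
// [[Rcpp::export]]
Rcpp::List cpp_fit_mnl(const arma::mat& X, const arma::ivec& y, int K,
                       int maxit = 200, double tol = 1e-8,
                       double gtol = 1e-6, double cap = 30.0) {
  const uword n = X.n_rows, d = X.n_cols;
  const uword m = (uword)(K - 1);
  mat B(d, m, fill::zeros);
  mat Yind(n, m, fill::zeros);
  for (uword i = 0; i < n; ++i)
    if (y[i] < (int)m) Yind(i, (uword)y[i]) = 1.0;

  double ll = mnl_loglik(X, y, B);
  bool converged = false;
  int it = 0;
  for (it = 0; it < maxit; ++it) {
    mat P = mnl_probs(X, B);
    mat R = Yind - P;                    // n x m residuals
    vec g(d * m);
    for (uword k = 0; k < m; ++k)
      g.subvec(k * d, k * d + d - 1) = X.t() * R.col(k);
    if (abs(g).max() < gtol) { converged = true; break; }

    mat H(d * m, d * m);
    for (uword a = 0; a < m; ++a) {
      for (uword b = a; b < m; ++b) {
        vec w;
        if (a == b) w = P.col(a) % (1.0 - P.col(a));
        else w = -(P.col(a) % P.col(b));
        mat blk = X.t() * (X.each_col() % w);
        H.submat(a * d, b * d, a * d + d - 1, b * d + d - 1) = blk;
        if (a != b)
          H.submat(b * d, a * d, b * d + d - 1, a * d + d - 1) = blk.t();
      }
    }

    vec step;
    bool ok = solve(step, H, g, solve_opts::likely_sympd + solve_opts::no_approx);
    if (!ok || !step.is_finite()) {
      mat Hr = H + 1e-8 * trace(H) / (double)(d * m) * eye(d * m, d * m);
      if (!solve(step, Hr, g) || !step.is_finite()) break;
    }

    // step halving with projection onto the coefficient box
    double t = 1.0, llnew = -datum::inf;
    mat Bnew;
    for (int h = 0; h < 30; ++h) {
      Bnew = B + t * reshape(step, d, m);
      Bnew = clamp(Bnew, -cap, cap);
      llnew = mnl_loglik(X, y, Bnew);
      if (llnew >= ll - 1e-12) break;
      t *= 0.5;
    }
    double rel = std::fabs(llnew - ll) / (std::fabs(ll) + 1.0);
    B = Bnew;
    if (llnew >= ll && rel < tol) { ll = llnew; converged = true; break; }
    ll = llnew;
  }

  return Rcpp::List::create(
      Rcpp::Named("coefficients") = B,
      Rcpp::Named("loglik") = ll,
      Rcpp::Named("converged") = converged,
      Rcpp::Named("iterations") = it + 1);
}

// [[Rcpp::export]]
double cpp_mnl_loglik(const arma::mat& X, const arma::ivec& y,
                      const arma::mat& B) {
  return mnl_loglik(X, y, B);
}

// Hot path for the MMPC loop: builds the design [1, FM[, idx]] internally
// from 0-based column indices and optionally warm-starts from the nested
// model's coefficients (zero rows appended for the extra regressors).
// [[Rcpp::export]]
Rcpp::List cpp_fit_mnl_idx(const arma::mat& FM, const arma::ivec& y, int K,
                           const arma::uvec& idx,
                           Rcpp::Nullable<Rcpp::NumericMatrix> warm =
                               R_NilValue,
                           int maxit = 200, double tol = 1e-8,
                           double gtol = 1e-6, double cap = 30.0) {
  const uword n = FM.n_rows, q = idx.n_elem;
  mat X(n, q + 1);
  X.col(0).ones();
  for (uword j = 0; j < q; ++j) X.col(j + 1) = FM.col(idx[j]);

  const uword m = (uword)(K - 1);
  mat B(q + 1, m, fill::zeros);
  if (warm.isNotNull()) {
    Rcpp::NumericMatrix w(warm);
    uword r = std::min((uword)w.nrow(), q + 1);
    for (uword j = 0; j < (uword)w.ncol() && j < m; ++j)
      for (uword i = 0; i < r; ++i) B(i, j) = w(i, j);
  }

  mat Yind(n, m, fill::zeros);
  for (uword i = 0; i < n; ++i)
    if (y[i] < (int)m) Yind(i, (uword)y[i]) = 1.0;
  const uword d = q + 1;

  // single-pass evaluation of the log-likelihood and class probabilities
  mat P(n, m);
  auto evalBoth = [&](const mat& Bc) -> double {
    mat eta = X * Bc;
    double llv = 0.0;
    for (uword i = 0; i < n; ++i) {
      double mx = 0.0;
      for (uword k = 0; k < m; ++k) mx = std::max(mx, eta(i, k));
      double s = std::exp(-mx);
      for (uword k = 0; k < m; ++k) {
        P(i, k) = std::exp(eta(i, k) - mx);
        s += P(i, k);
      }
      for (uword k = 0; k < m; ++k) P(i, k) /= s;
      double e = (y[i] < (int)m) ? eta(i, (uword)y[i]) : 0.0;
      llv += e - (mx + std::log(s));
    }
    return llv;
  };

  double ll = evalBoth(B);
  bool converged = false;
  int it = 0;
  for (it = 0; it < maxit; ++it) {
    mat R = Yind - P;
    vec g(d * m);
    for (uword k = 0; k < m; ++k)
      g.subvec(k * d, k * d + d - 1) = X.t() * R.col(k);
    if (abs(g).max() < gtol) { converged = true; break; }

    mat H(d * m, d * m);
    for (uword a = 0; a < m; ++a) {
      for (uword b = a; b < m; ++b) {
        vec w;
        if (a == b) w = P.col(a) % (1.0 - P.col(a));
        else w = -(P.col(a) % P.col(b));
        mat blk = X.t() * (X.each_col() % w);
        H.submat(a * d, b * d, a * d + d - 1, b * d + d - 1) = blk;
        if (a != b)
          H.submat(b * d, a * d, b * d + d - 1, a * d + d - 1) = blk.t();
      }
    }
    vec step;
    bool ok = solve(step, H, g,
                    solve_opts::likely_sympd + solve_opts::no_approx);
    if (!ok || !step.is_finite()) {
      mat Hr = H + (1e-8 * trace(H) / (double)(d * m) + 1e-10) *
                       eye(d * m, d * m);
      if (!solve(step, Hr, g) || !step.is_finite()) break;
    }
    double t = 1.0, llnew = -datum::inf;
    mat Bnew;
    for (int h = 0; h < 30; ++h) {
      Bnew = B + t * reshape(step, d, m);
      Bnew = clamp(Bnew, -cap, cap);
      llnew = evalBoth(Bnew);
      if (llnew >= ll - 1e-12) break;
      t *= 0.5;
    }
    double rel = std::fabs(llnew - ll) / (std::fabs(ll) + 1.0);
    B = Bnew;
    if (llnew >= ll && rel < tol) { ll = llnew; converged = true; break; }
    ll = llnew;
  }
  return Rcpp::List::create(Rcpp::Named("coefficients") = B,
                            Rcpp::Named("loglik") = ll,
                            Rcpp::Named("converged") = converged,
                            Rcpp::Named("iterations") = it + 1);
}
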