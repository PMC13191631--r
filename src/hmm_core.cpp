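// Numerical core for the Gaussian HMM: emission log-densities, scaled
// forward-backward, Viterbi decoding and a full Baum-Welch driver.
// Observation matrices are T x D (rows = time points).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double LOG2PI = 1.8378770664093454836;

// Cholesky factors of K covariance matrices; throws if not SPD.
static std::vector<mat> chol_factors(const cube& covs) {
  std::vector<mat> Ls(covs.n_slices);
  for (uword k = 0; k < covs.n_slices; ++k) {
    mat L;
    if (!chol(L, covs.slice(k), "lower"))
      Rcpp::stop("covariance matrix for state %d is not positive definite", (int)k + 1);
    Ls[k] = L;
  }
  return Ls;
}

// T x K matrix of log N(x_t | mu_k, Sigma_k).
// [[Rcpp::export]]
arma::mat cpp_log_emissions(const arma::mat& X, const arma::mat& means,
                            const arma::cube& covs) {
  const uword T = X.n_rows, D = X.n_cols, K = means.n_rows;
  std::vector<mat> Ls = chol_factors(covs);
  mat logB(T, K);
  for (uword k = 0; k < K; ++k) {
    double logdet = 2.0 * accu(log(Ls[k].diag()));
    mat Xc = X.each_row() - means.row(k);       // T x D
    // solve L * Z' = Xc'  =>  Z = Xc * inv(L)'
    mat Z = solve(trimatl(Ls[k]), Xc.t());      // D x T
    rowvec q = sum(square(Z), 0);               // Mahalanobis distances
    logB.col(k) = (-0.5 * (D * LOG2PI + logdet) - 0.5 * q.t());
  }
  return logB;
}

// Scaled forward-backward. Returns smoothed marginals gamma (T x K),
// summed two-slice counts xi_sum (K x K) and the sequence log-likelihood.
// [[Rcpp::export]]
Rcpp::List cpp_forward_backward(const arma::mat& logB, const arma::vec& log_pi,
                                const arma::mat& log_A) {
  const uword T = logB.n_rows, K = logB.n_cols;
  mat A = exp(log_A);
  // shift emissions per row for stability, work in scaled linear space
  vec shift = max(logB, 1);
  mat B = exp(logB.each_col() - shift);
  mat alpha(T, K), beta(T, K);
  vec c(T);
  double loglik = 0.0;

  rowvec a = exp(log_pi.t()) % B.row(0);
  c(0) = accu(a);
  alpha.row(0) = a / c(0);
  for (uword t = 1; t < T; ++t) {
    a = (alpha.row(t - 1) * A) % B.row(t);
    c(t) = accu(a);
    if (!(c(t) > 0)) Rcpp::stop("forward pass underflow at t=%d", (int)t + 1);
    alpha.row(t) = a / c(t);
  }
  loglik = accu(log(c)) + accu(shift);

  beta.row(T - 1).ones();
  mat xi_sum(K, K, fill::zeros);
  for (uword t = T - 1; t-- > 0; ) {
    rowvec bb = B.row(t + 1) % beta.row(t + 1);
    // two-slice joint (unnormalized in the scaled space, then normalized)
    mat xi = (A.each_col() % alpha.row(t).t());
    xi.each_row() %= bb;
    xi /= accu(xi);
    xi_sum += xi;
    beta.row(t) = (A * bb.t()).t() / c(t + 1);
  }
  mat gamma = alpha % beta;
  gamma.each_col() /= sum(gamma, 1);
  return Rcpp::List::create(Rcpp::Named("gamma") = gamma,
                            Rcpp::Named("xi_sum") = xi_sum,
                            Rcpp::Named("loglik") = loglik);
}

// Exact MAP path (1-based). Ties broken toward the lowest state index:
// strict inequality when scanning candidate predecessors in index order.
// [[Rcpp::export]]
arma::uvec cpp_viterbi(const arma::mat& logB, const arma::vec& log_pi,
                       const arma::mat& log_A) {
  const uword T = logB.n_rows, K = logB.n_cols;
  mat delta(T, K);
  umat psi(T, K, fill::zeros);
  delta.row(0) = log_pi.t() + logB.row(0);
  for (uword t = 1; t < T; ++t) {
    for (uword k = 0; k < K; ++k) {
      uword best = 0;
      double bestv = delta(t - 1, 0) + log_A(0, k);
      for (uword j = 1; j < K; ++j) {
        double v = delta(t - 1, j) + log_A(j, k);
        if (v > bestv) { bestv = v; best = j; }
      }
      delta(t, k) = bestv + logB(t, k);
      psi(t, k) = best;
    }
  }
  uvec path(T);
  path(T - 1) = delta.row(T - 1).index_max();
  // index_max returns the first (lowest) index on ties
  for (uword t = T - 1; t-- > 0; ) path(t) = psi(t + 1, path(t + 1));
  return path + 1;
}

// Baum-Welch over a list of independent sequences sharing parameters.
// Covariances regularized by diagonal loading eps * trace/D each M-step.
// Work buffers are allocated once and reused across states and iterations;
// emission log-densities use the uncentered quadratic form
// q_t = |L^-1 x_t|^2 - 2 (L^-1 x_t)'(L^-1 mu) + |L^-1 mu|^2.
// [[Rcpp::export]]
Rcpp::List cpp_baum_welch(const Rcpp::List& X_list, arma::mat means,
                          arma::cube covs, arma::mat A, arma::vec pi0,
                          int max_iter, double tol, double eps_reg) {
  const uword K = means.n_rows, D = means.n_cols;
  const int S = X_list.size();
  std::vector<mat> Xs(S), Xts(S);
  uword Ttot = 0, Tmax = 0;
  for (int s = 0; s < S; ++s) {
    Xs[s] = Rcpp::as<mat>(X_list[s]);
    Xts[s] = Xs[s].t();
    Ttot += Xs[s].n_rows;
    Tmax = std::max(Tmax, Xs[s].n_rows);
  }
  mat Zbuf(D, Tmax), Wbuf(Tmax, D), logBbuf(Tmax, K);
  std::vector<double> trace_ll;
  double prev_ll = -datum::inf;
  bool converged = false;

  for (int iter = 0; iter < max_iter; ++iter) {
    mat log_A = log(A);
    vec log_pi = log(pi0);
    std::vector<mat> Ls = chol_factors(covs);
    vec logdet(K);
    mat Lmu(D, K);
    for (uword k = 0; k < K; ++k) {
      logdet(k) = 2.0 * accu(log(Ls[k].diag()));
      Lmu.col(k) = solve(trimatl(Ls[k]), means.row(k).t());
    }
    double ll = 0.0;
    mat sum_g(K, 1, fill::zeros);
    mat sum_gx(K, D, fill::zeros);
    cube sum_gxx(D, D, K, fill::zeros);
    mat xi_tot(K, K, fill::zeros);
    vec pi_new(K, fill::zeros);

    for (int s = 0; s < S; ++s) {
      const uword T = Xs[s].n_rows;
      mat logB(logBbuf.memptr(), T, K, false, true);
      mat Z(Zbuf.memptr(), D, T, false, true);
      for (uword k = 0; k < K; ++k) {
        solve(Z, trimatl(Ls[k]), Xts[s]);
        double cc = dot(Lmu.col(k), Lmu.col(k));
        rowvec q = sum(square(Z), 0) - 2.0 * (Lmu.col(k).t() * Z);
        logB.col(k) = (-0.5 * (D * LOG2PI + logdet(k) + cc) - 0.5 * q.t());
      }
      Rcpp::List fb = cpp_forward_backward(logB, log_pi, log_A);
      mat gamma = fb["gamma"];
      mat xi = fb["xi_sum"];
      ll += Rcpp::as<double>(fb["loglik"]);
      xi_tot += xi;
      pi_new += gamma.row(0).t();
      mat Xw(Wbuf.memptr(), T, D, false, true);
      for (uword k = 0; k < K; ++k) {
        vec g = gamma.col(k);
        sum_g(k, 0) += accu(g);
        sum_gx.row(k) += g.t() * Xs[s];
        Xw = Xs[s].each_col() % sqrt(g);
        sum_gxx.slice(k) += Xw.t() * Xw;
      }
    }
    trace_ll.push_back(ll);
    if (iter > 0 && std::abs(ll - prev_ll) <=
          tol * (std::abs(prev_ll) + 1e-10)) {
      converged = true;
      prev_ll = ll;
      break;
    }
    prev_ll = ll;

    // M-step
    for (uword k = 0; k < K; ++k) {
      double Nk = sum_g(k, 0);
      rowvec mu = sum_gx.row(k) / Nk;
      mat Sg = sum_gxx.slice(k) / Nk - mu.t() * mu;
      Sg = symmatu(0.5 * (Sg + Sg.t()));
      Sg.diag() += eps_reg * arma::trace(Sg) / D;
      means.row(k) = mu;
      covs.slice(k) = Sg;
    }
    A = xi_tot.each_col() / sum(xi_tot, 1);
    pi0 = pi_new / accu(pi_new);
  }

  return Rcpp::List::create(
      Rcpp::Named("means") = means, Rcpp::Named("covs") = covs,
      Rcpp::Named("transition") = A, Rcpp::Named("initial") = pi0,
      Rcpp::Named("loglik_trace") = trace_ll,
      Rcpp::Named("loglik") = prev_ll,
      Rcpp::Named("converged") = converged,
      Rcpp::Named("n_obs") = (double)Ttot);
}
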