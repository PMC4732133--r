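// Continuous Gaussian-mixture HMM core: scaled forward log-likelihood and
// Baum-Welch (EM) re-estimation with diagonal covariances.
//
// Parameter layout shared with the R wrappers:
//   pi    : S            initial state distribution
//   A     : S x S        transition matrix (structural zeros preserved)
//   w     : S x M        mixture weights per state
//   means : D x M x S    component means   (cube)
//   vars  : D x M x S    component diagonal variances (cube)
// Sequences are T x D matrices.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double LOG2PI = std::log(2.0 * M_PI);

// log N(x | mu, diag(v)) for all frames and components of one state.
// X: T x D, mu: D x M, v: D x M  ->  T x M
static mat comp_logdens(const mat& X, const mat& mu, const mat& v) {
  const uword T = X.n_rows, D = X.n_cols, M = mu.n_cols;
  mat out(T, M);
  for (uword m = 0; m < M; ++m) {
    double cst = -0.5 * (D * LOG2PI + accu(log(v.col(m))));
    rowvec inv = 1.0 / v.col(m).t();
    vec q(T, fill::zeros);
    for (uword d = 0; d < D; ++d) {
      vec diff = X.col(d) - mu(d, m);
      q += diff % diff * inv(d);
    }
    out.col(m) = cst - 0.5 * q;
  }
  return out;
}

// per-frame log emission density of every state, plus the per-state
// per-component log densities (for mixture posteriors).
// lcomp: T x M x S cube; returns logB: T x S
static mat emission_logdens(const mat& X, const mat& w, const cube& means,
                            const cube& vars, cube& lcomp) {
  const uword T = X.n_rows, S = w.n_rows, M = w.n_cols;
  mat logB(T, S);
  lcomp.set_size(T, M, S);
  for (uword s = 0; s < S; ++s) {
    mat lc = comp_logdens(X, means.slice(s), vars.slice(s));
    lcomp.slice(s) = lc;
    rowvec lw(M);
    for (uword m = 0; m < M; ++m)
      lw(m) = w(s, m) > 0 ? std::log(w(s, m)) : -datum::inf;
    mat t = lc.each_row() + lw;
    vec mx = max(t, 1);
    mx.replace(-datum::inf, 0.0);
    logB.col(s) = mx + log(sum(exp(t.each_col() - mx), 1));
  }
  return logB;
}

// scaled forward pass; returns log-likelihood and (optionally) the scaled
// alpha matrix plus scaling info needed by the backward pass.
static double forward_scaled(const vec& pi, const mat& A, const mat& logB,
                             mat* alpha_out, vec* logc_out, vec* shift_out) {
  const uword T = logB.n_rows, S = logB.n_cols;
  mat alpha(T, S);
  vec logc(T), shift(T);
  double ll = 0.0;
  rowvec prev;
  for (uword t = 0; t < T; ++t) {
    // propagate the (normalized) mass first, then pick the scaling shift
    // from the reachable states so left-to-right dead states cannot force
    // an underflow
    rowvec p;  // state occupancy before emission, sums to 1
    if (t == 0) p = pi.t(); else p = prev * A;
    rowvec lq(S);
    for (uword s = 0; s < S; ++s)
      lq(s) = p(s) > 0 ? std::log(p(s)) + logB(t, s) : -datum::inf;
    shift(t) = lq.max();
    if (!std::isfinite(shift(t)))
      Rcpp::stop("zero-likelihood sequence in forward pass");
    rowvec a = exp(lq - shift(t));
    double norm = accu(a);
    a /= norm;
    alpha.row(t) = a;
    logc(t) = std::log(norm);
    ll += logc(t) + shift(t);
    prev = a;
  }
  if (alpha_out) *alpha_out = alpha;
  if (logc_out) *logc_out = logc;
  if (shift_out) *shift_out = shift;
  return ll;
}

// [[Rcpp::export]]
double cpp_forward_loglik(const arma::vec& pi, const arma::mat& A,
                          const arma::mat& w, const arma::cube& means,
                          const arma::cube& vars, const arma::mat& X) {
  cube lcomp;
  mat logB = emission_logdens(X, w, means, vars, lcomp);
  return forward_scaled(pi, A, logB, nullptr, nullptr, nullptr);
}

// [[Rcpp::export]]
Rcpp::List cpp_baum_welch(const Rcpp::List& Xlist, arma::vec pi, arma::mat A,
                          arma::mat w, arma::cube means, arma::cube vars,
                          int max_iter, double tol,
                          const arma::vec& var_floor) {
  const uword S = A.n_rows, M = w.n_cols, D = means.n_rows;
  const int n_seq = Xlist.size();
  std::vector<mat> seqs(n_seq);
  for (int i = 0; i < n_seq; ++i) seqs[i] = Rcpp::as<mat>(Xlist[i]);

  std::vector<double> trace;
  double prev_ll = -datum::inf;

  for (int it = 0; it < max_iter; ++it) {
    mat A_num(S, S, fill::zeros);
    vec pi_num(S, fill::zeros);
    mat G(S, M, fill::zeros);
    cube Gx(D, M, S, fill::zeros), Gx2(D, M, S, fill::zeros);
    double ll = 0.0;

    for (int i = 0; i < n_seq; ++i) {
      const mat& X = seqs[i];
      const uword T = X.n_rows;
      cube lcomp;
      mat logB = emission_logdens(X, w, means, vars, lcomp);
      mat alpha;
      vec logc, shift;
      ll += forward_scaled(pi, A, logB, &alpha, &logc, &shift);

      // scaled backward pass (Rabiner scaling: shares the forward c_t)
      mat beta(T, S);
      beta.row(T - 1).ones();
      for (uword t = T - 1; t-- > 0;) {
        rowvec b1 = exp(logB.row(t + 1) - shift(t + 1));
        vec tmp = A * (b1 % beta.row(t + 1)).t();
        beta.row(t) = tmp.t() / std::exp(logc(t + 1));
      }

      mat gamma = alpha % beta;           // rows sum to 1
      pi_num += gamma.row(0).t();

      for (uword t = 0; t + 1 < T; ++t) {
        rowvec b1 = exp(logB.row(t + 1) - shift(t + 1));
        mat xi = (alpha.row(t).t() * (b1 % beta.row(t + 1))) % A /
                 std::exp(logc(t + 1));
        A_num += xi;
      }

      // mixture responsibilities
      for (uword s = 0; s < S; ++s) {
        rowvec lw(M);
        for (uword m = 0; m < M; ++m)
          lw(m) = w(s, m) > 0 ? std::log(w(s, m)) : -datum::inf;
        mat post = lcomp.slice(s);
        post.each_row() += lw;
        post.each_col() -= logB.col(s);     // log p(m | x_t, s)
        post = exp(post);
        post.each_col() %= gamma.col(s);    // gamma_{t,s,m}
        rowvec gs = sum(post, 0);
        G.row(s) += gs;
        Gx.slice(s) += X.t() * post;                 // D x M
        Gx2.slice(s) += square(X).t() * post;
      }
    }

    trace.push_back(ll);
    if (it > 0 && ll - prev_ll < tol * (std::abs(prev_ll) + 1e-12)) break;
    prev_ll = ll;

    // ---- M step ----
    double pn = accu(pi_num);
    if (pn > 0) pi = pi_num / pn;
    for (uword s = 0; s < S; ++s) {
      double rs = accu(A_num.row(s));
      if (rs > 0) A.row(s) = A_num.row(s) / rs;
      double gs = accu(G.row(s));
      if (gs > 1e-12) {
        for (uword m = 0; m < M; ++m) {
          double g = G(s, m);
          if (g > 1e-12) {
            vec mu = Gx.slice(s).col(m) / g;
            vec v = Gx2.slice(s).col(m) / g - mu % mu;
            means.slice(s).col(m) = mu;
            vars.slice(s).col(m) = max(v, var_floor);
          }
          w(s, m) = g / gs;
        }
      }
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("pi") = pi, Rcpp::Named("A") = A, Rcpp::Named("w") = w,
      Rcpp::Named("means") = means, Rcpp::Named("vars") = vars,
      Rcpp::Named("loglik_trace") = trace);
}
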