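// Inner computational kernels of the variational engine:
//  - block-tridiagonal Gaussian smoother (variational Kalman E-step)
//  - Gauss-Seidel sweeps over the edge-indicator posteriors (A-step),
//    with the annealed mean-field update or the EM-mode continuous
//    parameter update.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Cholesky with escalating jitter; returns upper-triangular R with S = R'R.
// Jitter is only ever needed on nearly singular expected-precision blocks.
static mat chol_jitter(const mat& M, double& jitter_used) {
  mat S = 0.5 * (M + M.t());
  mat R;
  double j = 0.0;
  for (int k = 0; k < 6; ++k) {
    if (chol(R, S + j * eye(size(S)))) { jitter_used = std::max(jitter_used, j); return R; }
    j = (j == 0.0) ? 1e-9 : j * 100.0;
  }
  Rcpp::stop("precision block not positive definite even after jitter");
}

// Exact posterior moments of the latent states under the expected system.
// The joint posterior over (x_1,...,x_T) is Gaussian with block-tridiagonal
// precision: W = <H^-1> on the diagonal for t>=2, J = <(AoE)'H^-1(AoE)> for
// t<=T-1, off-diagonal blocks -K with K = <H^-1 AoE>, plus <R^-1> at observed
// points and a diffuse prior lambda0*I around x1mean at t=1.  Forward block
// elimination then backward substitution yields the smoothed means, marginal
// covariances and lag-one cross covariances.
// [[Rcpp::export]]
Rcpp::List smoother_cpp(const arma::mat& Y, const arma::ivec& obs,
                        int T, const arma::vec& w, const arma::vec& vr,
                        const arma::mat& J, const arma::mat& K,
                        const arma::vec& x1mean, double lambda0) {
  const int p = w.n_elem;
  if ((int)obs.n_elem != (int)Y.n_cols) Rcpp::stop("obs/Y mismatch");
  std::vector<int> obscol(T, -1);
  for (uword i = 0; i < obs.n_elem; ++i) {
    int t = obs(i) - 1;
    if (t < 0 || t >= T) Rcpp::stop("observed index out of range");
    obscol[t] = i;
  }
  mat Wd = diagmat(w), Vd = diagmat(vr);
  cube Cinv(p, p, T);
  mat Fv(p, T, fill::zeros);
  double logdetC = 0.0, jit = 0.0;
  for (int t = 0; t < T; ++t) {
    mat D(p, p, fill::zeros);
    vec b(p, fill::zeros);
    if (t < T - 1) D += J;
    if (t > 0) D += Wd;
    if (t == 0) { D += lambda0 * eye(p, p); b += lambda0 * x1mean; }
    if (obscol[t] >= 0) { D += Vd; b += vr % Y.col(obscol[t]); }
    if (t > 0) {
      // C_t = D_t - U Cinv_{t-1} U' with off-diagonal block U = -K
      D -= K * Cinv.slice(t - 1) * K.t();
      b += K * (Cinv.slice(t - 1) * Fv.col(t - 1));
    }
    mat R = chol_jitter(D, jit);
    logdetC += 2.0 * sum(log(R.diag()));
    mat Rinv = inv(trimatu(R));
    Cinv.slice(t) = Rinv * Rinv.t();
    Fv.col(t) = b;
  }
  mat Mu(p, T);
  cube Sig(p, p, T), Second(p, p, T);
  cube Cross(p, p, std::max(T - 1, 1));
  Mu.col(T - 1) = Cinv.slice(T - 1) * Fv.col(T - 1);
  Sig.slice(T - 1) = Cinv.slice(T - 1);
  for (int t = T - 2; t >= 0; --t) {
    Mu.col(t) = Cinv.slice(t) * (Fv.col(t) + K.t() * Mu.col(t + 1));
    mat CK = Cinv.slice(t) * K.t();
    mat crossS = CK * Sig.slice(t + 1);            // Sigma_{t,t+1}
    Sig.slice(t) = Cinv.slice(t) + crossS * CK.t();
    Cross.slice(t) = crossS.t() + Mu.col(t + 1) * Mu.col(t).t(); // <x_{t+1} x_t'>
  }
  for (int t = 0; t < T; ++t)
    Second.slice(t) = 0.5 * (Sig.slice(t) + Sig.slice(t).t()) + Mu.col(t) * Mu.col(t).t();
  if (!Mu.is_finite()) Rcpp::stop("non-finite smoothed moments");
  return Rcpp::List::create(
    Rcpp::Named("mean") = Mu,
    Rcpp::Named("second") = Second,
    Rcpp::Named("cross") = Cross,
    Rcpp::Named("cov") = Sig,
    Rcpp::Named("logdet_sigma") = -logdetC,
    Rcpp::Named("jitter") = jit);
}

// Gauss-Seidel sweeps over all edge-indicator coordinates (both conditions).
// For the annealed mean-field update each coordinate is set to the logistic
// of Delta/tau where Delta is the expected complete-log-joint difference
// between the edge being present and absent.  In EM mode the indicator is a
// deterministic parameter in [0,1] and the coordinate update is the exact
// maximizer of its (concave) quadratic objective.
// [[Rcpp::export]]
Rcpp::List astep_cpp(arma::mat e1, arma::mat e2, const arma::mat& mu,
                     const arma::cube& P,
                     const arma::mat& Sxx1, const arma::mat& Sxy1,
                     const arma::mat& Sxx2, const arma::mat& Sxy2,
                     const arma::vec& w, const arma::mat& g,
                     const arma::mat& psid,
                     double tau, int sweeps, bool em) {
  const int p = mu.n_rows;
  const double eps = 1e-12;
  for (int s = 0; s < sweeps; ++s) {
    for (int c = 0; c < 2; ++c) {
      mat& e = (c == 0) ? e1 : e2;
      mat& eo = (c == 0) ? e2 : e1;
      const mat& Sxx = (c == 0) ? Sxx1 : Sxx2;
      const mat& Sxy = (c == 0) ? Sxy1 : Sxy2;
      for (int i = 0; i < p; ++i) {
        const mat& Pi = P.slice(i);
        for (int j = 0; j < p; ++j) {
          double lin = w(i) * mu(i, j) * Sxy(i, j);
          double cross = 0.0;
          for (int k = 0; k < p; ++k)
            if (k != j) cross += e(i, k) * Pi(j, k) * Sxx(k, j);
          lin -= cross;
          double quad = Pi(j, j) * Sxx(j, j);
          double prior = (1.0 - eo(i, j)) * g(i, j) +
                         (1.0 - 2.0 * eo(i, j)) * psid(i, j);
          double enew;
          if (em) {
            double a = lin + prior;
            enew = (quad > 0.0) ? a / quad : (a > 0.0 ? 1.0 : 0.0);
            if (enew < 0.0) enew = 0.0;
            if (enew > 1.0) enew = 1.0;
          } else {
            double delta = lin - 0.5 * quad + prior;
            enew = 1.0 / (1.0 + std::exp(-delta / tau));
          }
          if (enew < eps) enew = eps;
          if (enew > 1.0 - eps) enew = 1.0 - eps;
          e(i, j) = enew;
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("e1") = e1, Rcpp::Named("e2") = e2);
}
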