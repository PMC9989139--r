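#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Dual Kalman filter for a time-varying MVAR(p) model x_t = sum_r A_r(t) x_{t-r} + e_t.
//
// Two coupled linear Kalman recursions:
//  * a weight filter over w = vec([A_1 ... A_p]) with random-walk dynamics
//    (process noise q I) and observation x_t = kron(xlag', I_N) w + e_t,
//    where xlag stacks the state filter's filtered lagged signals;
//  * a state filter over z_t = [x_t; ...; x_{t-p+1}] whose transition is the
//    companion matrix of the current coefficient estimates, observed through
//    y_t = x_t with observation noise r_obs I.
//
// The innovation covariance (the weight filter's measurement noise, an
// estimate of cov(e_t)) is adapted by exponential smoothing of innovation
// outer products at rate lambda.
//
// Returns per-sample coefficient trajectories W (n x N^2 p, rows before
// sample p+1 are zero), innovations, and the final innovation covariance.
//
// [[Rcpp::export]]
Rcpp::List dekf_cpp(const arma::mat& X, int p, double q, double init_scale,
                    double r_obs, double lambda) {
  const int n = X.n_rows;
  const int N = X.n_cols;
  const int M = N * N * p;
  const int S = N * p;

  mat W(n, M, fill::zeros);
  mat innov(n, N, fill::zeros);

  vec w(M, fill::zeros);
  mat Pw = init_scale * eye<mat>(M, M);
  const mat Qw = q * eye<mat>(M, M);

  // innovation covariance estimate, initialised at the data scale
  rowvec v = var(X, 0, 0);
  mat Rw = diagmat(conv_to<vec>::from(v));
  if (!Rw.is_finite() || trace(Rw) <= 0) Rw = eye<mat>(N, N);

  // filtered lag stack: [x_{t-1}; ...; x_{t-p}]
  vec zlag(S, fill::zeros);
  for (int r = 0; r < p; r++)
    zlag.subvec(r * N, r * N + N - 1) = X.row(p - 1 - r).t();
  mat Pz = eye<mat>(S, S);
  const mat Robs = r_obs * eye<mat>(N, N);
  const mat IN = eye<mat>(N, N);

  for (int t = p; t < n; t++) {
    // ---- weight filter ----------------------------------------------------
    Pw += Qw;
    mat H = kron(zlag.t(), IN);                // N x M
    vec y = X.row(t).t();
    vec eps = y - H * w;
    mat PHt = Pw * H.t();                      // M x N
    mat Sw = symmatu(H * PHt + Rw);
    Sw.diag() += 1e-10 * (1.0 + trace(Sw) / N);  // guard against degeneracy
    mat Sw_inv;
    if (!inv_sympd(Sw_inv, Sw))
      Rcpp::stop("numerically singular innovation covariance at sample %d; "
                 "increase q or the observation noise", t + 1);
    mat K = PHt * Sw_inv;                      // M x N
    w += K * eps;
    Pw = symmatu(Pw - K * H * Pw);

    Rw = symmatu((1.0 - lambda) * Rw + lambda * (eps * eps.t()));
    Rw.diag() += 1e-10;                        // keep strictly positive definite

    // ---- state filter -----------------------------------------------------
    mat F(S, S, fill::zeros);
    for (int r = 0; r < p; r++) {
      const mat Ar(const_cast<double*>(&w[r * N * N]), N, N, false, true);
      F.submat(0, r * N, N - 1, r * N + N - 1) = Ar;
    }
    if (p > 1)
      F.submat(N, 0, S - 1, S - N - 1) = eye<mat>(S - N, S - N);

    vec z_pred = F * zlag;
    mat Pz_pred = F * Pz * F.t();
    Pz_pred.submat(0, 0, N - 1, N - 1) += Rw;
    mat Sz = symmatu(Pz_pred.submat(0, 0, N - 1, N - 1) + Robs);
    Sz.diag() += 1e-10 * (1.0 + trace(Sz) / N);
    mat Sz_inv;
    if (!inv_sympd(Sz_inv, Sz))
      Rcpp::stop("numerically singular state innovation covariance at sample %d",
                 t + 1);
    mat Kz = Pz_pred.cols(0, N - 1) * Sz_inv;  // S x N
    vec z_filt = z_pred + Kz * (y - z_pred.subvec(0, N - 1));
    mat IKH = eye<mat>(S, S);
    IKH.cols(0, N - 1) -= Kz;
    Pz = symmatu(IKH * Pz_pred);
    Pz.diag() += 1e-12;

    W.row(t) = w.t();
    innov.row(t) = eps.t();
    zlag = z_filt;
  }

  return Rcpp::List::create(Rcpp::Named("W") = W,
                            Rcpp::Named("innov") = innov,
                            Rcpp::Named("sigma") = Rw);
}
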