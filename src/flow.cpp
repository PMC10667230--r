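// Inner loops of the diffeomorphic suture growth flow: explicit Euler
// integration of the combined locally-affine velocity field, and its
// adjoint (reverse-mode) pass used for analytic objective gradients.
//
// State: X (M x 3) grid-point positions; anchors are grid points
// (rows `arow`), advected by the same combined flow. Per step n:
//   X <- X + dt_n * ( ((W o proj_n) diag(v_n)) U + W diag(z_n) Y )
// with proj_n(m,a) = <X_m - X_{arow(a)}, u_a>, W the fixed normalized
// influence weights, u_a the suture growth directions and y_a the base
// displacement directions.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static vec anchor_offsets(const mat& X, const mat& U, const uvec& arow) {
  vec off(arow.n_elem);
  for (uword a = 0; a < arow.n_elem; ++a)
    off(a) = dot(X.row(arow(a)), U.row(a));
  return off;
}

// [[Rcpp::export]]
Rcpp::List cpp_flow(const arma::mat& X0, const arma::mat& U, const arma::mat& Y,
                    const arma::mat& W, const arma::uvec& arow,
                    const arma::mat& V, const arma::mat& Z,
                    const arma::vec& dtv, bool save_traj) {
  const uword N = V.n_rows, M = X0.n_rows;
  mat X = X0;
  mat Ut = U.t(), Yt = Y.t();
  cube traj;
  if (save_traj) {
    traj.set_size(M, 3, N + 1);
    traj.slice(0) = X;
  }
  int error_step = -1;
  for (uword n = 0; n < N; ++n) {
    mat proj = X * Ut;
    proj.each_row() -= anchor_offsets(X, U, arow).t();
    mat E = W % proj;
    E.each_row() %= V.row(n);
    mat WZ = W;
    WZ.each_row() %= Z.row(n);
    X += dtv(n) * (E * U + WZ * Y);
    if (save_traj) traj.slice(n + 1) = X;
    if (!X.is_finite()) { error_step = n + 1; break; }
  }
  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("X") = X,
    Rcpp::Named("error_step") = error_step);
  if (save_traj) out["traj"] = traj;
  return out;
}

// Adjoint of cpp_flow. `traj` is the saved forward trajectory (states
// 0..N). Gradient injections dL/dX_{idx} are supplied as a list of M x 3
// matrices `inj` with 0-based state indices `inj_idx`. Returns gradients
// of L with respect to the per-step rates V, Z, the weights W, and the
// initial state X0.
// [[Rcpp::export]]
Rcpp::List cpp_flow_adjoint(const arma::cube& traj, const arma::mat& U,
                            const arma::mat& Y, const arma::mat& W,
                            const arma::uvec& arow, const arma::mat& V,
                            const arma::mat& Z, const arma::vec& dtv,
                            const arma::ivec& inj_idx, const Rcpp::List& inj) {
  const uword N = V.n_rows, M = traj.n_rows, A = U.n_rows;
  mat lam(M, 3, fill::zeros);
  mat gV(N, A, fill::zeros), gZ(N, A, fill::zeros), gW(M, A, fill::zeros);
  mat Ut = U.t(), Yt = Y.t();

  // injections grouped by state index
  std::vector<std::vector<int> > at(N + 1);
  for (uword i = 0; i < inj_idx.n_elem; ++i)
    at[inj_idx(i)].push_back(i);

  for (int i : at[N]) lam += Rcpp::as<mat>(inj[i]);

  for (int n = N - 1; n >= 0; --n) {
    const mat& X = traj.slice(n);
    const double dt = dtv(n);
    rowvec v = V.row(n), z = Z.row(n);

    mat proj = X * Ut;
    proj.each_row() -= anchor_offsets(X, U, arow).t();
    mat LU = lam * Ut;   // LU(m,a) = <u_a, lambda_m>
    mat LY = lam * Yt;   // LY(m,a) = <y_a, lambda_m>

    mat WLU = W % LU;
    gV.row(n) = dt * sum(WLU % proj, 0);
    gZ.row(n) = dt * sum(W % LY, 0);
    mat gWn = LU % proj;
    gWn.each_row() %= v;
    mat gWz = LY;
    gWz.each_row() %= z;
    gW += dt * (gWn + gWz);

    // lambda update: own-position term plus anchor-position term
    mat Ev = WLU;
    Ev.each_row() %= v;
    mat dlam = dt * (Ev * U);
    rowvec coef = sum(WLU, 0);
    for (uword a = 0; a < A; ++a)
      dlam.row(arow(a)) -= dt * v(a) * coef(a) * U.row(a);
    lam += dlam;

    for (int i : at[n]) lam += Rcpp::as<mat>(inj[i]);
  }

  return Rcpp::List::create(
    Rcpp::Named("gV") = gV, Rcpp::Named("gZ") = gZ,
    Rcpp::Named("gW") = gW, Rcpp::Named("gX0") = lam);
}
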