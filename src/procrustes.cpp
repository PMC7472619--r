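// Per-frame orthogonal Procrustes fit of a rigid marker cluster.
// For each frame, finds the rotation R minimising || Q - P R^T || over
// centred marker sets (P = template, Q = frame), via the Kabsch SVD with a
// reflection guard, and returns the rotation as a unit quaternion together
// with the per-frame RMS residual.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

static arma::vec quat_from_R(const arma::mat33 &R) {
  arma::vec q(4);
  double tr = R(0, 0) + R(1, 1) + R(2, 2);
  if (tr > 0.0) {
    double s = std::sqrt(tr + 1.0) * 2.0;
    q = {0.25 * s, (R(2, 1) - R(1, 2)) / s, (R(0, 2) - R(2, 0)) / s,
         (R(1, 0) - R(0, 1)) / s};
  } else if (R(0, 0) > R(1, 1) && R(0, 0) > R(2, 2)) {
    double s = std::sqrt(1.0 + R(0, 0) - R(1, 1) - R(2, 2)) * 2.0;
    q = {(R(2, 1) - R(1, 2)) / s, 0.25 * s, (R(0, 1) + R(1, 0)) / s,
         (R(0, 2) + R(2, 0)) / s};
  } else if (R(1, 1) > R(2, 2)) {
    double s = std::sqrt(1.0 + R(1, 1) - R(0, 0) - R(2, 2)) * 2.0;
    q = {(R(0, 2) - R(2, 0)) / s, (R(0, 1) + R(1, 0)) / s, 0.25 * s,
         (R(1, 2) + R(2, 1)) / s};
  } else {
    double s = std::sqrt(1.0 + R(2, 2) - R(0, 0) - R(1, 1)) * 2.0;
    q = {(R(1, 0) - R(0, 1)) / s, (R(0, 2) + R(2, 0)) / s,
         (R(1, 2) + R(2, 1)) / s, 0.25 * s};
  }
  if (q(0) < 0.0) q = -q;
  return arma::normalise(q);
}

// tmpl: m x 3 template marker positions; frames: (n*m) x 3 stacked frames.
// [[Rcpp::export]]
Rcpp::List procrustes_frames(const arma::mat &tmpl, const arma::mat &frames) {
  const arma::uword m = tmpl.n_rows;
  if (tmpl.n_cols != 3 || frames.n_cols != 3 || frames.n_rows % m != 0)
    Rcpp::stop("template must be m x 3 and frames a stacked (n*m) x 3 matrix");
  const arma::uword n = frames.n_rows / m;

  arma::mat P = tmpl;
  P.each_row() -= arma::mean(tmpl, 0);

  arma::mat quats(n, 4);
  arma::vec resid(n);
  arma::mat33 H, U, V, R;
  arma::vec3 s;

  for (arma::uword i = 0; i < n; ++i) {
    arma::mat Q = frames.rows(i * m, (i + 1) * m - 1);
    Q.each_row() -= arma::mean(Q, 0);
    H = P.t() * Q;                       // 3x3 cross-covariance
    if (!arma::svd(U, s, V, H))
      Rcpp::stop("SVD failed on frame %d", (int)(i + 1));
    R = V * U.t();
    if (arma::det(R) < 0.0) {            // reflection guard
      V.col(2) *= -1.0;
      R = V * U.t();
    }
    resid(i) = std::sqrt(arma::accu(arma::square(Q - P * R.t())) / (double)m);
    quats.row(i) = quat_from_R(R).t();
  }
  return Rcpp::List::create(Rcpp::Named("quat") = quats,
                            Rcpp::Named("residual") = resid);
}
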