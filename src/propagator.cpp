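#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Propagate x' = A x + u(t) e1, x(0) = 0, where u(t) is piecewise constant.
// seg: rows (start, end, level) partitioning [0, max(times)];
// times: sorted, nonnegative. Returns states at the requested times.
//
// Fast path: eigendecomposition of A, exact per-segment update
//   x(t0+dt) = V e^{L dt} V^-1 x0 + u V phi(L, dt) V^-1 e1,
//   phi_i = (e^{l_i dt} - 1) / l_i   (dt when l_i ~ 0),
// used when the eigenvector matrix is well conditioned. Otherwise each
// constant-input stretch is advanced with the exponential of the augmented
// (n+1) x (n+1) matrix [[A, u e1], [0, 0]] (scaling-and-squaring), which
// handles defective A (e.g. repeated eigenvalues from tied rates).

static arma::mat propagate_expm(const arma::mat& A, const arma::mat& seg,
                                const arma::vec& times) {
  const unsigned int n = A.n_rows;
  arma::vec x(n, arma::fill::zeros);
  arma::mat out(times.n_elem, n, arma::fill::zeros);
  double tcur = 0.0;
  unsigned int s = 0;
  for (unsigned int i = 0; i < times.n_elem; ++i) {
    const double tt = times(i);
    while (tcur < tt - 1e-13) {
      while (s + 1 < seg.n_rows && tcur >= seg(s, 1) - 1e-13) ++s;
      const double tend = std::min(tt, seg(s, 1));
      if (tend <= tcur + 1e-15) { tcur = tt; break; }
      const double dt = tend - tcur;
      arma::mat M(n + 1, n + 1, arma::fill::zeros);
      M.submat(0, 0, n - 1, n - 1) = A * dt;
      M(0, n) = seg(s, 2) * dt;
      const arma::mat E = arma::expmat(M);
      x = E.submat(0, 0, n - 1, n - 1) * x + E.submat(0, n, n - 1, n);
      tcur = tend;
    }
    out.row(i) = x.t();
  }
  return out;
}

// [[Rcpp::export]]
arma::mat lin_propagate(const arma::mat& A, const arma::mat& seg,
                        const arma::vec& times) {
  const unsigned int n = A.n_rows;
  arma::cx_vec eval;
  arma::cx_mat V;
  bool ok = arma::eig_gen(eval, V, A);
  if (ok) {
    double rc = arma::rcond(V);
    if (!(rc > 1e-9)) ok = false;
  }
  if (!ok) return propagate_expm(A, seg, times);

  arma::cx_mat Vi;
  if (!arma::inv(Vi, V)) return propagate_expm(A, seg, times);
  const arma::cx_vec vi1 = Vi.col(0);  // V^-1 e1

  arma::cx_vec c(n, arma::fill::zeros);  // eigen-coordinates of the state
  arma::mat out(times.n_elem, n, arma::fill::zeros);
  double tcur = 0.0;
  unsigned int s = 0;
  for (unsigned int i = 0; i < times.n_elem; ++i) {
    const double tt = times(i);
    while (tcur < tt - 1e-13) {
      while (s + 1 < seg.n_rows && tcur >= seg(s, 1) - 1e-13) ++s;
      const double tend = std::min(tt, seg(s, 1));
      if (tend <= tcur + 1e-15) { tcur = tt; break; }
      const double dt = tend - tcur;
      const double u = seg(s, 2);
      for (unsigned int k = 0; k < n; ++k) {
        const std::complex<double> l = eval(k);
        const std::complex<double> el = std::exp(l * dt);
        const std::complex<double> phi =
          (std::abs(l) < 1e-12) ? std::complex<double>(dt, 0.0)
                                : (el - 1.0) / l;
        c(k) = el * c(k) + u * phi * vi1(k);
      }
      tcur = tend;
    }
    out.row(i) = arma::real(V * c).t();
  }
  return out;
}
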