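// Davydov D1 variational dynamics for the Holstein exciton-phonon model.
//
// State: alpha (N complex exciton amplitudes, site-major over rings) and
// lambda (N x Nq complex phonon displacements; each site carries the modes of
// its own ring's bath). All frequencies/energies enter in rad/fs, time in fs.
//
// Equations of motion (Dirac-Frenkel on the D1 manifold; displacements of a
// site in other rings' baths are identically zero, so inter-ring
// coherent-state overlaps factor through the phonon vacuum):
//   i d/dt alpha_j = sum_k J_jk S_jk alpha_k
//                    - alpha_j Re(lambda_j^dag kappa_j)
//                    - alpha_j [Re(lambda_j^dag R_j) - |lambda_j|^2 Re G_j] / |alpha_j|^2
//   i d/dt lambda_jq = omega_q lambda_jq - kappa_jq
//                      + [R_jq - lambda_jq G_j] / |alpha_j|^2
// with S_jk the Debye-Waller overlap, A = J % S, G_j = conj(alpha_j) (A alpha)_j,
// R_jq = conj(alpha_j) sum_{k in ring(j)} A_jk alpha_k lambda_kq, and
// kappa_jq = (g_q omega_q / sqrt(Ns)) exp(-i q n_j).
// Denominators are regularized by |alpha_j|^2 + eps.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct D1System {
  mat J;              // N x N, rad/fs
  vec omega;          // Nq, rad/fs
  rowvec omega_r;
  cx_rowvec omega_cr;
  cx_mat kappa;       // N x Nq, rad/fs
  uword nrings, ns, N, Nq;
  double eps;
};

struct D1Work {
  vec b, eb, denom, lk, lr, gre;
  cx_mat A, R;
  cx_vec u, G;
};

// Debye-Waller overlap matrix folded into A = J % S
void build_A(const D1System& sys, const cx_vec& alpha, const cx_mat& lambda,
             D1Work& w) {
  mat ab2 = square(abs(lambda));
  w.b = 0.5 * sum(ab2, 1);
  w.eb = exp(-w.b);
  mat Sg = w.eb * w.eb.t();
  w.A = cx_mat(sys.J % Sg, mat(sys.N, sys.N, fill::zeros));
  for (uword r = 0; r < sys.nrings; ++r) {
    uword a0 = r * sys.ns, a1 = a0 + sys.ns - 1;
    cx_mat lam_r = lambda.rows(a0, a1);
    cx_mat cross = conj(lam_r) * strans(lam_r);
    w.A.submat(a0, a0, a1, a1) %= exp(cross);
  }
}

void d1_rhs(const D1System& sys, const cx_vec& alpha, const cx_mat& lambda,
            cx_vec& dalpha, cx_mat& dlambda, D1Work& w) {
  build_A(sys, alpha, lambda, w);
  w.u = w.A * alpha;
  w.G = conj(alpha) % w.u;
  w.denom = square(abs(alpha)) + sys.eps;

  w.R.set_size(sys.N, sys.Nq);
  for (uword r = 0; r < sys.nrings; ++r) {
    uword a0 = r * sys.ns, a1 = a0 + sys.ns - 1;
    cx_mat B = lambda.rows(a0, a1);
    B.each_col() %= alpha.subvec(a0, a1);
    cx_mat Rr = w.A.submat(a0, a0, a1, a1) * B;
    Rr.each_col() %= conj(alpha.subvec(a0, a1));
    w.R.rows(a0, a1) = Rr;
  }

  w.lk = real(sum(conj(lambda) % sys.kappa, 1));
  w.lr = real(sum(conj(lambda) % w.R, 1));
  w.gre = real(w.G);

  const std::complex<double> mi(0.0, -1.0);
  vec scal = w.lk + (w.lr - 2.0 * w.b % w.gre) / w.denom;
  dalpha = mi * (w.u - alpha % cx_vec(scal, vec(sys.N, fill::zeros)));

  dlambda = lambda;
  dlambda.each_row() %= sys.omega_cr;
  dlambda -= sys.kappa;
  cx_mat corr = lambda;
  corr.each_col() %= w.G;
  corr = w.R - corr;
  corr.each_col() /= cx_vec(w.denom, vec(sys.N, fill::zeros));
  dlambda += corr;
  dlambda *= mi;
}

double d1_energy(const D1System& sys, const cx_vec& alpha,
                 const cx_mat& lambda, D1Work& w) {
  build_A(sys, alpha, lambda, w);
  double e_ex = real(cdot(alpha, w.A * alpha));
  mat l2m = square(abs(lambda));
  l2m.each_row() %= sys.omega_r;
  vec bath_site = sum(l2m, 1) - 2.0 * real(sum(conj(lambda) % sys.kappa, 1));
  vec pop = square(abs(alpha));
  return e_ex + dot(pop, bath_site);
}

D1System make_system(const mat& J, const vec& omega, const cx_mat& kappa,
                     int nrings, int ns, double eps) {
  D1System sys;
  sys.J = J; sys.omega = omega; sys.kappa = kappa;
  sys.omega_r = omega.t();
  sys.omega_cr = cx_rowvec(sys.omega_r, rowvec(omega.n_elem, fill::zeros));
  sys.nrings = (uword)nrings; sys.ns = (uword)ns;
  sys.N = J.n_rows; sys.Nq = omega.n_elem; sys.eps = eps;
  if (sys.N != sys.nrings * sys.ns) Rcpp::stop("N != nrings * ns");
  if (kappa.n_rows != sys.N || kappa.n_cols != sys.Nq)
    Rcpp::stop("kappa shape mismatch");
  return sys;
}

} // namespace

// [[Rcpp::export]]
Rcpp::List d1_rhs_cpp(const arma::cx_vec& alpha, const arma::cx_mat& lambda,
                      const arma::mat& J, const arma::vec& omega,
                      const arma::cx_mat& kappa, int nrings, int ns,
                      double eps) {
  D1System sys = make_system(J, omega, kappa, nrings, ns, eps);
  D1Work w;
  cx_vec da;
  cx_mat dl;
  d1_rhs(sys, alpha, lambda, da, dl, w);
  return Rcpp::List::create(Rcpp::Named("dalpha") = da,
                            Rcpp::Named("dlambda") = dl);
}

// [[Rcpp::export]]
double d1_energy_cpp(const arma::cx_vec& alpha, const arma::cx_mat& lambda,
                     const arma::mat& J, const arma::vec& omega,
                     const arma::cx_mat& kappa, int nrings, int ns,
                     double eps) {
  D1System sys = make_system(J, omega, kappa, nrings, ns, eps);
  D1Work w;
  return d1_energy(sys, alpha, lambda, w);
}

// Fixed-step classical 4th-order Runge-Kutta propagation with strided
// snapshots. Aborts if the wavefunction norm drifts beyond norm_tol.
// [[Rcpp::export]]
Rcpp::List d1_propagate_cpp(const arma::cx_vec& alpha0,
                            const arma::cx_mat& lambda0,
                            const arma::mat& J, const arma::vec& omega,
                            const arma::cx_mat& kappa, int nrings, int ns,
                            double dt, int n_steps, int stride, double eps,
                            double norm_tol) {
  D1System sys = make_system(J, omega, kappa, nrings, ns, eps);
  D1Work w;
  cx_vec alpha = alpha0;
  cx_mat lambda = lambda0;

  const uword n_snap = (uword)(n_steps / stride) + 1;
  cx_mat out_alpha(sys.N, n_snap);
  cx_cube out_lambda(sys.N, sys.Nq, n_snap);
  vec out_norm(n_snap), out_energy(n_snap), out_t(n_snap);

  cx_vec k1a, k2a, k3a, k4a;
  cx_mat k1l, k2l, k3l, k4l;

  uword isnap = 0;
  auto record = [&](double t) {
    out_alpha.col(isnap) = alpha;
    out_lambda.slice(isnap) = lambda;
    double nrm = accu(square(abs(alpha)));
    out_norm(isnap) = nrm;
    out_energy(isnap) = d1_energy(sys, alpha, lambda, w);
    out_t(isnap) = t;
    ++isnap;
    if (std::abs(nrm - out_norm(0)) > norm_tol)
      Rcpp::stop("norm drift %.3e exceeds tolerance %.1e: reduce dt",
                 std::abs(nrm - out_norm(0)), norm_tol);
  };
  record(0.0);

  for (int step = 1; step <= n_steps; ++step) {
    d1_rhs(sys, alpha, lambda, k1a, k1l, w);
    d1_rhs(sys, alpha + 0.5 * dt * k1a, lambda + 0.5 * dt * k1l, k2a, k2l, w);
    d1_rhs(sys, alpha + 0.5 * dt * k2a, lambda + 0.5 * dt * k2l, k3a, k3l, w);
    d1_rhs(sys, alpha + dt * k3a, lambda + dt * k3l, k4a, k4l, w);
    alpha += (dt / 6.0) * (k1a + 2.0 * k2a + 2.0 * k3a + k4a);
    lambda += (dt / 6.0) * (k1l + 2.0 * k2l + 2.0 * k3l + k4l);
    if (step % stride == 0) record(step * dt);
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(
      Rcpp::Named("times") = out_t,
      Rcpp::Named("alpha") = out_alpha,
      Rcpp::Named("lambda") = out_lambda,
      Rcpp::Named("norm") = out_norm,
      Rcpp::Named("energy") = out_energy);
}
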