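// Fewest-switches surface hopping on linear-vibronic-coupling surfaces.
//
// Dynamics run in dimensionless normal coordinates Q with Hamiltonian
//   H = sum_k omega_k P_k^2 / 2 + V_ad(Q),  v_k = Qdot_k = omega_k P_k,
// i.e. effective mass 1/omega_k per mode.  Velocity Verlet on the active
// adiabatic surface; electronic amplitudes integrated with RK4 on
// n_substeps per nuclear step with linear interpolation of the state
// energies and the scalar couplings v.d_ij; Tully hop probabilities
// evaluated once per nuclear step from the end-of-step quantities; hops
// rescale the velocity along the nonadiabatic coupling vector.
//
// Uses R's RNG so ensembles are reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct LVCEval {
  arma::vec E;       // adiabatic energies, ascending
  arma::mat U;       // eigenvectors (columns)
  arma::mat grad;    // n_states x n_modes
  arma::cube nac;    // n_states x n_states x n_modes
  int degen;
};

static void lvc_eval(const arma::vec &omega, const arma::vec &offsets,
                     const arma::mat &kappa, const arma::cube &lambda,
                     const arma::mat &lambda0, const arma::vec &Q,
                     double gap_floor, LVCEval &ev) {
  const int ns = offsets.n_elem, nm = omega.n_elem;
  double vcom = 0.5 * arma::dot(omega, Q % Q);
  arma::mat H = lambda0;
  for (int k = 0; k < nm; ++k) H += lambda.slice(k) * Q(k);
  for (int a = 0; a < ns; ++a)
    H(a, a) += offsets(a) + vcom + arma::dot(kappa.row(a).t(), Q);
  arma::eig_sym(ev.E, ev.U, H);  // ascending
  ev.degen = 0;
  for (int k = 0; k < nm; ++k) {
    arma::mat W = lambda.slice(k);
    for (int a = 0; a < ns; ++a) W(a, a) = kappa(a, k) + omega(k) * Q(k);
    arma::mat M = ev.U.t() * W * ev.U;
    for (int a = 0; a < ns; ++a) ev.grad(a, k) = M(a, a);
    for (int i = 0; i < ns; ++i)
      for (int j = 0; j < ns; ++j) {
        if (i == j) { ev.nac(i, j, k) = 0.0; continue; }
        double dE = ev.E(j) - ev.E(i);
        if (std::abs(dE) < gap_floor) {
          dE = (dE >= 0 ? gap_floor : -gap_floor);
          ev.degen++;
        }
        ev.nac(i, j, k) = M(i, j) / dE;
      }
  }
}

static void align_phase(const arma::mat &Uprev, LVCEval &ev) {
  const int ns = ev.U.n_cols;
  arma::vec s(ns, arma::fill::ones);
  for (int i = 0; i < ns; ++i)
    if (arma::dot(Uprev.col(i), ev.U.col(i)) < 0) s(i) = -1.0;
  for (int i = 0; i < ns; ++i) {
    if (s(i) < 0) ev.U.col(i) *= -1.0;
    for (int j = 0; j < ns; ++j)
      if (s(i) * s(j) < 0) ev.nac.tube(i, j) *= -1.0;
  }
}

// RK4 for  i cdot = diag(E) c - i K c   (K real antisymmetric, = v.d)
// i.e. cdot = -i E % c - K c, with linear interpolation E0->E1, K0->K1.
static double rk4_coeffs(arma::cx_vec &c, const arma::vec &E0,
                         const arma::vec &E1, const arma::mat &K0,
                         const arma::mat &K1, double dt, int nsub) {
  const arma::cx_double I(0.0, 1.0);
  const double h = dt / nsub;
  arma::vec Ea, Eb, Em;
  arma::mat Ka, Kb, Km;
  for (int s = 0; s < nsub; ++s) {
    double f0 = double(s) / nsub, f1 = double(s + 1) / nsub,
           fm = (f0 + f1) / 2;
    Ea = E0 + f0 * (E1 - E0); Ka = K0 + f0 * (K1 - K0);
    Em = E0 + fm * (E1 - E0); Km = K0 + fm * (K1 - K0);
    Eb = E0 + f1 * (E1 - E0); Kb = K0 + f1 * (K1 - K0);
    arma::cx_vec k1 = -I * (Ea % c) - Ka * c;
    arma::cx_vec c2 = c + 0.5 * h * k1;
    arma::cx_vec k2 = -I * (Em % c2) - Km * c2;
    arma::cx_vec c3 = c + 0.5 * h * k2;
    arma::cx_vec k3 = -I * (Em % c3) - Km * c3;
    arma::cx_vec c4 = c + h * k3;
    arma::cx_vec k4 = -I * (Eb % c4) - Kb * c4;
    c += h / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
  }
  return std::abs(arma::norm(c) - 1.0);
}

// [[Rcpp::export(name = ".lvc_fssh_cpp")]]
List lvc_fssh_cpp(const arma::vec &omega, const arma::vec &offsets,
                  const arma::mat &kappa, const arma::cube &lambda,
                  const arma::mat &lambda0, const arma::vec &Q0,
                  const arma::vec &P0, double dt,
                  int nsteps, int nsub, int init_state, bool allow_hops,
                  bool reverse_frustrated, double gap_floor = 1e-8,
                  double norm_tol = 1e-6) {
  const int ns = offsets.n_elem, nm = omega.n_elem;
  LVCEval cur, nxt;
  cur.grad.set_size(ns, nm); cur.nac.set_size(ns, ns, nm);
  nxt.grad.set_size(ns, nm); nxt.nac.set_size(ns, ns, nm);

  arma::vec Q = Q0, v = omega % P0;  // velocities Qdot
  int act = init_state - 1;
  arma::cx_vec c(ns, arma::fill::zeros);
  c(act) = 1.0;

  lvc_eval(omega, offsets, kappa, lambda, lambda0, Q, gap_floor, cur);

  arma::mat Qrec(nsteps + 1, nm), Vrec(nsteps + 1, nm),
      Erec(nsteps + 1, ns), Cre(nsteps + 1, ns), Cim(nsteps + 1, ns);
  arma::ivec arec(nsteps + 1);
  arma::vec etot(nsteps + 1), norm_err(nsteps + 1, arma::fill::zeros);
  std::vector<double> hop_time, hop_gap;
  std::vector<int> hop_from, hop_to, hop_acc;
  int degen_total = cur.degen;

  auto kinetic = [&](const arma::vec &vv) {
    return 0.5 * arma::dot(vv % vv, 1.0 / omega);
  };
  auto record = [&](int t) {
    Qrec.row(t) = Q.t(); Vrec.row(t) = v.t(); Erec.row(t) = cur.E.t();
    arec(t) = act + 1;
    Cre.row(t) = arma::real(c).t(); Cim.row(t) = arma::imag(c).t();
    etot(t) = kinetic(v) + cur.E(act);
  };
  record(0);

  for (int step = 0; step < nsteps; ++step) {
    arma::vec a0 = -cur.grad.row(act).t() % omega;  // accel = -grad/m
    arma::vec vh = v + 0.5 * dt * a0;
    arma::vec Qn = Q + dt * vh;
    lvc_eval(omega, offsets, kappa, lambda, lambda0, Qn, gap_floor, nxt);
    align_phase(cur.U, nxt);
    degen_total += nxt.degen;
    arma::vec a1 = -nxt.grad.row(act).t() % omega;
    arma::vec vn = vh + 0.5 * dt * a1;

    // scalar couplings v.d at both ends
    arma::mat K0(ns, ns, arma::fill::zeros), K1(ns, ns, arma::fill::zeros);
    for (int k = 0; k < nm; ++k) {
      K0 += cur.nac.slice(k) * v(k);
      K1 += nxt.nac.slice(k) * vn(k);
    }
    arma::cx_vec c_try = c;
    double drift = rk4_coeffs(c_try, cur.E, nxt.E, K0, K1, dt, nsub);
    if (drift >= norm_tol) {
      c_try = c;
      drift = rk4_coeffs(c_try, cur.E, nxt.E, K0, K1, dt, 4 * nsub);
    }
    c = c_try / arma::norm(c_try);
    norm_err(step + 1) = drift;

    Q = Qn; v = vn; cur = nxt;

    if (allow_hops) {
      double pa = std::norm(c(act));
      if (pa > 1e-10) {
        arma::vec g(ns, arma::fill::zeros);
        for (int j = 0; j < ns; ++j) {
          if (j == act) continue;
          double flux = 2.0 * dt *
              std::real(std::conj(c(act)) * c(j) * K1(act, j)) / pa;
          g(j) = std::max(0.0, flux);
        }
        double gsum = arma::accu(g);
        if (gsum > 1.0) g /= gsum;
        double xi = R::runif(0.0, 1.0), cum = 0.0;
        for (int j = 0; j < ns; ++j) {
          if (j == act) continue;
          cum += g(j);
          if (xi < cum) {
            arma::vec h = cur.nac.tube(act, j);
            double hn2 = arma::dot(h, h);
            if (hn2 < 1e-24) h = v / std::max(arma::norm(v), 1e-300);
            double A = 0.5 * arma::dot(h % h, omega);
            double B = arma::dot(v, h);
            double dE = cur.E(j) - cur.E(act);
            double disc = B * B - 4.0 * A * dE;
            bool ok = disc >= 0.0 && A > 0.0;
            hop_time.push_back((step + 1) * dt);
            hop_from.push_back(act + 1);
            hop_to.push_back(j + 1);
            hop_gap.push_back(dE);
            if (ok) {
              double r1 = (-B + std::sqrt(disc)) / (2.0 * A);
              double r2 = (-B - std::sqrt(disc)) / (2.0 * A);
              double gam = (std::abs(r1) < std::abs(r2)) ? r1 : r2;
              v += gam * (h % omega);
              act = j;
              hop_acc.push_back(1);
            } else {
              hop_acc.push_back(0);
              if (reverse_frustrated && A > 0.0) v += (-B / A) * (h % omega);
            }
            break;
          }
        }
      }
    }
    record(step + 1);
  }

  return List::create(
      _["Q"] = Qrec, _["V"] = Vrec, _["energies"] = Erec,
      _["active"] = arec, _["coeff_re"] = Cre, _["coeff_im"] = Cim,
      _["etot"] = etot, _["norm_err"] = norm_err,
      _["hops"] = DataFrame::create(
          _["time"] = hop_time, _["from"] = hop_from, _["to"] = hop_to,
          _["accepted"] = hop_acc, _["gap"] = hop_gap),
      _["degenerate_evals"] = degen_total);
}
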