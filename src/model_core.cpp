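#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Analytic model surface for a hydrogen-bonded water dimer, atom order
// O H H O H H, coordinates in bohr, energies in hartree.  Intramolecular:
// Morse OH bonds + harmonic bend.  Intermolecular (2-body): O-O Morse well,
// four equivalent H...O cross Morse wells, four equivalent H-H exponential
// repulsions.  All terms depend on interatomic distances/angles only, so the
// surface is exactly invariant under rigid motions and under permutation of
// the two H atoms within a monomer (and under monomer exchange).

struct Par {
  double De, aOH, rOH, kb, th0;          // monomer
  double Doo, aoo, roo;                  // O-O Morse well
  double Dho, aho, rho;                  // H...O cross Morse well
  double Dhh, ahh, rhh;                  // H-H Morse (shallow well, steep wall)
  double qh, rcut;                       // damped Coulomb: +qh on H, -2qh on O
  double mu0, mu1;                       // bond-dipole expansion
};

static Par getpar(const List& p) {
  Par q;
  q.De  = as<double>(p["d_oh"]);   q.aOH = as<double>(p["a_oh"]);
  q.rOH = as<double>(p["r_oh"]);   q.kb  = as<double>(p["k_bend"]);
  q.th0 = as<double>(p["theta0"]);
  q.Doo = as<double>(p["d_oo"]);   q.aoo = as<double>(p["a_oo"]);
  q.roo = as<double>(p["r_oo"]);
  q.Dho = as<double>(p["d_ho"]);   q.aho = as<double>(p["a_ho"]);
  q.rho = as<double>(p["r_ho"]);
  q.Dhh = as<double>(p["d_hh"]);   q.ahh = as<double>(p["a_hh"]);
  q.rhh = as<double>(p["r_hh"]);
  q.qh  = as<double>(p["q_h"]);    q.rcut = as<double>(p["r_damp"]);
  q.mu0 = as<double>(p["mu0"]);    q.mu1 = as<double>(p["mu1"]);
  return q;
}

static inline double dvec(const double* x, int i, int j, double* d) {
  d[0] = x[3*i]   - x[3*j];
  d[1] = x[3*i+1] - x[3*j+1];
  d[2] = x[3*i+2] - x[3*j+2];
  return std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
}

// bonded Morse: 0 at r = re, +D at infinity
static inline double morse_bond(double r, double D, double a, double re,
                                double* dv) {
  double u = std::exp(-a * (r - re)), om = 1.0 - u;
  if (dv) *dv = 2.0 * D * a * om * u;
  return D * om * om;
}

// damped Coulomb: qq/r * exp(-(r/rc)^4), short of its undamped value only
// beyond ~rc so the 2-body term decays to numerical zero at long range
static inline double coulomb_damped(double r, double qq, double rc,
                                    double* dv) {
  double z = r / rc, z4 = z*z*z*z;
  double f = std::exp(-z4);
  double v = qq / r * f;
  if (dv) *dv = v * (-1.0 / r - 4.0 * z4 / r);
  return v;
}

// Morse well: -D at r = re, 0 at infinity
static inline double morse_well(double r, double D, double a, double re,
                                double* dv) {
  double u = std::exp(-a * (r - re));
  if (dv) *dv = 2.0 * D * a * u * (1.0 - u);
  return D * (u * u - 2.0 * u);
}

static inline void add_radial(double* g, const double* d, double r,
                              double dv, int i, int j) {
  for (int k = 0; k < 3; ++k) {
    double f = dv * d[k] / r;
    g[3*i+k] += f;
    g[3*j+k] -= f;
  }
}

// one water monomer with O at atom index o, H at o+1, o+2
static double monomer_eg(const double* x, int o, const Par& p, double* g) {
  double e = 0.0, d1[3], d2[3], dv;
  double r1 = dvec(x, o + 1, o, d1);
  e += morse_bond(r1, p.De, p.aOH, p.rOH, g ? &dv : nullptr);
  if (g) add_radial(g, d1, r1, dv, o + 1, o);
  double r2 = dvec(x, o + 2, o, d2);
  e += morse_bond(r2, p.De, p.aOH, p.rOH, g ? &dv : nullptr);
  if (g) add_radial(g, d2, r2, dv, o + 2, o);

  double c = (d1[0]*d2[0] + d1[1]*d2[1] + d1[2]*d2[2]) / (r1 * r2);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  double th = std::acos(c);
  e += 0.5 * p.kb * (th - p.th0) * (th - p.th0);
  if (g) {
    double s = std::sqrt(1.0 - c * c);
    if (s < 1e-10) s = 1e-10;
    double pref = -p.kb * (th - p.th0) / s;   // dE/dc
    for (int k = 0; k < 3; ++k) {
      double dc1 = d2[k] / (r1 * r2) - c * d1[k] / (r1 * r1);
      double dc2 = d1[k] / (r1 * r2) - c * d2[k] / (r2 * r2);
      g[3*(o+1)+k] += pref * dc1;
      g[3*(o+2)+k] += pref * dc2;
      g[3*o+k]     -= pref * (dc1 + dc2);
    }
  }
  return e;
}

// 2-body term over atoms {0,1,2} x {3,4,5}
static double pair_eg(const double* x, const Par& p, double* g) {
  double e = 0.0, d[3], dv, r;
  r = dvec(x, 0, 3, d);
  e += morse_well(r, p.Doo, p.aoo, p.roo, g ? &dv : nullptr);
  if (g) add_radial(g, d, r, dv, 0, 3);
  const int hd[2] = {1, 2}, ha[2] = {4, 5};
  for (int i = 0; i < 2; ++i) {           // donor H ... acceptor O
    r = dvec(x, hd[i], 3, d);
    e += morse_well(r, p.Dho, p.aho, p.rho, g ? &dv : nullptr);
    if (g) add_radial(g, d, r, dv, hd[i], 3);
  }
  for (int j = 0; j < 2; ++j) {           // acceptor H ... donor O
    r = dvec(x, ha[j], 0, d);
    e += morse_well(r, p.Dho, p.aho, p.rho, g ? &dv : nullptr);
    if (g) add_radial(g, d, r, dv, ha[j], 0);
  }
  for (int i = 0; i < 2; ++i)
    for (int j = 0; j < 2; ++j) {
      r = dvec(x, hd[i], ha[j], d);
      e += morse_well(r, p.Dhh, p.ahh, p.rhh, g ? &dv : nullptr);
      if (g) add_radial(g, d, r, dv, hd[i], ha[j]);
    }
  if (p.qh != 0.0) {
    const double qO = -2.0 * p.qh, qH = p.qh;
    const int atoms1[3] = {0, 1, 2}, atoms2[3] = {3, 4, 5};
    const double q1[3] = {qO, qH, qH}, q2[3] = {qO, qH, qH};
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) {
        r = dvec(x, atoms1[i], atoms2[j], d);
        e += coulomb_damped(r, q1[i] * q2[j], p.rcut,
                            g ? &dv : nullptr);
        if (g) add_radial(g, d, r, dv, atoms1[i], atoms2[j]);
      }
  }
  return e;
}

static double total_eg(const double* x, const Par& p, double* g) {
  return monomer_eg(x, 0, p, g) + monomer_eg(x, 3, p, g) + pair_eg(x, p, g);
}

// bond-dipole model: mu = sum over OH bonds of (mu0 + mu1 (r - re)) u_hat,
// u_hat pointing O -> H.  J is 3 x 3N (row = dipole component), may be null.
static void dipole_acc(const double* x, int o, const Par& p,
                       double* mu, double* J, int ncol) {
  for (int h = o + 1; h <= o + 2; ++h) {
    double d[3];
    double r = dvec(x, h, o, d);
    double m = p.mu0 + p.mu1 * (r - p.rOH);
    double u[3] = {d[0] / r, d[1] / r, d[2] / r};
    for (int a = 0; a < 3; ++a) mu[a] += m * u[a];
    if (J) {
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b) {
          double dab = (a == b) ? 1.0 : 0.0;
          double val = p.mu1 * u[b] * u[a] + m * (dab - u[a] * u[b]) / r;
          J[a + 3 * (3 * h + b)] += val;
          J[a + 3 * (3 * o + b)] -= val;
        }
    }
  }
  (void)ncol;
}

// ---------------------------------------------------------------- exports

// [[Rcpp::export]]
double pq_model_energy(NumericVector coords, List par) {
  Par p = getpar(par);
  return total_eg(REAL(coords), p, nullptr);
}

// [[Rcpp::export]]
NumericVector pq_model_energy_batch(NumericMatrix X, List par) {
  // rows of X are 18-long coordinate vectors
  Par p = getpar(par);
  int n = X.nrow();
  NumericVector out(n);
  std::vector<double> x(18);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < 18; ++k) x[k] = X(i, k);
    out[i] = total_eg(x.data(), p, nullptr);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector pq_model_gradient(NumericVector coords, List par) {
  Par p = getpar(par);
  NumericVector g(coords.size());
  total_eg(REAL(coords), p, REAL(g));
  return g;
}

// [[Rcpp::export]]
double pq_model_pair_energy(NumericVector coords, List par) {
  Par p = getpar(par);
  return pair_eg(REAL(coords), p, nullptr);
}

// [[Rcpp::export]]
NumericVector pq_model_pair_gradient(NumericVector coords, List par) {
  Par p = getpar(par);
  NumericVector g(coords.size());
  pair_eg(REAL(coords), p, REAL(g));
  return g;
}

// [[Rcpp::export]]
double pq_model_monomer_energy(NumericVector coords9, List par) {
  Par p = getpar(par);
  return monomer_eg(REAL(coords9), 0, p, nullptr);
}

// [[Rcpp::export]]
NumericVector pq_model_monomer_gradient(NumericVector coords9, List par) {
  Par p = getpar(par);
  NumericVector g(coords9.size());
  monomer_eg(REAL(coords9), 0, p, REAL(g));
  return g;
}

// [[Rcpp::export]]
NumericVector pq_model_dipole(NumericVector coords, List par) {
  Par p = getpar(par);
  NumericVector mu(3);
  dipole_acc(REAL(coords), 0, p, REAL(mu), nullptr, 18);
  dipole_acc(REAL(coords), 3, p, REAL(mu), nullptr, 18);
  return mu;
}

// [[Rcpp::export]]
NumericMatrix pq_model_dipole_batch(NumericMatrix X, List par) {
  Par p = getpar(par);
  int n = X.nrow();
  NumericMatrix out(n, 3);
  std::vector<double> x(18);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < 18; ++k) x[k] = X(i, k);
    double mu[3] = {0, 0, 0};
    dipole_acc(x.data(), 0, p, mu, nullptr, 18);
    dipole_acc(x.data(), 3, p, mu, nullptr, 18);
    for (int a = 0; a < 3; ++a) out(i, a) = mu[a];
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix pq_model_dipole_jacobian(NumericVector coords, List par) {
  Par p = getpar(par);
  NumericMatrix J(3, 18);
  NumericVector mu(3);
  dipole_acc(REAL(coords), 0, p, REAL(mu), REAL(J), 18);
  dipole_acc(REAL(coords), 3, p, REAL(mu), REAL(J), 18);
  return J;
}

// [[Rcpp::export]]
NumericVector pq_model_monomer_dipole(NumericVector coords9, List par) {
  Par p = getpar(par);
  NumericVector mu(3);
  dipole_acc(REAL(coords9), 0, p, REAL(mu), nullptr, 9);
  return mu;
}

// Velocity-Verlet propagation of the completed-square cavity Hamiltonian on
// the model dimer surface.  All quantities in atomic units.  Cavity modes
// enter with unit mass; ck = sqrt(2/omega^3) g.  With g = 0 every coupling
// contribution is an exact floating-point zero, so the nuclear update is
// value-identical to a cavity-free propagation.
// [[Rcpp::export]]
List pq_propagate_model(NumericVector coords, NumericVector vels,
                        NumericVector mass_atoms,
                        NumericVector omega, NumericVector gfac,
                        NumericMatrix epol, NumericVector q0,
                        NumericVector p0, double dt, int nsteps, int stride,
                        double rcrit, List par_, bool stop_at_diss) {
  Par p = getpar(par_);
  const int nat = 6, nc = 18;
  const int k = omega.size();
  std::vector<double> x(REAL(coords), REAL(coords) + nc);
  std::vector<double> v(REAL(vels), REAL(vels) + nc);
  std::vector<double> m(nc);
  for (int i = 0; i < nat; ++i)
    for (int a = 0; a < 3; ++a) m[3*i+a] = mass_atoms[i];
  std::vector<double> q(k), pc(k), ck(k), aq(k);
  for (int j = 0; j < k; ++j) {
    q[j] = q0[j]; pc[j] = p0[j];
    ck[j] = std::sqrt(2.0 / (omega[j]*omega[j]*omega[j])) * gfac[j];
  }

  std::vector<double> grad(nc), J(3 * nc), fnuc(nc);
  double mu[3], V = 0.0;

  auto forces = [&](void) {
    std::fill(grad.begin(), grad.end(), 0.0);
    std::fill(J.begin(), J.end(), 0.0);
    mu[0] = mu[1] = mu[2] = 0.0;
    V = total_eg(x.data(), p, grad.data());
    dipole_acc(x.data(), 0, p, mu, J.data(), nc);
    dipole_acc(x.data(), 3, p, mu, J.data(), nc);
    for (int i = 0; i < nc; ++i) fnuc[i] = -grad[i];
    for (int j = 0; j < k; ++j) {
      double me = mu[0]*epol(0,j) + mu[1]*epol(1,j) + mu[2]*epol(2,j);
      double s = q[j] + ck[j] * me;
      double w2s = omega[j] * omega[j] * s;
      aq[j] = -w2s;
      double cf = w2s * ck[j];
      for (int i = 0; i < nc; ++i) {
        double je = J[0 + 3*i]*epol(0,j) + J[1 + 3*i]*epol(1,j) +
                    J[2 + 3*i]*epol(2,j);
        fnuc[i] -= cf * je;
      }
    }
  };

  auto roo = [&](void) {
    double d0 = x[0] - x[9], d1 = x[1] - x[10], d2 = x[2] - x[11];
    return std::sqrt(d0*d0 + d1*d1 + d2*d2);
  };

  std::vector<double> t_rec, emol_rec, ecav_rec, efield_rec, roo_rec;
  bool dissociated = false;
  double t_diss = NA_REAL;
  int steps_done = 0;

  auto record = [&](double t) {
    double ke = 0.0;
    for (int i = 0; i < nc; ++i) ke += 0.5 * m[i] * v[i] * v[i];
    double ecav = 0.0, efield = 0.0;
    for (int j = 0; j < k; ++j) {
      double me = mu[0]*epol(0,j) + mu[1]*epol(1,j) + mu[2]*epol(2,j);
      double s = q[j] + ck[j] * me;
      ecav   += 0.5 * pc[j]*pc[j] + 0.5 * omega[j]*omega[j]*q[j]*q[j];
      efield += 0.5 * pc[j]*pc[j] + 0.5 * omega[j]*omega[j]*s*s;
    }
    t_rec.push_back(t);
    emol_rec.push_back(ke + V);
    ecav_rec.push_back(ecav);
    efield_rec.push_back(efield);
    roo_rec.push_back(roo());
  };

  forces();
  record(0.0);
  if (roo() >= rcrit) { dissociated = true; t_diss = 0.0; }

  for (int step = 1; step <= nsteps && !(dissociated && stop_at_diss);
       ++step) {
    for (int i = 0; i < nc; ++i) {
      v[i] += 0.5 * dt * fnuc[i] / m[i];
      x[i] += dt * v[i];
    }
    for (int j = 0; j < k; ++j) {
      pc[j] += 0.5 * dt * aq[j];
      q[j]  += dt * pc[j];
    }
    forces();
    for (int i = 0; i < nc; ++i) v[i] += 0.5 * dt * fnuc[i] / m[i];
    for (int j = 0; j < k; ++j) pc[j] += 0.5 * dt * aq[j];
    steps_done = step;
    double t = step * dt;
    if (!dissociated && roo() >= rcrit) {
      dissociated = true;
      t_diss = t;
    }
    if (step % stride == 0 || (dissociated && stop_at_diss) ||
        step == nsteps)
      record(t);
    if (dissociated && stop_at_diss) break;
  }

  return List::create(
    _["time"] = wrap(t_rec), _["E_mol"] = wrap(emol_rec),
    _["E_cav"] = wrap(ecav_rec), _["E_field"] = wrap(efield_rec),
    _["R_OO"] = wrap(roo_rec), _["dissociated"] = dissociated,
    _["t_diss"] = t_diss, _["steps"] = steps_done,
    _["coords"] = wrap(x), _["velocities"] = wrap(v),
    _["q"] = wrap(q), _["p"] = wrap(pc));
}
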