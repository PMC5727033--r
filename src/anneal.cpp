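// Desk-scale restraint-satisfaction engine: Cartesian simulated annealing
// (overdamped Langevin with a cooling schedule) followed by a FIRE quench,
// on a pseudo-energy of covalent-geometry terms, flat-bottom ambiguous
// distance restraints (r^-6 pooled effective distances), flat-bottom
// torsion restraints and a soft CA-CA repulsion.

#include <Rcpp.h>
#include <cmath>
#include <random>
using namespace Rcpp;

struct Vec3 {
  double x, y, z;
  Vec3(double x_ = 0, double y_ = 0, double z_ = 0) : x(x_), y(y_), z(z_) {}
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
  double dot(const Vec3& o) const { return x * o.x + y * o.y + z * o.z; }
  Vec3 cross(const Vec3& o) const {
    return Vec3(y * o.z - z * o.y, z * o.x - x * o.z, x * o.y - y * o.x);
  }
  double norm() const { return std::sqrt(x * x + y * y + z * z); }
};

struct System {
  int n;
  // bonds
  std::vector<int> bi, bj; std::vector<double> br0; double bk;
  // angles
  std::vector<int> ai, aj, ak_; std::vector<double> at0; double ak;
  // dihedral-type terms (omega, impropers, torsion restraints): flat-bottom
  std::vector<int> di, dj, dk_, dl;
  std::vector<double> dc, dw, dkf;
  // distance restraints: options flattened
  std::vector<int> rstart;           // size nrest+1
  std::vector<int> oi, oj;
  std::vector<double> ocorr;         // pseudo-atom distance correction
  std::vector<double> rlo, rup; double rk;
  // nonbonded CA repulsion
  std::vector<int> ca; std::vector<int> ca_res;
  double nb_rmin, nb_k;
};

static inline double wrap_pi(double a) {
  while (a > M_PI) a -= 2 * M_PI;
  while (a < -M_PI) a += 2 * M_PI;
  return a;
}

// energy and gradient; grad accumulated (must be zeroed by caller)
static double energy_grad(const System& S, const std::vector<Vec3>& x,
                          std::vector<Vec3>* grad,
                          double restraint_scale,
                          double* e_restraint_out = nullptr,
                          double geometry_scale = 1.0) {
  double E = 0.0, Er = 0.0;
  const double gs = geometry_scale;
  // bonds
  for (size_t t = 0; t < S.bi.size(); ++t) {
    Vec3 d = x[S.bi[t]] - x[S.bj[t]];
    double r = d.norm(); if (r < 1e-9) r = 1e-9;
    double dr = r - S.br0[t];
    E += gs * S.bk * dr * dr;
    if (grad) {
      Vec3 g = d * (gs * 2.0 * S.bk * dr / r);
      (*grad)[S.bi[t]] = (*grad)[S.bi[t]] + g;
      (*grad)[S.bj[t]] = (*grad)[S.bj[t]] - g;
    }
  }
  // angles
  for (size_t t = 0; t < S.ai.size(); ++t) {
    Vec3 u = x[S.ai[t]] - x[S.aj[t]];
    Vec3 v = x[S.ak_[t]] - x[S.aj[t]];
    double nu = u.norm(), nv = v.norm();
    if (nu < 1e-9 || nv < 1e-9) continue;
    double c = u.dot(v) / (nu * nv);
    c = std::max(-0.999999, std::min(0.999999, c));
    double th = std::acos(c), s = std::sqrt(1.0 - c * c);
    double dth = th - S.at0[t];
    E += gs * S.ak * dth * dth;
    if (grad) {
      double pref = gs * 2.0 * S.ak * dth;
      Vec3 uh = u * (1.0 / nu), vh = v * (1.0 / nv);
      Vec3 gi = (uh * c - vh) * (1.0 / (nu * s));
      Vec3 gk = (vh * c - uh) * (1.0 / (nv * s));
      (*grad)[S.ai[t]] = (*grad)[S.ai[t]] + gi * pref;
      (*grad)[S.ak_[t]] = (*grad)[S.ak_[t]] + gk * pref;
      (*grad)[S.aj[t]] = (*grad)[S.aj[t]] - (gi + gk) * pref;
    }
  }
  // dihedral flat-bottom terms
  for (size_t t = 0; t < S.di.size(); ++t) {
    const Vec3 &p1 = x[S.di[t]], &p2 = x[S.dj[t]], &p3 = x[S.dk_[t]], &p4 = x[S.dl[t]];
    Vec3 b1 = p2 - p1, b2 = p3 - p2, b3 = p4 - p3;
    Vec3 n1 = b1.cross(b2), n2 = b2.cross(b3);
    double nb2 = b2.norm();
    if (nb2 < 1e-9 || n1.norm() < 1e-9 || n2.norm() < 1e-9) continue;
    Vec3 b2h = b2 * (1.0 / nb2);
    double xcomp = n1.dot(n2);
    double ycomp = n1.cross(b2h).dot(n2);
    double phi = std::atan2(ycomp, xcomp);
    double dev = wrap_pi(phi - S.dc[t]);
    double w = S.dw[t];
    double excess = 0.0;
    if (dev > w) excess = dev - w; else if (dev < -w) excess = dev + w;
    if (excess == 0.0) continue;
    E += gs * S.dkf[t] * excess * excess;
    if (grad) {
      double pref = gs * 2.0 * S.dkf[t] * excess;
      double n1sq = n1.dot(n1), n2sq = n2.dot(n2);
      Vec3 F = n1 * (nb2 / n1sq);          // dphi/dp1
      Vec3 G = n2 * (-nb2 / n2sq);         // dphi/dp4
      double c12 = b1.dot(b2) / (nb2 * nb2);
      double c32 = b3.dot(b2) / (nb2 * nb2);
      Vec3 gp2 = F * (-(1.0 + c12)) + G * c32;
      Vec3 gp3 = F * c12 - G * (1.0 + c32);
      (*grad)[S.di[t]] = (*grad)[S.di[t]] + F * pref;
      (*grad)[S.dj[t]] = (*grad)[S.dj[t]] + gp2 * pref;
      (*grad)[S.dk_[t]] = (*grad)[S.dk_[t]] + gp3 * pref;
      (*grad)[S.dl[t]] = (*grad)[S.dl[t]] + G * pref;
    }
  }
  // ambiguous distance restraints (r^-6 pooling, flat-bottom quadratic)
  int nrest = (int)S.rstart.size() - 1;
  for (int r = 0; r < nrest; ++r) {
    int from = S.rstart[r], to = S.rstart[r + 1];
    double sum6 = 0.0;
    double floorr = std::max(0.5, S.rlo[r]);
    for (int t = from; t < to; ++t) {
      Vec3 d = x[S.oi[t]] - x[S.oj[t]];
      double rr = d.norm();
      if (S.ocorr[t] > 0) rr = std::max(rr - S.ocorr[t], floorr);
      if (rr < 1e-6) rr = 1e-6;
      sum6 += std::pow(rr, -6.0);
    }
    if (sum6 <= 0) continue;
    double deff = std::pow(sum6, -1.0 / 6.0);
    double excess = 0.0;
    if (deff > S.rup[r]) excess = deff - S.rup[r];
    else if (deff < S.rlo[r]) excess = deff - S.rlo[r];
    if (excess == 0.0) continue;
    double e1 = restraint_scale * S.rk * excess * excess;
    E += e1; Er += e1;
    if (grad) {
      double dEddeff = 2.0 * restraint_scale * S.rk * excess;
      for (int t = from; t < to; ++t) {
        Vec3 d = x[S.oi[t]] - x[S.oj[t]];
        double rn = d.norm(); if (rn < 1e-6) rn = 1e-6;
        double rr = rn;
        if (S.ocorr[t] > 0) {
          rr = rn - S.ocorr[t];
          if (rr < floorr) continue;   // clamped region: no gradient
        }
        double dd = dEddeff * std::pow(deff / rr, 7.0);
        Vec3 g = d * (dd / rn);
        (*grad)[S.oi[t]] = (*grad)[S.oi[t]] + g;
        (*grad)[S.oj[t]] = (*grad)[S.oj[t]] - g;
      }
    }
  }
  // soft CA-CA repulsion, skipping sequence neighbours
  int nca = (int)S.ca.size();
  for (int a = 0; a < nca; ++a) {
    for (int b = a + 1; b < nca; ++b) {
      if (std::abs(S.ca_res[a] - S.ca_res[b]) < 2) continue;
      Vec3 d = x[S.ca[a]] - x[S.ca[b]];
      double rr = d.norm();
      if (rr >= S.nb_rmin || rr < 1e-9) continue;
      double dr = S.nb_rmin - rr;
      E += gs * S.nb_k * dr * dr;
      if (grad) {
        Vec3 g = d * (gs * -2.0 * S.nb_k * dr / rr);
        (*grad)[S.ca[a]] = (*grad)[S.ca[a]] + g;
        (*grad)[S.ca[b]] = (*grad)[S.ca[b]] - g;
      }
    }
  }
  if (e_restraint_out) *e_restraint_out = Er;
  return E;
}

static System build_system(List sys) {
  System S;
  S.n = as<int>(sys["n_atoms"]);
  IntegerMatrix B = sys["bonds"];
  NumericVector br0 = sys["bond_r0"];
  S.bk = as<double>(sys["bond_k"]);
  for (int i = 0; i < B.nrow(); ++i) {
    S.bi.push_back(B(i, 0)); S.bj.push_back(B(i, 1)); S.br0.push_back(br0[i]);
  }
  IntegerMatrix A = sys["angles"];
  NumericVector at0 = sys["angle_t0"];
  S.ak = as<double>(sys["angle_k"]);
  for (int i = 0; i < A.nrow(); ++i) {
    S.ai.push_back(A(i, 0)); S.aj.push_back(A(i, 1)); S.ak_.push_back(A(i, 2));
    S.at0.push_back(at0[i]);
  }
  IntegerMatrix D = sys["dihedrals"];
  NumericVector dc = sys["dih_center"], dw = sys["dih_halfwidth"], dk = sys["dih_k"];
  for (int i = 0; i < D.nrow(); ++i) {
    S.di.push_back(D(i, 0)); S.dj.push_back(D(i, 1));
    S.dk_.push_back(D(i, 2)); S.dl.push_back(D(i, 3));
    S.dc.push_back(dc[i]); S.dw.push_back(dw[i]); S.dkf.push_back(dk[i]);
  }
  IntegerVector rstart = sys["rest_start"], oi = sys["opt_i"], oj = sys["opt_j"];
  NumericVector rlo = sys["rest_lower"], rup = sys["rest_upper"];
  NumericVector ocorr = sys["opt_corr"];
  S.rk = as<double>(sys["rest_k"]);
  S.rstart = std::vector<int>(rstart.begin(), rstart.end());
  S.oi = std::vector<int>(oi.begin(), oi.end());
  S.oj = std::vector<int>(oj.begin(), oj.end());
  S.ocorr = std::vector<double>(ocorr.begin(), ocorr.end());
  S.rlo = std::vector<double>(rlo.begin(), rlo.end());
  S.rup = std::vector<double>(rup.begin(), rup.end());
  IntegerVector ca = sys["ca_idx"], car = sys["ca_res"];
  S.ca = std::vector<int>(ca.begin(), ca.end());
  S.ca_res = std::vector<int>(car.begin(), car.end());
  S.nb_rmin = as<double>(sys["nb_rmin"]);
  S.nb_k = as<double>(sys["nb_k"]);
  return S;
}

// [[Rcpp::export(name = ".cpp_energy")]]
List cpp_energy(NumericMatrix coords, List sys) {
  System S = build_system(sys);
  std::vector<Vec3> x(S.n);
  for (int i = 0; i < S.n; ++i) x[i] = Vec3(coords(i, 0), coords(i, 1), coords(i, 2));
  double er = 0.0;
  double E = energy_grad(S, x, nullptr, 1.0, &er);
  return List::create(_["total"] = E, _["restraint"] = er,
                      _["geometry"] = E - er);
}

// [[Rcpp::export(name = ".cpp_gradient")]]
NumericMatrix cpp_gradient(NumericMatrix coords, List sys) {
  System S = build_system(sys);
  std::vector<Vec3> x(S.n);
  for (int i = 0; i < S.n; ++i) x[i] = Vec3(coords(i, 0), coords(i, 1), coords(i, 2));
  std::vector<Vec3> g(S.n);
  energy_grad(S, x, &g, 1.0);
  NumericMatrix out(S.n, 3);
  for (int i = 0; i < S.n; ++i) { out(i, 0) = g[i].x; out(i, 1) = g[i].y; out(i, 2) = g[i].z; }
  return out;
}

// FIRE minimiser (Bitzek et al. 2006), fixed iteration budget
static double fire_minimise(const System& S, std::vector<Vec3>& x, int maxit,
                            double dt0, double restraint_scale) {
  int n = S.n;
  std::vector<Vec3> v(n), g(n);
  double dt = dt0, alpha = 0.1;
  int n_pos = 0;
  double E = 0.0;
  for (int it = 0; it < maxit; ++it) {
    for (int i = 0; i < n; ++i) g[i] = Vec3();
    E = energy_grad(S, x, &g, restraint_scale);
    double P = 0.0, vn = 0.0, fn = 0.0;
    for (int i = 0; i < n; ++i) {
      P += -(g[i].dot(v[i]));
      vn += v[i].dot(v[i]); fn += g[i].dot(g[i]);
    }
    vn = std::sqrt(vn); fn = std::sqrt(fn);
    if (fn < 1e-8) break;
    for (int i = 0; i < n; ++i) {
      Vec3 fh = g[i] * (-1.0 / fn);
      v[i] = v[i] * (1 - alpha) + fh * (alpha * vn);
    }
    if (P > 0) {
      if (++n_pos > 5) { dt = std::min(dt * 1.1, 10 * dt0); alpha *= 0.99; }
    } else {
      n_pos = 0; dt *= 0.5; alpha = 0.1;
      for (int i = 0; i < n; ++i) v[i] = Vec3();
    }
    for (int i = 0; i < n; ++i) {
      v[i] = v[i] - g[i] * dt;
      // displacement cap for stability
      double sp = v[i].norm() * dt;
      Vec3 dx = v[i] * dt;
      if (sp > 0.5) dx = dx * (0.5 / sp);
      x[i] = x[i] + dx;
    }
  }
  return E;
}

// [[Rcpp::export(name = ".cpp_anneal")]]
List cpp_anneal(NumericMatrix coords, List sys, List sched, int seed) {
  System S = build_system(sys);
  std::vector<Vec3> x(S.n);
  for (int i = 0; i < S.n; ++i) x[i] = Vec3(coords(i, 0), coords(i, 1), coords(i, 2));

  int n_high = as<int>(sched["n_high"]);
  int n_cool = as<int>(sched["n_cool"]);
  int n_quench = as<int>(sched["n_quench"]);
  double T_high = as<double>(sched["temp_high"]);
  double dt = as<double>(sched["dt"]);
  double fcap = as<double>(sched["force_cap"]);
  double gs0 = as<double>(sched["geom_soft"]);
  double dt_hot = as<double>(sched["dt_hot"]);

  std::mt19937_64 rng(seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  std::vector<Vec3> g(S.n);

  int total = n_high + n_cool;
  for (int it = 0; it < total; ++it) {
    double frac = (it < n_high) ? 0.0 : double(it - n_high) / double(n_cool);
    double T = T_high * (1.0 - frac);
    // restraints act at full strength throughout; covalent geometry is
    // soft while hot (lets the topology form) and hardens while cooling
    double gs = (it < n_high) ? gs0 : std::min(1.0, gs0 + (1.0 - gs0) * frac / 0.4);
    double step = (it < n_high) ? dt_hot : dt;
    for (int i = 0; i < S.n; ++i) g[i] = Vec3();
    energy_grad(S, x, &g, 1.0, nullptr, gs);
    double noise = std::sqrt(2.0 * step * T);
    for (int i = 0; i < S.n; ++i) {
      double gn = g[i].norm();
      if (gn > fcap) g[i] = g[i] * (fcap / gn);
      x[i] = x[i] - g[i] * step +
        Vec3(gauss(rng), gauss(rng), gauss(rng)) * noise;
    }
  }
  double E = fire_minimise(S, x, n_quench, dt, 1.0);
  if (!std::isfinite(E)) stop("annealing diverged (non-finite energy), seed %d", seed);

  NumericMatrix out(S.n, 3);
  for (int i = 0; i < S.n; ++i) { out(i, 0) = x[i].x; out(i, 1) = x[i].y; out(i, 2) = x[i].z; }
  double er = 0.0;
  double Efin = energy_grad(S, x, nullptr, 1.0, &er);
  return List::create(_["coords"] = out, _["energy"] = Efin,
                      _["restraint_energy"] = er);
}
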