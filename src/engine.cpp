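// Coarse-grained potential evaluation and BAOAB Langevin sampling.
//
// A "term set" is an R list of plain matrices/vectors describing one
// Hamiltonian (see compile_termset() on the R side).  The sampler can mix
// two term sets sharing one coordinate array, F = wA*F_A + wB*F_B, which is
// what the alchemical transformation needs; per-sample energies of both
// sets are recorded so <dV/dlambda> can be formed afterwards.
//
// Units: kcal/mol, Angstrom, ps, amu.  KCAL converts kcal/mol/A per amu to
// A/ps^2 (4184 J/mol / (1e-3 kg/mol) scaled to A, ps).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double KCAL = 418.4;             // amu A^2/ps^2 per kcal/mol
static const double KB = 1.987204e-3;         // kcal/mol/K
static const double E_BLOWUP = 1e6;           // kcal/mol instability cap

struct TermSet {
  int n;
  NumericMatrix bonds;        // i j k r0
  NumericMatrix angles;       // i j l k theta0   (j = apex)
  NumericMatrix pairs;        // i j A sigma      capped soft repulsion
  NumericMatrix prest;        // i k r0 px py pz  point distance restraint
  NumericMatrix drest;        // i j k r0         pair distance restraint
  NumericMatrix arest;        // i axis k x0      single-axis restraint
  NumericMatrix walls;        // cx cy cz radius A
  NumericVector wall_scale;   // per bead
  NumericVector radii;        // per bead
  NumericVector anchor;       // active px py pz depth width
  NumericVector anchor_q;     // per bead
  NumericVector slab;         // active half_width k_conf eps_solv
  NumericVector slab_mask;    // per bead
  NumericMatrix dwell;        // i h a c tilt     quartic double well on x
};

static TermSet parse_termset(const List& ts) {
  TermSet t;
  t.n = as<int>(ts["n"]);
  t.bonds = as<NumericMatrix>(ts["bonds"]);
  t.angles = as<NumericMatrix>(ts["angles"]);
  t.pairs = as<NumericMatrix>(ts["pairs"]);
  t.prest = as<NumericMatrix>(ts["point_restraints"]);
  t.drest = as<NumericMatrix>(ts["dist_restraints"]);
  t.arest = as<NumericMatrix>(ts["axis_restraints"]);
  t.walls = as<NumericMatrix>(ts["walls"]);
  t.wall_scale = as<NumericVector>(ts["wall_scale"]);
  t.radii = as<NumericVector>(ts["radii"]);
  t.anchor = as<NumericVector>(ts["anchor"]);
  t.anchor_q = as<NumericVector>(ts["anchor_q"]);
  t.slab = as<NumericVector>(ts["slab"]);
  t.slab_mask = as<NumericVector>(ts["slab_mask"]);
  t.dwell = as<NumericMatrix>(ts["dwell"]);
  return t;
}

// Accumulate energy (returned) and w-scaled forces into F (may be NULL).
// comp: optional 8-slot component accumulator
// (bond, angle, pair, wall, anchor, slab, restraint, external).
static double eval_terms(const TermSet& t, const double* x, double* F,
                         double w, double* comp) {
  const int n = t.n;
  double E = 0.0;
  double Ec[8] = {0, 0, 0, 0, 0, 0, 0, 0};

  // bonds
  for (int b = 0; b < t.bonds.nrow(); ++b) {
    int i = (int)t.bonds(b, 0), j = (int)t.bonds(b, 1);
    double k = t.bonds(b, 2), r0 = t.bonds(b, 3);
    double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1],
           dz = x[3 * i + 2] - x[3 * j + 2];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double d = r - r0;
    Ec[0] += 0.5 * k * d * d;
    if (F && r > 1e-12) {
      double f = -w * k * d / r;
      F[3 * i] += f * dx; F[3 * i + 1] += f * dy; F[3 * i + 2] += f * dz;
      F[3 * j] -= f * dx; F[3 * j + 1] -= f * dy; F[3 * j + 2] -= f * dz;
    }
  }

  // angles (apex j)
  for (int a = 0; a < t.angles.nrow(); ++a) {
    int i = (int)t.angles(a, 0), j = (int)t.angles(a, 1),
        l = (int)t.angles(a, 2);
    double k = t.angles(a, 3), th0 = t.angles(a, 4);
    double ux = x[3 * i] - x[3 * j], uy = x[3 * i + 1] - x[3 * j + 1],
           uz = x[3 * i + 2] - x[3 * j + 2];
    double vx = x[3 * l] - x[3 * j], vy = x[3 * l + 1] - x[3 * j + 1],
           vz = x[3 * l + 2] - x[3 * j + 2];
    double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
    double nv = std::sqrt(vx * vx + vy * vy + vz * vz);
    if (nu < 1e-12 || nv < 1e-12) continue;
    double c = (ux * vx + uy * vy + uz * vz) / (nu * nv);
    if (c > 1.0) c = 1.0; if (c < -1.0) c = -1.0;
    double th = std::acos(c);
    double d = th - th0;
    Ec[1] += 0.5 * k * d * d;
    double s = std::sqrt(1.0 - c * c);
    if (F && s > 1e-8) {
      double dUdth = k * d;
      // dtheta/dxi = (c*u_hat - v_hat) / (nu * s) etc.
      double uhx = ux / nu, uhy = uy / nu, uhz = uz / nu;
      double vhx = vx / nv, vhy = vy / nv, vhz = vz / nv;
      double gix = (c * uhx - vhx) / (nu * s),
             giy = (c * uhy - vhy) / (nu * s),
             giz = (c * uhz - vhz) / (nu * s);
      double glx = (c * vhx - uhx) / (nv * s),
             gly = (c * vhy - uhy) / (nv * s),
             glz = (c * vhz - uhz) / (nv * s);
      F[3 * i] -= w * dUdth * gix; F[3 * i + 1] -= w * dUdth * giy;
      F[3 * i + 2] -= w * dUdth * giz;
      F[3 * l] -= w * dUdth * glx; F[3 * l + 1] -= w * dUdth * gly;
      F[3 * l + 2] -= w * dUdth * glz;
      F[3 * j] += w * dUdth * (gix + glx);
      F[3 * j + 1] += w * dUdth * (giy + gly);
      F[3 * j + 2] += w * dUdth * (giz + glz);
    }
  }

  // capped soft-sphere pairs: U = A (1 - (r/sigma)^2)^2, r < sigma
  for (int p = 0; p < t.pairs.nrow(); ++p) {
    int i = (int)t.pairs(p, 0), j = (int)t.pairs(p, 1);
    double A = t.pairs(p, 2), sig = t.pairs(p, 3);
    double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1],
           dz = x[3 * i + 2] - x[3 * j + 2];
    double r2 = dx * dx + dy * dy + dz * dz, s2 = sig * sig;
    if (r2 >= s2) continue;
    double q = 1.0 - r2 / s2;
    Ec[2] += A * q * q;
    if (F) {
      double f = w * 4.0 * A * q / s2;  // -dU/dr / r
      F[3 * i] += f * dx; F[3 * i + 1] += f * dy; F[3 * i + 2] += f * dz;
      F[3 * j] -= f * dx; F[3 * j + 1] -= f * dy; F[3 * j + 2] -= f * dz;
    }
  }

  // wall spheres (external): same capped form, sigma = radius + bead radius
  for (int wl = 0; wl < t.walls.nrow(); ++wl) {
    double cx = t.walls(wl, 0), cy = t.walls(wl, 1), cz = t.walls(wl, 2);
    double rad = t.walls(wl, 3), A = t.walls(wl, 4);
    for (int i = 0; i < n; ++i) {
      double sc = t.wall_scale[i];
      if (sc == 0.0) continue;
      double sig = rad + t.radii[i], s2 = sig * sig;
      double dx = x[3 * i] - cx, dy = x[3 * i + 1] - cy, dz = x[3 * i + 2] - cz;
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= s2) continue;
      double q = 1.0 - r2 / s2;
      Ec[3] += sc * A * q * q;
      if (F) {
        double f = w * sc * 4.0 * A * q / s2;
        F[3 * i] += f * dx; F[3 * i + 1] += f * dy; F[3 * i + 2] += f * dz;
      }
    }
  }

  // anchor well (external): U = -depth * q_i * exp(-r^2 / (2 width^2))
  if (t.anchor[0] != 0.0) {
    double px = t.anchor[1], py = t.anchor[2], pz = t.anchor[3];
    double D = t.anchor[4], wdt = t.anchor[5];
    double w2 = wdt * wdt;
    for (int i = 0; i < n; ++i) {
      double qi = t.anchor_q[i];
      if (qi == 0.0) continue;
      double dx = x[3 * i] - px, dy = x[3 * i + 1] - py, dz = x[3 * i + 2] - pz;
      double r2 = dx * dx + dy * dy + dz * dz;
      double e = std::exp(-r2 / (2.0 * w2));
      Ec[4] += -D * qi * e;
      if (F) {
        double f = -w * D * qi * e / w2;  // F = -dU/dx
        F[3 * i] += f * dx; F[3 * i + 1] += f * dy; F[3 * i + 2] += f * dz;
      }
    }
  }

  // slab (external): flat-bottom confinement on |z| plus smooth solvation well
  if (t.slab[0] != 0.0) {
    double hw = t.slab[1], kc = t.slab[2], eps = t.slab[3];
    for (int i = 0; i < n; ++i) {
      if (t.slab_mask[i] == 0.0) continue;
      double z = x[3 * i + 2];
      double az = std::fabs(z);
      if (az > hw) {
        double d = az - hw;
        Ec[5] += 0.5 * kc * d * d;
        if (F) F[3 * i + 2] -= w * kc * d * (z > 0 ? 1.0 : -1.0);
      }
      if (eps != 0.0) {
        double tz = z / hw, t6 = tz * tz * tz; t6 *= t6;
        double den = 1.0 + t6;
        Ec[5] += -eps / den;
        if (F) {
          double t5 = tz * tz; t5 = t5 * t5 * tz;
          F[3 * i + 2] -= w * eps * 6.0 * t5 / (hw * den * den);
        }
      }
    }
  }

  // point distance restraints
  for (int p = 0; p < t.prest.nrow(); ++p) {
    int i = (int)t.prest(p, 0);
    double k = t.prest(p, 1), r0 = t.prest(p, 2);
    double dx = x[3 * i] - t.prest(p, 3), dy = x[3 * i + 1] - t.prest(p, 4),
           dz = x[3 * i + 2] - t.prest(p, 5);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double d = r - r0;
    Ec[6] += 0.5 * k * d * d;
    if (F) {
      if (r0 == 0.0) {  // harmonic in displacement, no singularity
        F[3 * i] -= w * k * dx; F[3 * i + 1] -= w * k * dy;
        F[3 * i + 2] -= w * k * dz;
      } else if (r > 1e-12) {
        double f = -w * k * d / r;
        F[3 * i] += f * dx; F[3 * i + 1] += f * dy; F[3 * i + 2] += f * dz;
      }
    }
  }

  // pair distance restraints
  for (int p = 0; p < t.drest.nrow(); ++p) {
    int i = (int)t.drest(p, 0), j = (int)t.drest(p, 1);
    double k = t.drest(p, 2), r0 = t.drest(p, 3);
    double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1],
           dz = x[3 * i + 2] - x[3 * j + 2];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double d = r - r0;
    Ec[6] += 0.5 * k * d * d;
    if (F && r > 1e-12) {
      double f = -w * k * d / r;
      F[3 * i] += f * dx; F[3 * i + 1] += f * dy; F[3 * i + 2] += f * dz;
      F[3 * j] -= f * dx; F[3 * j + 1] -= f * dy; F[3 * j + 2] -= f * dz;
    }
  }

  // single-axis restraints
  for (int p = 0; p < t.arest.nrow(); ++p) {
    int i = (int)t.arest(p, 0), ax = (int)t.arest(p, 1);
    double k = t.arest(p, 2), x0 = t.arest(p, 3);
    double d = x[3 * i + ax] - x0;
    Ec[6] += 0.5 * k * d * d;
    if (F) F[3 * i + ax] -= w * k * d;
  }

  // double-well fixture term on the |x| distance coordinate: a capped
  // barrier bump of height h and half-width a centred at |x| = c, plus a
  // linear tilt in (|x| - c); symmetric in x so the fold of the distance
  // coordinate leaves the landscape unchanged
  for (int p = 0; p < t.dwell.nrow(); ++p) {
    int i = (int)t.dwell(p, 0);
    double h = t.dwell(p, 1), a = t.dwell(p, 2), c = t.dwell(p, 3),
           tilt = t.dwell(p, 4);
    double r = std::fabs(x[3 * i]);
    double u = (r - c) / a;
    double dUdr = tilt;
    double Eterm = tilt * (r - c);
    if (std::fabs(u) < 1.0) {
      double q = 1.0 - u * u;
      Eterm += h * q * q;
      dUdr += -4.0 * h * u * q / a;
    }
    Ec[7] += Eterm;
    if (F) F[3 * i] -= w * dUdr * (x[3 * i] >= 0 ? 1.0 : -1.0);
  }

  for (int c = 0; c < 8; ++c) E += Ec[c];
  if (comp) for (int c = 0; c < 8; ++c) comp[c] += Ec[c];
  return E;
}

// [[Rcpp::export]]
List cpp_energy(List ts, NumericMatrix coords) {
  TermSet t = parse_termset(ts);
  if (coords.nrow() != t.n) stop("coordinate/bead count mismatch");
  for (int i = 0; i < coords.length(); ++i)
    if (!R_finite(coords[i])) stop("invalid input: non-finite coordinates");
  std::vector<double> x(3 * t.n);
  for (int i = 0; i < t.n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = coords(i, d);
  double comp[8] = {0, 0, 0, 0, 0, 0, 0, 0};
  double E = eval_terms(t, x.data(), nullptr, 1.0, comp);
  NumericVector cv = NumericVector::create(
      _["bond"] = comp[0], _["angle"] = comp[1], _["pair"] = comp[2],
      _["wall"] = comp[3], _["anchor"] = comp[4], _["slab"] = comp[5],
      _["restraint"] = comp[6], _["external"] = comp[7]);
  return List::create(_["total"] = E, _["components"] = cv);
}

// [[Rcpp::export]]
NumericMatrix cpp_forces(List ts, NumericMatrix coords) {
  TermSet t = parse_termset(ts);
  if (coords.nrow() != t.n) stop("coordinate/bead count mismatch");
  for (int i = 0; i < coords.length(); ++i)
    if (!R_finite(coords[i])) stop("invalid input: non-finite coordinates");
  std::vector<double> x(3 * t.n), F(3 * t.n, 0.0);
  for (int i = 0; i < t.n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = coords(i, d);
  eval_terms(t, x.data(), F.data(), 1.0, nullptr);
  NumericMatrix out(t.n, 3);
  for (int i = 0; i < t.n; ++i)
    for (int d = 0; d < 3; ++d) out(i, d) = F[3 * i + d];
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_init_velocities(NumericVector masses, double temperature) {
  int n = masses.size();
  NumericMatrix v(n, 3);
  double kT = KB * temperature * KCAL;
  for (int i = 0; i < n; ++i) {
    double s = std::sqrt(kT / masses[i]);
    for (int d = 0; d < 3; ++d) v(i, d) = s * norm_rand();
  }
  // remove net linear momentum
  double M = 0.0, P[3] = {0, 0, 0};
  for (int i = 0; i < n; ++i) {
    M += masses[i];
    for (int d = 0; d < 3; ++d) P[d] += masses[i] * v(i, d);
  }
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) v(i, d) -= P[d] / M;
  return v;
}

static void shake_positions(const NumericMatrix& cons,
                            const NumericVector& masses, double* x) {
  const double tol = 1e-6;
  for (int iter = 0; iter < 200; ++iter) {
    bool ok = true;
    for (int c = 0; c < cons.nrow(); ++c) {
      int i = (int)cons(c, 0), j = (int)cons(c, 1);
      double d0 = cons(c, 2);
      double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1],
             dz = x[3 * i + 2] - x[3 * j + 2];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      double diff = r - d0;
      if (std::fabs(diff) > tol) {
        ok = false;
        double wi = masses[j] / (masses[i] + masses[j]);
        double wj = masses[i] / (masses[i] + masses[j]);
        double ux = dx / r, uy = dy / r, uz = dz / r;
        x[3 * i] -= diff * wi * ux; x[3 * i + 1] -= diff * wi * uy;
        x[3 * i + 2] -= diff * wi * uz;
        x[3 * j] += diff * wj * ux; x[3 * j + 1] += diff * wj * uy;
        x[3 * j + 2] += diff * wj * uz;
      }
    }
    if (ok) break;
  }
}

static void rattle_velocities(const NumericMatrix& cons,
                              const NumericVector& masses, const double* x,
                              double* v) {
  for (int c = 0; c < cons.nrow(); ++c) {
    int i = (int)cons(c, 0), j = (int)cons(c, 1);
    double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1],
           dz = x[3 * i + 2] - x[3 * j + 2];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-12) continue;
    double ux = dx / r, uy = dy / r, uz = dz / r;
    double vr = (v[3 * i] - v[3 * j]) * ux + (v[3 * i + 1] - v[3 * j + 1]) * uy +
                (v[3 * i + 2] - v[3 * j + 2]) * uz;
    double wi = masses[j] / (masses[i] + masses[j]);
    double wj = masses[i] / (masses[i] + masses[j]);
    v[3 * i] -= vr * wi * ux; v[3 * i + 1] -= vr * wi * uy;
    v[3 * i + 2] -= vr * wi * uz;
    v[3 * j] += vr * wj * ux; v[3 * j + 1] += vr * wj * uy;
    v[3 * j + 2] += vr * wj * uz;
  }
}

// BAOAB Langevin sampler over one term set or a weighted mix of two.
// obs rows: (type, i, j_or_axis, px, py, pz); type 0 = pair distance,
// 1 = distance to point, 2 = axis coordinate of bead i.
// [[Rcpp::export]]
List cpp_run_langevin(List tsA_, Nullable<List> tsB_, double wA, double wB,
                      NumericMatrix coords0, NumericVector masses, double dt,
                      double gamma, double temperature, int n_steps,
                      int n_equil, int stride, NumericMatrix constraints,
                      NumericMatrix obs, bool record_frames,
                      Nullable<NumericMatrix> velocities0) {
  TermSet tA = parse_termset(tsA_);
  bool dual = tsB_.isNotNull();
  TermSet tB;
  if (dual) tB = parse_termset(as<List>(tsB_));
  const int n = tA.n;
  if (coords0.nrow() != n) stop("coordinate/bead count mismatch");
  for (int i = 0; i < coords0.length(); ++i)
    if (!R_finite(coords0[i])) stop("invalid input: non-finite coordinates");

  std::vector<double> x(3 * n), v(3 * n), F(3 * n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = coords0(i, d);

  if (velocities0.isNotNull()) {
    NumericMatrix v0 = as<NumericMatrix>(velocities0);
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) v[3 * i + d] = v0(i, d);
  } else {
    NumericMatrix v0 = cpp_init_velocities(masses, temperature);
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) v[3 * i + d] = v0(i, d);
  }

  const double kT = KB * temperature * KCAL;
  const double c1 = std::exp(-gamma * dt);
  const double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1));
  const bool has_cons = constraints.nrow() > 0;

  int n_samples = (n_steps - n_equil) / stride;
  if (n_samples < 0) n_samples = 0;
  NumericVector eA(n_samples), eB(dual ? n_samples : 0), ekin(n_samples);
  NumericMatrix obs_out(n_samples, obs.nrow());
  NumericVector frames;
  if (record_frames) frames = NumericVector(Dimension(n_samples, n, 3));

  // initial forces
  std::fill(F.begin(), F.end(), 0.0);
  eval_terms(tA, x.data(), F.data(), wA, nullptr);
  if (dual) eval_terms(tB, x.data(), F.data(), wB, nullptr);

  int si = 0;
  for (int step = 1; step <= n_steps; ++step) {
    // B
    for (int i = 0; i < n; ++i) {
      double a = 0.5 * dt * KCAL / masses[i];
      v[3 * i] += a * F[3 * i]; v[3 * i + 1] += a * F[3 * i + 1];
      v[3 * i + 2] += a * F[3 * i + 2];
    }
    // A
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
    // O
    if (gamma > 0.0) {
      for (int i = 0; i < n; ++i) {
        double s = c2 * std::sqrt(kT / masses[i]);
        v[3 * i] = c1 * v[3 * i] + s * norm_rand();
        v[3 * i + 1] = c1 * v[3 * i + 1] + s * norm_rand();
        v[3 * i + 2] = c1 * v[3 * i + 2] + s * norm_rand();
      }
    }
    // A
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
    if (has_cons) shake_positions(constraints, masses, x.data());
    // B with new forces
    std::fill(F.begin(), F.end(), 0.0);
    eval_terms(tA, x.data(), F.data(), wA, nullptr);
    if (dual) eval_terms(tB, x.data(), F.data(), wB, nullptr);
    for (int i = 0; i < n; ++i) {
      double a = 0.5 * dt * KCAL / masses[i];
      v[3 * i] += a * F[3 * i]; v[3 * i + 1] += a * F[3 * i + 1];
      v[3 * i + 2] += a * F[3 * i + 2];
    }
    if (has_cons) rattle_velocities(constraints, masses, x.data(), v.data());

    if (step > n_equil && (step - n_equil) % stride == 0 && si < n_samples) {
      double EA = eval_terms(tA, x.data(), nullptr, 1.0, nullptr);
      if (!R_finite(EA) || std::fabs(EA) > E_BLOWUP)
        stop("instability: potential energy exceeded 1e6 kcal/mol; use a smaller timestep");
      eA[si] = EA;
      if (dual) {
        double EB = eval_terms(tB, x.data(), nullptr, 1.0, nullptr);
        if (!R_finite(EB) || std::fabs(EB) > E_BLOWUP)
          stop("instability: potential energy exceeded 1e6 kcal/mol; use a smaller timestep");
        eB[si] = EB;
      }
      double K = 0.0;
      for (int i = 0; i < n; ++i)
        K += 0.5 * masses[i] * (v[3 * i] * v[3 * i] + v[3 * i + 1] * v[3 * i + 1] +
                                v[3 * i + 2] * v[3 * i + 2]);
      ekin[si] = K / KCAL;
      for (int o = 0; o < obs.nrow(); ++o) {
        int type = (int)obs(o, 0), i = (int)obs(o, 1);
        if (type == 0) {
          int j = (int)obs(o, 2);
          double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1],
                 dz = x[3 * i + 2] - x[3 * j + 2];
          obs_out(si, o) = std::sqrt(dx * dx + dy * dy + dz * dz);
        } else if (type == 1) {
          double dx = x[3 * i] - obs(o, 3), dy = x[3 * i + 1] - obs(o, 4),
                 dz = x[3 * i + 2] - obs(o, 5);
          obs_out(si, o) = std::sqrt(dx * dx + dy * dy + dz * dz);
        } else {
          obs_out(si, o) = x[3 * i + (int)obs(o, 2)];
        }
      }
      if (record_frames)
        for (int i = 0; i < n; ++i)
          for (int d = 0; d < 3; ++d)
            frames[si + n_samples * (i + n * d)] = x[3 * i + d];
      ++si;
    }
  }

  NumericMatrix xf(n, 3), vf(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      xf(i, d) = x[3 * i + d];
      vf(i, d) = v[3 * i + d];
    }
  List out = List::create(
      _["energy_A"] = eA, _["energy_B"] = eB, _["kinetic"] = ekin,
      _["obs"] = obs_out, _["final_coords"] = xf, _["final_velocities"] = vf);
  if (record_frames) out["frames"] = frames;
  return out;
}
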