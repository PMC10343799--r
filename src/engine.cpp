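// Reduced-model steered MD engine: velocity-Verlet integration of harmonic
// bonds and angles restrained to the template geometry, a soft short-range
// pairwise repulsion to prevent overlap, external Hooke "scaffold" springs
// (atom-atom or atom-to-fixed-anchor), and a collisional thermostat (random
// elastic collisions with virtual particles of mass m0, Maxwell-distributed
// at the target temperature, per-atom Poisson rate lambda).
//
// All randomness is counter-based: each variate is a pure hash of
// (seed, step counter, atom, substream), so trajectories are bitwise
// reproducible, stages can continue a stream via step_offset, and a mirrored
// run can replay the identical collision sequence with the x impulse
// component negated (mirror_impulses) to test parity equivariance.
//
// Internal units: A, a.m.u., ps; energies in a.m.u. A^2/ps^2.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline uint64_t sm64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline uint64_t ctr_hash(uint64_t seed, uint64_t step, uint64_t atom,
                                uint64_t sub) {
  uint64_t x = sm64(seed ^ 0x6C62272E07BB0142ULL);
  x = sm64(x ^ (step * 0xA0761D6478BD642FULL));
  x = sm64(x ^ (atom * 0xE7037ED1A0B428DBULL));
  x = sm64(x ^ (sub * 0x8EBC6AF09C88C6E3ULL));
  return x;
}

// uniform in (0, 1]
static inline double u01(uint64_t h) {
  return ((h >> 11) + 1.0) * (1.0 / 9007199254740992.0);
}

static inline double norm1(uint64_t seed, uint64_t step, uint64_t atom,
                           uint64_t sub, double *second) {
  double u1 = u01(ctr_hash(seed, step, atom, sub));
  double u2 = u01(ctr_hash(seed, step, atom, sub + 1));
  double r = std::sqrt(-2.0 * std::log(u1));
  *second = r * std::sin(2.0 * M_PI * u2);
  return r * std::cos(2.0 * M_PI * u2);
}

struct Forces {
  std::vector<double> fx, fy, fz;
  double pe;
  void reset(int n) {
    fx.assign(n, 0.0); fy.assign(n, 0.0); fz.assign(n, 0.0); pe = 0.0;
  }
};

static inline uint64_t pair_key(int i, int j) {
  if (i > j) std::swap(i, j);
  return (uint64_t)i << 32 | (uint64_t)j;
}

class Engine {
public:
  int n;
  std::vector<double> x, y, z, vx, vy, vz, mass;
  // bonds
  std::vector<int> ba, bb;
  std::vector<double> bk, br0;
  // angles (a - b - c, vertex b)
  std::vector<int> aa, ab, ac;
  std::vector<double> ak, ath0;
  // springs: atom-atom (sb >= 0) or atom-anchor (sb < 0)
  std::vector<int> sa, sb;
  std::vector<double> sk, sr0, anx, any_, anz;
  std::vector<char> fixed;
  std::vector<uint64_t> excl; // sorted pair keys excluded from repulsion
  double rep_eps, rep_cut;

  bool excluded(int i, int j) const {
    return std::binary_search(excl.begin(), excl.end(), pair_key(i, j));
  }

  void bonded_forces(Forces &F) {
    for (size_t b = 0; b < ba.size(); ++b) {
      int i = ba[b], j = bb[b];
      double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < 1e-12) continue;
      double d = r - br0[b];
      F.pe += 0.5 * bk[b] * d * d;
      double c = bk[b] * d / r;
      F.fx[i] += c * dx; F.fy[i] += c * dy; F.fz[i] += c * dz;
      F.fx[j] -= c * dx; F.fy[j] -= c * dy; F.fz[j] -= c * dz;
    }
    for (size_t t = 0; t < aa.size(); ++t) {
      int i = aa[t], j = ab[t], k = ac[t];
      double r1x = x[i] - x[j], r1y = y[i] - y[j], r1z = z[i] - z[j];
      double r2x = x[k] - x[j], r2y = y[k] - y[j], r2z = z[k] - z[j];
      double n1 = std::sqrt(r1x * r1x + r1y * r1y + r1z * r1z);
      double n2 = std::sqrt(r2x * r2x + r2y * r2y + r2z * r2z);
      if (n1 < 1e-12 || n2 < 1e-12) continue;
      double cth = (r1x * r2x + r1y * r2y + r1z * r2z) / (n1 * n2);
      cth = std::max(-1.0, std::min(1.0, cth));
      double th = std::acos(cth);
      double d = th - ath0[t];
      F.pe += 0.5 * ak[t] * d * d;
      double sth = std::sqrt(1.0 - cth * cth);
      if (sth < 1e-8) continue; // force vanishes smoothly near 0/pi
      // F_i = -k (theta - theta0) dtheta/dr_i and dtheta/dr = -g/sin(theta)
      // with g = d(cos theta)/dr, so the coefficient on g is +k d / sin.
      double coef = ak[t] * d / sth;
      double gix = (r2x / (n1 * n2) - cth * r1x / (n1 * n1));
      double giy = (r2y / (n1 * n2) - cth * r1y / (n1 * n1));
      double giz = (r2z / (n1 * n2) - cth * r1z / (n1 * n1));
      double gkx = (r1x / (n1 * n2) - cth * r2x / (n2 * n2));
      double gky = (r1y / (n1 * n2) - cth * r2y / (n2 * n2));
      double gkz = (r1z / (n1 * n2) - cth * r2z / (n2 * n2));
      F.fx[i] += coef * gix; F.fy[i] += coef * giy; F.fz[i] += coef * giz;
      F.fx[k] += coef * gkx; F.fy[k] += coef * gky; F.fz[k] += coef * gkz;
      F.fx[j] -= coef * (gix + gkx);
      F.fy[j] -= coef * (giy + gky);
      F.fz[j] -= coef * (giz + gkz);
    }
  }

  void spring_forces(Forces &F, double scale) {
    if (scale <= 0.0) return;
    for (size_t s = 0; s < sa.size(); ++s) {
      int i = sa[s];
      double px, py, pz;
      if (sb[s] >= 0) { px = x[sb[s]]; py = y[sb[s]]; pz = z[sb[s]]; }
      else { px = anx[s]; py = any_[s]; pz = anz[s]; }
      double dx = px - x[i], dy = py - y[i], dz = pz - z[i];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < 1e-12) continue;
      double kk = sk[s] * scale;
      double d = r - sr0[s];
      F.pe += 0.5 * kk * d * d;
      double c = kk * d / r;
      F.fx[i] += c * dx; F.fy[i] += c * dy; F.fz[i] += c * dz;
      if (sb[s] >= 0) {
        F.fx[sb[s]] -= c * dx; F.fy[sb[s]] -= c * dy; F.fz[sb[s]] -= c * dz;
      }
    }
  }

  // candidate pair buffer: sorted before accumulation so the floating-point
  // summation order is independent of the cell traversal (this is what makes
  // a mirrored run the bitwise mirror of the original)
  std::vector<uint64_t> pair_buf;

  void repulsion_forces(Forces &F) {
    if (rep_eps <= 0.0) return;
    double rc = rep_cut, rc2 = rc * rc;
    pair_buf.clear();
    double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0],
           zmin = z[0], zmax = z[0];
    for (int i = 1; i < n; ++i) {
      xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
      ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
      zmin = std::min(zmin, z[i]); zmax = std::max(zmax, z[i]);
    }
    int ncx = std::max(1, (int)((xmax - xmin) / rc) + 1);
    int ncy = std::max(1, (int)((ymax - ymin) / rc) + 1);
    int ncz = std::max(1, (int)((zmax - zmin) / rc) + 1);
    if ((double)ncx * ncy * ncz > 4e6) { // pathological spread: O(n^2) fallback
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) buf_pair(i, j, rc2);
      flush_pairs(F, rc2, rc);
      return;
    }
    std::vector<int> head((size_t)ncx * ncy * ncz, -1), nxt(n);
    std::vector<int> cix(n), ciy(n), ciz(n);
    for (int i = 0; i < n; ++i) {
      int cx = std::min(ncx - 1, (int)((x[i] - xmin) / rc));
      int cy = std::min(ncy - 1, (int)((y[i] - ymin) / rc));
      int cz = std::min(ncz - 1, (int)((z[i] - zmin) / rc));
      cix[i] = cx; ciy[i] = cy; ciz[i] = cz;
      size_t c = ((size_t)cz * ncy + cy) * ncx + cx;
      nxt[i] = head[c]; head[c] = i;
    }
    for (int i = 0; i < n; ++i) {
      for (int dz_ = -1; dz_ <= 1; ++dz_) {
        int cz = ciz[i] + dz_; if (cz < 0 || cz >= ncz) continue;
        for (int dy_ = -1; dy_ <= 1; ++dy_) {
          int cy = ciy[i] + dy_; if (cy < 0 || cy >= ncy) continue;
          for (int dx_ = -1; dx_ <= 1; ++dx_) {
            int cx = cix[i] + dx_; if (cx < 0 || cx >= ncx) continue;
            int j = head[((size_t)cz * ncy + cy) * ncx + cx];
            for (; j >= 0; j = nxt[j])
              if (j > i) buf_pair(i, j, rc2);
          }
        }
      }
    }
    flush_pairs(F, rc2, rc);
  }

  void buf_pair(int i, int j, double rc2) {
    double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= rc2 || r2 < 1e-20) return;
    if (excluded(i, j)) return;
    pair_buf.push_back(pair_key(i, j));
  }

  void flush_pairs(Forces &F, double rc2, double rc) {
    std::sort(pair_buf.begin(), pair_buf.end());
    for (uint64_t key : pair_buf)
      rep_pair(F, (int)(key >> 32), (int)(key & 0xFFFFFFFFULL), rc2, rc);
  }

  void rep_pair(Forces &F, int i, int j, double rc2, double rc) {
    double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
    double r2 = dx * dx + dy * dy + dz * dz;
    double r = std::sqrt(r2);
    double q = 1.0 - r / rc;
    F.pe += rep_eps * q * q;
    double c = 2.0 * rep_eps * q / (rc * r); // repulsive, pushes apart
    F.fx[i] -= c * dx; F.fy[i] -= c * dy; F.fz[i] -= c * dz;
    F.fx[j] += c * dx; F.fy[j] += c * dy; F.fz[j] += c * dz;
  }

  void all_forces(Forces &F, double spring_scale) {
    F.reset(n);
    bonded_forces(F);
    spring_forces(F, spring_scale);
    repulsion_forces(F);
    for (int i = 0; i < n; ++i)
      if (fixed[i]) { F.fx[i] = 0; F.fy[i] = 0; F.fz[i] = 0; }
  }

  double kinetic() const {
    double ke = 0.0;
    for (int i = 0; i < n; ++i)
      ke += 0.5 * mass[i] * (vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
    return ke;
  }
};

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(NumericMatrix coords, NumericMatrix vel, NumericVector mass,
                IntegerMatrix bonds, NumericVector bond_k,
                NumericVector bond_r0,
                IntegerMatrix angles, NumericVector angle_k,
                NumericVector angle_theta0,
                IntegerMatrix springs, NumericVector spring_k,
                NumericVector spring_r0, NumericMatrix anchors,
                double spring_scale,
                double rep_eps, double rep_cutoff,
                double lambda, double m0, double temperature,
                bool thermostat_on,
                double dt, IntegerVector fixed_atoms, int nsteps,
                double seed, double step_offset, bool mirror_impulses,
                int save_every) {
  const double kB = 0.831446262;
  Engine E;
  E.n = coords.nrow();
  E.x.resize(E.n); E.y.resize(E.n); E.z.resize(E.n);
  E.vx.resize(E.n); E.vy.resize(E.n); E.vz.resize(E.n);
  E.mass.resize(E.n);
  for (int i = 0; i < E.n; ++i) {
    E.x[i] = coords(i, 0); E.y[i] = coords(i, 1); E.z[i] = coords(i, 2);
    E.vx[i] = vel(i, 0); E.vy[i] = vel(i, 1); E.vz[i] = vel(i, 2);
    E.mass[i] = mass[i];
  }
  for (int b = 0; b < bonds.nrow(); ++b) {
    E.ba.push_back(bonds(b, 0) - 1); E.bb.push_back(bonds(b, 1) - 1);
    E.bk.push_back(bond_k[b]); E.br0.push_back(bond_r0[b]);
  }
  for (int t = 0; t < angles.nrow(); ++t) {
    E.aa.push_back(angles(t, 0) - 1); E.ab.push_back(angles(t, 1) - 1);
    E.ac.push_back(angles(t, 2) - 1);
    E.ak.push_back(angle_k[t]); E.ath0.push_back(angle_theta0[t]);
  }
  for (int s = 0; s < springs.nrow(); ++s) {
    E.sa.push_back(springs(s, 0) - 1);
    E.sb.push_back(springs(s, 1) - 1); // 0 in R (anchor) becomes -1
    E.sk.push_back(spring_k[s]); E.sr0.push_back(spring_r0[s]);
    E.anx.push_back(anchors(s, 0)); E.any_.push_back(anchors(s, 1));
    E.anz.push_back(anchors(s, 2));
  }
  E.fixed.assign(E.n, 0);
  for (int i = 0; i < fixed_atoms.size(); ++i)
    E.fixed[fixed_atoms[i] - 1] = 1;
  for (int i = 0; i < E.n; ++i)
    if (E.fixed[i]) { E.vx[i] = 0; E.vy[i] = 0; E.vz[i] = 0; }
  E.rep_eps = rep_eps; E.rep_cut = rep_cutoff;
  // repulsion exclusions: 1-2 and 1-3 pairs
  for (size_t b = 0; b < E.ba.size(); ++b)
    E.excl.push_back(pair_key(E.ba[b], E.bb[b]));
  for (size_t t = 0; t < E.aa.size(); ++t)
    E.excl.push_back(pair_key(E.aa[t], E.ac[t]));
  std::sort(E.excl.begin(), E.excl.end());
  E.excl.erase(std::unique(E.excl.begin(), E.excl.end()), E.excl.end());

  uint64_t useed = (uint64_t)(int64_t)seed;
  uint64_t ustep0 = (uint64_t)(int64_t)step_offset;
  double pcoll = 1.0 - std::exp(-lambda * dt);
  double sigma = std::sqrt(kB * temperature / m0);

  Forces F;
  E.all_forces(F, spring_scale);

  std::vector<NumericMatrix> frames;
  std::vector<double> times, pes, kes;
  auto snapshot = [&](int step) {
    NumericMatrix m(E.n, 3);
    for (int i = 0; i < E.n; ++i) {
      m(i, 0) = E.x[i]; m(i, 1) = E.y[i]; m(i, 2) = E.z[i];
    }
    frames.push_back(m);
    times.push_back(step * dt);
    pes.push_back(F.pe);
    kes.push_back(E.kinetic());
  };

  for (int step = 0; step < nsteps; ++step) {
    for (int i = 0; i < E.n; ++i) {
      if (E.fixed[i]) continue;
      double h = 0.5 * dt / E.mass[i];
      E.vx[i] += h * F.fx[i]; E.vy[i] += h * F.fy[i]; E.vz[i] += h * F.fz[i];
      E.x[i] += dt * E.vx[i]; E.y[i] += dt * E.vy[i]; E.z[i] += dt * E.vz[i];
    }
    E.all_forces(F, spring_scale);
    for (int i = 0; i < E.n; ++i) {
      if (E.fixed[i]) continue;
      double h = 0.5 * dt / E.mass[i];
      E.vx[i] += h * F.fx[i]; E.vy[i] += h * F.fy[i]; E.vz[i] += h * F.fz[i];
    }
    if (thermostat_on && lambda > 0) {
      uint64_t sc = ustep0 + (uint64_t)step;
      for (int i = 0; i < E.n; ++i) {
        if (E.fixed[i]) continue;
        if (u01(ctr_hash(useed, sc, (uint64_t)i, 0)) < pcoll) {
          double g2, g4;
          double g1 = norm1(useed, sc, (uint64_t)i, 1, &g2);
          double g3 = norm1(useed, sc, (uint64_t)i, 3, &g4);
          double ux = sigma * g1, uy = sigma * g2, uz = sigma * g3;
          if (mirror_impulses) ux = -ux;
          double m = E.mass[i];
          double A = (m - m0) / (m + m0), B = 2.0 * m0 / (m + m0);
          E.vx[i] = A * E.vx[i] + B * ux;
          E.vy[i] = A * E.vy[i] + B * uy;
          E.vz[i] = A * E.vz[i] + B * uz;
        }
      }
    }
    if ((step & 0x3F) == 0) {
      for (int i = 0; i < E.n; ++i)
        if (!std::isfinite(E.x[i]) || !std::isfinite(E.y[i]) ||
            !std::isfinite(E.z[i])) {
          double fmax = 0;
          for (int j2 = 0; j2 < E.n; ++j2)
            fmax = std::max(fmax, std::abs(F.fx[j2]));
          stop("simulation blew up at step %d (non-finite coordinate, "
               "max |F| = %g)", step + 1, fmax);
        }
      Rcpp::checkUserInterrupt();
    }
    if (save_every > 0 && ((step + 1) % save_every == 0))
      snapshot(step + 1);
  }
  if (save_every <= 0 || nsteps % save_every != 0 || nsteps == 0)
    snapshot(nsteps);

  NumericMatrix xyz(E.n, 3), vout(E.n, 3);
  for (int i = 0; i < E.n; ++i) {
    xyz(i, 0) = E.x[i]; xyz(i, 1) = E.y[i]; xyz(i, 2) = E.z[i];
    vout(i, 0) = E.vx[i]; vout(i, 1) = E.vy[i]; vout(i, 2) = E.vz[i];
  }
  return List::create(_["coords"] = xyz, _["velocities"] = vout,
                      _["frames"] = wrap(frames), _["times"] = wrap(times),
                      _["potential"] = wrap(pes), _["kinetic"] = wrap(kes),
                      _["steps"] = nsteps);
}
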