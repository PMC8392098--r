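// Core DPD force loop and integrator.
//
// Reduced units throughout: r_c = 1, k_B T = 1, bead mass m = 1 (unless
// overridden), tau the derived time unit.  Pair noise is counter-based
// (seed, evaluation counter, ordered pair) so alpha_ij == alpha_ji holds by
// construction and trajectories are bit-reproducible for a given seed
// independent of pair iteration order.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <unordered_set>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// counter-based RNG (splitmix64 mixing + Box-Muller)

static inline uint64_t sm64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline double u01(uint64_t h) {
  // 53-bit mantissa uniform in [0, 1)
  return (double)(h >> 11) * (1.0 / 9007199254740992.0);
}

static inline double pair_gauss(uint64_t seed, uint64_t ctr,
                                uint32_t i, uint32_t j) {
  if (i > j) { uint32_t t = i; i = j; j = t; }
  uint64_t s = sm64(seed ^ 0x5851F42D4C957F2DULL);
  s = sm64(s ^ ctr);
  s = sm64(s ^ (((uint64_t)i << 32) | (uint64_t)j));
  uint64_t h1 = sm64(s);
  uint64_t h2 = sm64(h1 ^ 0xA0761D6478BD642FULL);
  double u1 = u01(h1);
  double u2 = u01(h2);
  if (u1 < 1e-300) u1 = 1e-300;
  return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
}

// [[Rcpp::export]]
NumericVector sample_pair_noise_cpp(int seed, int n, int i, int j) {
  NumericVector out(n);
  for (int k = 0; k < n; ++k)
    out[k] = pair_gauss((uint64_t)seed, (uint64_t)k, (uint32_t)i, (uint32_t)j);
  return out;
}

// ---------------------------------------------------------------------------
// geometry helpers

struct Box {
  double L[3];
  bool per[3];
};

static inline double minimg(double d, double L, bool per) {
  if (!per) return d;
  if (d >  0.5 * L) d -= L * std::floor(d / L + 0.5);
  else if (d < -0.5 * L) d -= L * std::floor(d / L + 0.5);
  return d;
}

static inline void pair_sep(const Box& box,
                            double xi, double yi, double zi,
                            double xj, double yj, double zj,
                            double* d) {
  d[0] = minimg(xi - xj, box.L[0], box.per[0]);
  d[1] = minimg(yi - yj, box.L[1], box.per[1]);
  d[2] = minimg(zi - zj, box.L[2], box.per[2]);
}

// ---------------------------------------------------------------------------
// simulation scratch state

struct Sim {
  int N;
  std::vector<double> x, y, z;     // positions
  std::vector<double> vx, vy, vz;  // velocities
  std::vector<double> fx, fy, fz;  // force accumulator
  std::vector<int> species;        // 0 water, 1 eg, 2 rbc
  std::vector<int> role;           // 0 free, 1 tethered, 2 driven
  std::vector<double> mass;
  Box box;

  // pair parameters
  double a[3][3];
  double beta, kBT, dt, sigma;
  bool noise;
  bool exclude12;
  std::unordered_set<uint64_t> bonded;

  // walls
  bool wall_on;
  double a_wall;

  // body force on water beads
  double gx, gy, gz;

  // topology
  std::vector<int> b_i, b_j;
  std::vector<double> b_ks, b_b0;
  std::vector<int> an_i, an_j, an_k;
  std::vector<double> an_kE, an_phi0;

  // recording of pair (non-bonded) forces on selected beads.  Only the
  // conservative + dissipative terms are streamed: the random term has
  // exactly zero mean and would dominate the variance of any time average.
  std::vector<int> rec_slot;       // -1 or slot index
  int n_rec;
  std::vector<double> rec_w;       // from-water pair force, 3 * n_rec
  std::vector<double> rec_all;     // total pair force, 3 * n_rec
  std::vector<double> rec_w_acc, rec_all_acc;  // running per-step sums
  long rec_count;

  // diagnostics
  double e_bond, e_bend;
  long degenerate_pairs;

  // cell list scratch
  std::vector<int> head, nxt;
};

static inline uint64_t bkey(int i, int j) {
  if (i > j) std::swap(i, j);
  return ((uint64_t)i << 32) | (uint64_t)j;
}

// shift (sx, sy, sz) is the periodic image translation applied to bead j
static inline void add_pair_force(Sim& S, int i, int j, uint64_t seed,
                                  uint64_t ctr,
                                  double sx, double sy, double sz) {
  double d0 = S.x[i] - S.x[j] - sx;
  double d1 = S.y[i] - S.y[j] - sy;
  double d2 = S.z[i] - S.z[j] - sz;
  double r2 = d0 * d0 + d1 * d1 + d2 * d2;
  if (r2 >= 1.0) return;
  if (S.exclude12 && S.bonded.count(bkey(i, j))) return;
  double d[3] = {d0, d1, d2};
  if (r2 < 1e-24) { S.degenerate_pairs++; return; }
  double r = std::sqrt(r2);
  double w = 1.0 - r;
  double ex = d[0] / r, ey = d[1] / r, ez = d[2] / r;
  double aij = S.a[S.species[i]][S.species[j]];
  double dvx = S.vx[i] - S.vx[j];
  double dvy = S.vy[i] - S.vy[j];
  double dvz = S.vz[i] - S.vz[j];
  double ev = ex * dvx + ey * dvy + ez * dvz;
  double fcd = aij * w - S.beta * w * w * ev;   // conservative + dissipative
  double fmag = fcd;
  if (S.noise) {
    double alpha = pair_gauss(seed, ctr, (uint32_t)i, (uint32_t)j);
    fmag += S.sigma * w * alpha;
  }
  double fxp = fmag * ex, fyp = fmag * ey, fzp = fmag * ez;
  S.fx[i] += fxp; S.fy[i] += fyp; S.fz[i] += fzp;
  S.fx[j] -= fxp; S.fy[j] -= fyp; S.fz[j] -= fzp;
  if (S.n_rec) {
    double cx = fcd * ex, cy = fcd * ey, cz = fcd * ez;
    int si = S.rec_slot[i], sj = S.rec_slot[j];
    if (si >= 0) {
      S.rec_all[3 * si] += cx; S.rec_all[3 * si + 1] += cy;
      S.rec_all[3 * si + 2] += cz;
      if (S.species[j] == 0) {
        S.rec_w[3 * si] += cx; S.rec_w[3 * si + 1] += cy;
        S.rec_w[3 * si + 2] += cz;
      }
    }
    if (sj >= 0) {
      S.rec_all[3 * sj] -= cx; S.rec_all[3 * sj + 1] -= cy;
      S.rec_all[3 * sj + 2] -= cz;
      if (S.species[i] == 0) {
        S.rec_w[3 * sj] -= cx; S.rec_w[3 * sj + 1] -= cy;
        S.rec_w[3 * sj + 2] -= cz;
      }
    }
  }
}

// all pair forces via cell list (falls back to O(N^2) for small boxes)
static void pair_forces(Sim& S, uint64_t seed, uint64_t ctr) {
  const int N = S.N;
  int nc[3];
  bool small = false;
  for (int k = 0; k < 3; ++k) {
    nc[k] = (int)std::floor(S.box.L[k]);
    if (nc[k] < 1) nc[k] = 1;
    if (S.box.per[k] && nc[k] < 3) small = true;
  }
  if (small || (long)nc[0] * nc[1] * nc[2] < 8 || N < 64) {
    for (int i = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j) {
        double d[3];
        pair_sep(S.box, S.x[i], S.y[i], S.z[i], S.x[j], S.y[j], S.z[j], d);
        add_pair_force(S, i, j, seed, ctr,
                       S.x[i] - S.x[j] - d[0],
                       S.y[i] - S.y[j] - d[1],
                       S.z[i] - S.z[j] - d[2]);
      }
    return;
  }
  const int ncell = nc[0] * nc[1] * nc[2];
  S.head.assign(ncell, -1);
  S.nxt.resize(N);
  const double iwx = nc[0] / S.box.L[0];
  const double iwy = nc[1] / S.box.L[1];
  const double iwz = nc[2] / S.box.L[2];
  for (int i = 0; i < N; ++i) {
    int a = (int)(S.x[i] * iwx);
    int b = (int)(S.y[i] * iwy);
    int c = (int)(S.z[i] * iwz);
    if (a < 0) a = 0;
    if (a >= nc[0]) a = nc[0] - 1;
    if (b < 0) b = 0;
    if (b >= nc[1]) b = nc[1] - 1;
    if (c < 0) c = 0;
    if (c >= nc[2]) c = nc[2] - 1;
    int cell = (a * nc[1] + b) * nc[2] + c;
    S.nxt[i] = S.head[cell];
    S.head[cell] = i;
  }
  // half neighbor stencil (13 offsets) + same cell; periodic wrapping is
  // folded into a per-offset image shift applied to bead j
  static const int off[13][3] = {
    {1,0,0}, {0,1,0}, {0,0,1}, {1,1,0}, {1,-1,0}, {1,0,1}, {1,0,-1},
    {0,1,1}, {0,1,-1}, {1,1,1}, {1,1,-1}, {1,-1,1}, {1,-1,-1}
  };
  for (int a = 0; a < nc[0]; ++a)
    for (int b = 0; b < nc[1]; ++b)
      for (int c = 0; c < nc[2]; ++c) {
        int cell = (a * nc[1] + b) * nc[2] + c;
        if (S.head[cell] < 0) continue;
        // same cell, i<j
        for (int i = S.head[cell]; i >= 0; i = S.nxt[i])
          for (int j = S.nxt[i]; j >= 0; j = S.nxt[j])
            add_pair_force(S, i, j, seed, ctr, 0.0, 0.0, 0.0);
        for (int o = 0; o < 13; ++o) {
          int aa = a + off[o][0], bb = b + off[o][1], cc = c + off[o][2];
          double sx = 0.0, sy = 0.0, sz = 0.0;
          if (aa < 0) { if (!S.box.per[0]) continue; aa += nc[0]; sx = -S.box.L[0]; }
          else if (aa >= nc[0]) { if (!S.box.per[0]) continue; aa -= nc[0]; sx = S.box.L[0]; }
          if (bb < 0) { if (!S.box.per[1]) continue; bb += nc[1]; sy = -S.box.L[1]; }
          else if (bb >= nc[1]) { if (!S.box.per[1]) continue; bb -= nc[1]; sy = S.box.L[1]; }
          if (cc < 0) { if (!S.box.per[2]) continue; cc += nc[2]; sz = -S.box.L[2]; }
          else if (cc >= nc[2]) { if (!S.box.per[2]) continue; cc -= nc[2]; sz = S.box.L[2]; }
          int cell2 = (aa * nc[1] + bb) * nc[2] + cc;
          if (S.head[cell2] < 0) continue;
          for (int i = S.head[cell]; i >= 0; i = S.nxt[i])
            for (int j = S.head[cell2]; j >= 0; j = S.nxt[j])
              add_pair_force(S, i, j, seed, ctr, sx, sy, sz);
        }
      }
}

static void bond_forces(Sim& S) {
  const int nb = (int)S.b_i.size();
  for (int b = 0; b < nb; ++b) {
    int i = S.b_i[b], j = S.b_j[b];
    double d[3];
    pair_sep(S.box, S.x[i], S.y[i], S.z[i], S.x[j], S.y[j], S.z[j], d);
    double r = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
    if (r < 1e-12) { S.degenerate_pairs++; continue; }
    double ks = S.b_ks[b], b0 = S.b_b0[b];
    double dr = r - b0;
    S.e_bond += ks * dr * dr;             // E = k_s (r - b0)^2, no 1/2
    double fmag = -2.0 * ks * dr / r;     // on i along +d restores b0
    S.fx[i] += fmag * d[0]; S.fy[i] += fmag * d[1]; S.fz[i] += fmag * d[2];
    S.fx[j] -= fmag * d[0]; S.fy[j] -= fmag * d[1]; S.fz[j] -= fmag * d[2];
  }
}

static void angle_forces(Sim& S) {
  const int na = (int)S.an_i.size();
  for (int t = 0; t < na; ++t) {
    int i = S.an_i[t], j = S.an_j[t], k = S.an_k[t]; // j is the center
    double u[3], v[3];
    pair_sep(S.box, S.x[i], S.y[i], S.z[i], S.x[j], S.y[j], S.z[j], u);
    pair_sep(S.box, S.x[k], S.y[k], S.z[k], S.x[j], S.y[j], S.z[j], v);
    double ru = std::sqrt(u[0]*u[0] + u[1]*u[1] + u[2]*u[2]);
    double rv = std::sqrt(v[0]*v[0] + v[1]*v[1] + v[2]*v[2]);
    if (ru < 1e-12 || rv < 1e-12) { S.degenerate_pairs++; continue; }
    double cphi = (u[0]*v[0] + u[1]*v[1] + u[2]*v[2]) / (ru * rv);
    if (cphi > 1.0) cphi = 1.0;
    if (cphi < -1.0) cphi = -1.0;
    double phi = std::acos(cphi);
    double kE = S.an_kE[t], phi0 = S.an_phi0[t];
    double dphi = phi - phi0;
    S.e_bend += 0.5 * kE * dphi * dphi;   // E = 1/2 k_E (phi - phi0)^2
    double s = std::sin(phi);
    if (s < 1e-8) s = 1e-8;               // dphi -> 0 in step; limit finite
    double coef = kE * dphi / s;          // F = coef * d(cos phi)/d r
    // d(cos phi)/d r_i and /d r_k
    double gix = (v[0] / (ru * rv)) - cphi * u[0] / (ru * ru);
    double giy = (v[1] / (ru * rv)) - cphi * u[1] / (ru * ru);
    double giz = (v[2] / (ru * rv)) - cphi * u[2] / (ru * ru);
    double gkx = (u[0] / (ru * rv)) - cphi * v[0] / (rv * rv);
    double gky = (u[1] / (ru * rv)) - cphi * v[1] / (rv * rv);
    double gkz = (u[2] / (ru * rv)) - cphi * v[2] / (rv * rv);
    double fix = coef * gix, fiy = coef * giy, fiz = coef * giz;
    double fkx = coef * gkx, fky = coef * gky, fkz = coef * gkz;
    S.fx[i] += fix; S.fy[i] += fiy; S.fz[i] += fiz;
    S.fx[k] += fkx; S.fy[k] += fky; S.fz[k] += fkz;
    S.fx[j] -= fix + fkx; S.fy[j] -= fiy + fky; S.fz[j] -= fiz + fkz;
  }
}

static void wall_forces_(Sim& S) {
  if (!S.wall_on) return;
  const double Ly = S.box.L[1];
  for (int i = 0; i < S.N; ++i) {
    double yi = S.y[i];
    if (yi < 1.0) {
      double w = 1.0 - yi;
      if (w > 1.0) w = 1.0;               // clamped beyond the plane
      S.fy[i] += S.a_wall * w;
    } else if (yi > Ly - 1.0) {
      double w = 1.0 - (Ly - yi);
      if (w > 1.0) w = 1.0;
      S.fy[i] -= S.a_wall * w;
    }
  }
}

static void body_force_(Sim& S) {
  if (S.gx == 0.0 && S.gy == 0.0 && S.gz == 0.0) return;
  for (int i = 0; i < S.N; ++i)
    if (S.species[i] == 0 && S.role[i] == 0) {
      S.fx[i] += S.gx; S.fy[i] += S.gy; S.fz[i] += S.gz;
    }
}

static void eval_forces(Sim& S, uint64_t seed, uint64_t ctr) {
  std::fill(S.fx.begin(), S.fx.end(), 0.0);
  std::fill(S.fy.begin(), S.fy.end(), 0.0);
  std::fill(S.fz.begin(), S.fz.end(), 0.0);
  if (S.n_rec) {
    std::fill(S.rec_w.begin(), S.rec_w.end(), 0.0);
    std::fill(S.rec_all.begin(), S.rec_all.end(), 0.0);
  }
  S.e_bond = 0.0; S.e_bend = 0.0;
  pair_forces(S, seed, ctr);
  bond_forces(S);
  angle_forces(S);
  wall_forces_(S);
  body_force_(S);
}

// ---------------------------------------------------------------------------
// construction from R arguments

static Sim make_sim(const NumericMatrix& pos, const NumericMatrix& vel,
                    const IntegerVector& species, const IntegerVector& role,
                    const NumericVector& mass,
                    const NumericVector& boxL, const LogicalVector& periodic,
                    const NumericMatrix& aMat, double beta, double kBT,
                    double dt, bool noise, bool exclude12,
                    bool wall_on, double a_wall,
                    const NumericVector& body_force,
                    const IntegerMatrix& bonds, const NumericVector& bond_ks,
                    const NumericVector& bond_b0,
                    const IntegerMatrix& angles, const NumericVector& angle_kE,
                    const NumericVector& angle_phi0,
                    const IntegerVector& record_ids) {
  Sim S;
  S.N = pos.nrow();
  S.x.resize(S.N); S.y.resize(S.N); S.z.resize(S.N);
  S.vx.resize(S.N); S.vy.resize(S.N); S.vz.resize(S.N);
  S.fx.resize(S.N); S.fy.resize(S.N); S.fz.resize(S.N);
  S.species.resize(S.N); S.role.resize(S.N); S.mass.resize(S.N);
  for (int i = 0; i < S.N; ++i) {
    S.x[i] = pos(i, 0); S.y[i] = pos(i, 1); S.z[i] = pos(i, 2);
    S.vx[i] = vel(i, 0); S.vy[i] = vel(i, 1); S.vz[i] = vel(i, 2);
    S.species[i] = species[i]; S.role[i] = role[i];
    S.mass[i] = (mass.size() == 1) ? mass[0] : mass[i];
  }
  for (int k = 0; k < 3; ++k) { S.box.L[k] = boxL[k]; S.box.per[k] = periodic[k]; }
  for (int p = 0; p < 3; ++p)
    for (int q = 0; q < 3; ++q)
      S.a[p][q] = aMat(p, q);
  S.beta = beta; S.kBT = kBT; S.dt = dt;
  S.sigma = std::sqrt(2.0 * beta * kBT / dt);
  S.noise = noise;
  S.exclude12 = exclude12;
  S.wall_on = wall_on; S.a_wall = a_wall;
  S.gx = body_force[0]; S.gy = body_force[1]; S.gz = body_force[2];
  int nb = bonds.nrow();
  S.b_i.resize(nb); S.b_j.resize(nb); S.b_ks.resize(nb); S.b_b0.resize(nb);
  for (int b = 0; b < nb; ++b) {
    S.b_i[b] = bonds(b, 0); S.b_j[b] = bonds(b, 1);
    S.b_ks[b] = (bond_ks.size() == 1) ? bond_ks[0] : bond_ks[b];
    S.b_b0[b] = (bond_b0.size() == 1) ? bond_b0[0] : bond_b0[b];
    if (exclude12) S.bonded.insert(bkey(S.b_i[b], S.b_j[b]));
  }
  int na = angles.nrow();
  S.an_i.resize(na); S.an_j.resize(na); S.an_k.resize(na);
  S.an_kE.resize(na); S.an_phi0.resize(na);
  for (int t = 0; t < na; ++t) {
    S.an_i[t] = angles(t, 0); S.an_j[t] = angles(t, 1); S.an_k[t] = angles(t, 2);
    S.an_kE[t] = (angle_kE.size() == 1) ? angle_kE[0] : angle_kE[t];
    S.an_phi0[t] = (angle_phi0.size() == 1) ? angle_phi0[0] : angle_phi0[t];
  }
  S.n_rec = record_ids.size();
  S.rec_slot.assign(S.N, -1);
  for (int s = 0; s < S.n_rec; ++s) S.rec_slot[record_ids[s]] = s;
  S.rec_w.assign(3 * S.n_rec, 0.0);
  S.rec_all.assign(3 * S.n_rec, 0.0);
  S.rec_w_acc.assign(3 * S.n_rec, 0.0);
  S.rec_all_acc.assign(3 * S.n_rec, 0.0);
  S.rec_count = 0;
  S.e_bond = 0.0; S.e_bend = 0.0;
  S.degenerate_pairs = 0;
  return S;
}

// single force evaluation, decomposed, for unit tests and diagnostics
// [[Rcpp::export]]
List dpd_forces_cpp(NumericMatrix pos, NumericMatrix vel,
                    IntegerVector species, IntegerVector role,
                    NumericVector mass,
                    NumericVector boxL, LogicalVector periodic,
                    NumericMatrix aMat, double beta, double kBT, double dt,
                    bool noise, bool exclude12, bool wall_on, double a_wall,
                    NumericVector body_force,
                    IntegerMatrix bonds, NumericVector bond_ks,
                    NumericVector bond_b0,
                    IntegerMatrix angles, NumericVector angle_kE,
                    NumericVector angle_phi0,
                    int seed, double step) {
  IntegerVector rec(0);
  Sim S = make_sim(pos, vel, species, role, mass, boxL, periodic, aMat, beta,
                   kBT, dt, noise, exclude12, wall_on, a_wall, body_force,
                   bonds, bond_ks, bond_b0, angles, angle_kE, angle_phi0, rec);
  const int N = S.N;
  NumericMatrix fpair(N, 3), fbond(N, 3), fangle(N, 3), fwall(N, 3), ftot(N, 3);

  std::fill(S.fx.begin(), S.fx.end(), 0.0);
  std::fill(S.fy.begin(), S.fy.end(), 0.0);
  std::fill(S.fz.begin(), S.fz.end(), 0.0);
  pair_forces(S, (uint64_t)seed, (uint64_t)step);
  for (int i = 0; i < N; ++i) {
    fpair(i,0) = S.fx[i]; fpair(i,1) = S.fy[i]; fpair(i,2) = S.fz[i];
  }
  std::fill(S.fx.begin(), S.fx.end(), 0.0);
  std::fill(S.fy.begin(), S.fy.end(), 0.0);
  std::fill(S.fz.begin(), S.fz.end(), 0.0);
  S.e_bond = 0.0;
  bond_forces(S);
  for (int i = 0; i < N; ++i) {
    fbond(i,0) = S.fx[i]; fbond(i,1) = S.fy[i]; fbond(i,2) = S.fz[i];
  }
  std::fill(S.fx.begin(), S.fx.end(), 0.0);
  std::fill(S.fy.begin(), S.fy.end(), 0.0);
  std::fill(S.fz.begin(), S.fz.end(), 0.0);
  S.e_bend = 0.0;
  angle_forces(S);
  for (int i = 0; i < N; ++i) {
    fangle(i,0) = S.fx[i]; fangle(i,1) = S.fy[i]; fangle(i,2) = S.fz[i];
  }
  std::fill(S.fx.begin(), S.fx.end(), 0.0);
  std::fill(S.fy.begin(), S.fy.end(), 0.0);
  std::fill(S.fz.begin(), S.fz.end(), 0.0);
  wall_forces_(S);
  for (int i = 0; i < N; ++i) {
    fwall(i,0) = S.fx[i]; fwall(i,1) = S.fy[i]; fwall(i,2) = S.fz[i];
  }
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k)
      ftot(i, k) = fpair(i, k) + fbond(i, k) + fangle(i, k) + fwall(i, k);

  return List::create(_["force"] = ftot, _["pair"] = fpair,
                      _["bond"] = fbond, _["angle"] = fangle,
                      _["wall"] = fwall, _["e_bond"] = S.e_bond,
                      _["e_bend"] = S.e_bend,
                      _["degenerate_pairs"] = (double)S.degenerate_pairs);
}

// ---------------------------------------------------------------------------
// Groot-Warren modified velocity-Verlet driver

// [[Rcpp::export]]
List dpd_run_cpp(NumericMatrix pos, NumericMatrix vel,
                 IntegerVector species, IntegerVector role,
                 NumericMatrix drive,            // N x 3 prescribed velocity
                 NumericVector mass,
                 NumericVector boxL, LogicalVector periodic,
                 NumericMatrix aMat, double beta, double kBT, double dt,
                 double lambda,
                 bool noise, bool exclude12, bool wall_on, double a_wall,
                 NumericVector body_force,
                 IntegerMatrix bonds, NumericVector bond_ks,
                 NumericVector bond_b0,
                 IntegerMatrix angles, NumericVector angle_kE,
                 NumericVector angle_phi0,
                 int nsteps, double step0, int seed,
                 int frame_every, int sample_every,
                 IntegerVector record_ids, int record_every,
                 Nullable<NumericMatrix> f_init,
                 IntegerMatrix obs_bonds, IntegerMatrix obs_angles,
                 int obs_every) {
  Sim S = make_sim(pos, vel, species, role, mass, boxL, periodic, aMat, beta,
                   kBT, dt, noise, exclude12, wall_on, a_wall, body_force,
                   bonds, bond_ks, bond_b0, angles, angle_kE, angle_phi0,
                   record_ids);
  const int N = S.N;
  const double Lx = S.box.L[0], Ly = S.box.L[1], Lz = S.box.L[2];

  // pin driven velocities to the prescribed value
  for (int i = 0; i < N; ++i) {
    if (S.role[i] == 2) {
      S.vx[i] = drive(i, 0); S.vy[i] = drive(i, 1); S.vz[i] = drive(i, 2);
    } else if (S.role[i] == 1) {
      S.vx[i] = 0.0; S.vy[i] = 0.0; S.vz[i] = 0.0;
    }
  }

  uint64_t sd = (uint64_t)seed;
  if (f_init.isNotNull()) {
    NumericMatrix f0(f_init);
    std::fill(S.fx.begin(), S.fx.end(), 0.0);
    std::fill(S.fy.begin(), S.fy.end(), 0.0);
    std::fill(S.fz.begin(), S.fz.end(), 0.0);
    for (int i = 0; i < N; ++i) {
      S.fx[i] = f0(i, 0); S.fy[i] = f0(i, 1); S.fz[i] = f0(i, 2);
    }
  } else {
    eval_forces(S, sd, (uint64_t)step0);
  }

  int n_frames = frame_every > 0 ? nsteps / frame_every : 0;
  List frames(n_frames);
  NumericVector frame_time(n_frames);
  int n_samp = sample_every > 0 ? nsteps / sample_every : 0;
  NumericVector temp(n_samp), temp_time(n_samp);
  int n_obs = obs_every > 0 ? nsteps / obs_every : 0;
  NumericMatrix obs_r(n_obs, obs_bonds.nrow());
  NumericMatrix obs_phi(n_obs, obs_angles.nrow());
  NumericVector obs_time(n_obs);
  int oi = 0;
  int n_recs = (record_every > 0 && S.n_rec > 0) ? nsteps / record_every : 0;
  NumericMatrix rec_w_out(n_recs, 3 * S.n_rec);
  NumericMatrix rec_all_out(n_recs, 3 * S.n_rec);
  NumericVector rec_time(n_recs);
  int fi = 0, si = 0, ri = 0;
  long reflections = 0;

  std::vector<double> ofx(N), ofy(N), ofz(N), svx(N), svy(N), svz(N);

  for (int s = 0; s < nsteps; ++s) {
    uint64_t ctr = (uint64_t)(step0 + s + 1);
    // position update + velocity prediction
    for (int i = 0; i < N; ++i) {
      if (S.role[i] == 0) {
        double im = 1.0 / S.mass[i];
        S.x[i] += dt * S.vx[i] + 0.5 * dt * dt * S.fx[i] * im;
        S.y[i] += dt * S.vy[i] + 0.5 * dt * dt * S.fy[i] * im;
        S.z[i] += dt * S.vz[i] + 0.5 * dt * dt * S.fz[i] * im;
        svx[i] = S.vx[i]; svy[i] = S.vy[i]; svz[i] = S.vz[i];
        S.vx[i] += lambda * dt * S.fx[i] * im;   // predicted velocity
        S.vy[i] += lambda * dt * S.fy[i] * im;
        S.vz[i] += lambda * dt * S.fz[i] * im;
      } else if (S.role[i] == 2) {
        S.x[i] += dt * drive(i, 0);
        S.y[i] += dt * drive(i, 1);
        S.z[i] += dt * drive(i, 2);
        svx[i] = S.vx[i]; svy[i] = S.vy[i]; svz[i] = S.vz[i];
      } else {
        svx[i] = 0.0; svy[i] = 0.0; svz[i] = 0.0;
      }
      // wrap periodic axes
      if (S.box.per[0]) { S.x[i] -= Lx * std::floor(S.x[i] / Lx); }
      if (S.box.per[2]) { S.z[i] -= Lz * std::floor(S.z[i] / Lz); }
      if (S.box.per[1]) { S.y[i] -= Ly * std::floor(S.y[i] / Ly); }
      else if (S.role[i] == 0) {
        // reflective backstop behind the soft walls
        if (S.y[i] < 0.0) { S.y[i] = -S.y[i]; S.vy[i] = -S.vy[i]; svy[i] = -svy[i]; reflections++; }
        if (S.y[i] > Ly)  { S.y[i] = 2.0 * Ly - S.y[i]; S.vy[i] = -S.vy[i]; svy[i] = -svy[i]; reflections++; }
      }
    }
    // forces at new positions with predicted velocities
    for (int i = 0; i < N; ++i) { ofx[i] = S.fx[i]; ofy[i] = S.fy[i]; ofz[i] = S.fz[i]; }
    eval_forces(S, sd, ctr);
    if (S.n_rec) {
      for (int k = 0; k < 3 * S.n_rec; ++k) {
        S.rec_w_acc[k] += S.rec_w[k];
        S.rec_all_acc[k] += S.rec_all[k];
      }
      S.rec_count++;
    }
    // velocity correction
    for (int i = 0; i < N; ++i) {
      if (S.role[i] == 0) {
        double im = 1.0 / S.mass[i];
        S.vx[i] = svx[i] + 0.5 * dt * (ofx[i] + S.fx[i]) * im;
        S.vy[i] = svy[i] + 0.5 * dt * (ofy[i] + S.fy[i]) * im;
        S.vz[i] = svz[i] + 0.5 * dt * (ofz[i] + S.fz[i]) * im;
      }
    }
    // sampling
    if (sample_every > 0 && (s + 1) % sample_every == 0) {
      double ke = 0.0; long nf = 0;
      for (int i = 0; i < N; ++i)
        if (S.role[i] == 0) {
          ke += S.mass[i] * (S.vx[i]*S.vx[i] + S.vy[i]*S.vy[i] + S.vz[i]*S.vz[i]);
          nf++;
        }
      temp[si] = nf > 0 ? ke / (3.0 * nf) : NA_REAL;
      temp_time[si] = (step0 + s + 1) * dt;
      si++;
    }
    if (record_every > 0 && S.n_rec > 0 && (s + 1) % record_every == 0 && ri < n_recs) {
      double inv = S.rec_count > 0 ? 1.0 / S.rec_count : 0.0;
      for (int k = 0; k < 3 * S.n_rec; ++k) {
        rec_w_out(ri, k) = S.rec_w_acc[k] * inv;
        rec_all_out(ri, k) = S.rec_all_acc[k] * inv;
        S.rec_w_acc[k] = 0.0; S.rec_all_acc[k] = 0.0;
      }
      S.rec_count = 0;
      rec_time[ri] = (step0 + s + 1) * dt;
      ri++;
    }
    if (obs_every > 0 && (s + 1) % obs_every == 0 && oi < n_obs) {
      for (int b = 0; b < obs_bonds.nrow(); ++b) {
        int i = obs_bonds(b, 0), j = obs_bonds(b, 1);
        double d[3];
        pair_sep(S.box, S.x[i], S.y[i], S.z[i], S.x[j], S.y[j], S.z[j], d);
        obs_r(oi, b) = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
      }
      for (int t = 0; t < obs_angles.nrow(); ++t) {
        int i = obs_angles(t, 0), j = obs_angles(t, 1), k = obs_angles(t, 2);
        double u[3], v[3];
        pair_sep(S.box, S.x[i], S.y[i], S.z[i], S.x[j], S.y[j], S.z[j], u);
        pair_sep(S.box, S.x[k], S.y[k], S.z[k], S.x[j], S.y[j], S.z[j], v);
        double ru = std::sqrt(u[0]*u[0] + u[1]*u[1] + u[2]*u[2]);
        double rv = std::sqrt(v[0]*v[0] + v[1]*v[1] + v[2]*v[2]);
        double c = (u[0]*v[0] + u[1]*v[1] + u[2]*v[2]) / (ru * rv);
        if (c > 1.0) c = 1.0;
        if (c < -1.0) c = -1.0;
        obs_phi(oi, t) = std::acos(c);
      }
      obs_time[oi] = (step0 + s + 1) * dt;
      oi++;
    }
    if (frame_every > 0 && (s + 1) % frame_every == 0 && fi < n_frames) {
      NumericMatrix fr(N, 6);
      for (int i = 0; i < N; ++i) {
        fr(i, 0) = S.x[i]; fr(i, 1) = S.y[i]; fr(i, 2) = S.z[i];
        fr(i, 3) = S.vx[i]; fr(i, 4) = S.vy[i]; fr(i, 5) = S.vz[i];
      }
      frames[fi] = fr;
      frame_time[fi] = (step0 + s + 1) * dt;
      fi++;
    }
    if ((s + 1) % 1000 == 0) {
      // cheap corruption check
      double probe = S.x[0] + S.vx[0] + S.fx[0];
      if (!std::isfinite(probe))
        stop("non-finite state at step %g; aborting", step0 + s + 1);
      Rcpp::checkUserInterrupt();
    }
  }

  NumericMatrix pos_out(N, 3), vel_out(N, 3), f_out(N, 3);
  for (int i = 0; i < N; ++i) {
    pos_out(i, 0) = S.x[i]; pos_out(i, 1) = S.y[i]; pos_out(i, 2) = S.z[i];
    vel_out(i, 0) = S.vx[i]; vel_out(i, 1) = S.vy[i]; vel_out(i, 2) = S.vz[i];
    f_out(i, 0) = S.fx[i]; f_out(i, 1) = S.fy[i]; f_out(i, 2) = S.fz[i];
  }
  return List::create(_["pos"] = pos_out, _["vel"] = vel_out,
                      _["force"] = f_out,
                      _["frames"] = frames, _["frame_time"] = frame_time,
                      _["temperature"] = temp, _["temperature_time"] = temp_time,
                      _["rec_water"] = rec_w_out, _["rec_all"] = rec_all_out,
                      _["rec_time"] = rec_time,
                      _["obs_r"] = obs_r, _["obs_phi"] = obs_phi,
                      _["obs_time"] = obs_time,
                      _["step_end"] = step0 + nsteps,
                      _["reflections"] = (double)reflections,
                      _["degenerate_pairs"] = (double)S.degenerate_pairs);
}

// minimum chain-bead distance filter for solvent insertion
// [[Rcpp::export]]
LogicalVector overlap_ok_cpp(NumericMatrix water, NumericMatrix chain,
                             NumericVector boxL, LogicalVector periodic,
                             double min_dist) {
  int nw = water.nrow(), nc = chain.nrow();
  Box box;
  for (int k = 0; k < 3; ++k) { box.L[k] = boxL[k]; box.per[k] = periodic[k]; }
  double md2 = min_dist * min_dist;
  LogicalVector ok(nw, true);
  if (nc == 0) return ok;
  // coarse cell grid over chain beads (cell edge >= min_dist, use 1 r_c)
  int ncx = std::max(1, (int)std::floor(box.L[0]));
  int ncy = std::max(1, (int)std::floor(box.L[1]));
  int ncz = std::max(1, (int)std::floor(box.L[2]));
  std::vector<int> head(ncx * ncy * ncz, -1), nxt(nc);
  auto cell_of = [&](double x, double y, double z) {
    int a = (int)std::floor(x / (box.L[0] / ncx));
    int b = (int)std::floor(y / (box.L[1] / ncy));
    int c = (int)std::floor(z / (box.L[2] / ncz));
    a = std::min(std::max(a, 0), ncx - 1);
    b = std::min(std::max(b, 0), ncy - 1);
    c = std::min(std::max(c, 0), ncz - 1);
    return (a * ncy + b) * ncz + c;
  };
  for (int j = 0; j < nc; ++j) {
    int cell = cell_of(chain(j,0), chain(j,1), chain(j,2));
    nxt[j] = head[cell]; head[cell] = j;
  }
  for (int i = 0; i < nw; ++i) {
    int a0 = (int)std::floor(water(i,0) / (box.L[0] / ncx));
    int b0 = (int)std::floor(water(i,1) / (box.L[1] / ncy));
    int c0 = (int)std::floor(water(i,2) / (box.L[2] / ncz));
    for (int da = -1; da <= 1 && ok[i]; ++da)
      for (int db = -1; db <= 1 && ok[i]; ++db)
        for (int dc = -1; dc <= 1 && ok[i]; ++dc) {
          int a = a0 + da, b = b0 + db, c = c0 + dc;
          if (box.per[0]) a = (a % ncx + ncx) % ncx; else if (a < 0 || a >= ncx) continue;
          if (box.per[1]) b = (b % ncy + ncy) % ncy; else if (b < 0 || b >= ncy) continue;
          if (box.per[2]) c = (c % ncz + ncz) % ncz; else if (c < 0 || c >= ncz) continue;
          for (int j = head[(a * ncy + b) * ncz + c]; j >= 0; j = nxt[j]) {
            double d[3];
            pair_sep(box, water(i,0), water(i,1), water(i,2),
                     chain(j,0), chain(j,1), chain(j,2), d);
            if (d[0]*d[0] + d[1]*d[1] + d[2]*d[2] < md2) { ok[i] = false; break; }
          }
        }
  }
  return ok;
}
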