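// DPD integrator core: cell-list pair search, soft conservative repulsion,
// Groot-Warren dissipative/random thermostat, harmonic bonds, modified
// velocity-Verlet with predictor factor lambda.  Reduced units throughout
// (r_c = 1, kT target in params, per-bead masses in units of the water bead).
#include <Rcpp.h>
#include <vector>
#include <random>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

inline double min_image(double d, double L) {
  return d - L * std::nearbyint(d / L);
}

// Linked-cell grid.  Cell edge >= cutoff; falls back to all-pairs when any
// dimension holds fewer than 3 cells (periodic images would double-count).
struct CellGrid {
  int nc[3];
  double L[3], inv_cw[3];
  bool allpairs;
  std::vector<int> head, nxt;

  void init(const double* box, double cutoff, int N) {
    allpairs = false;
    for (int d = 0; d < 3; ++d) {
      L[d] = box[d];
      nc[d] = (int)std::floor(box[d] / cutoff);
      if (nc[d] < 3) allpairs = true;
    }
    if (allpairs) return;
    for (int d = 0; d < 3; ++d) inv_cw[d] = nc[d] / box[d];
    head.assign((size_t)nc[0] * nc[1] * nc[2], -1);
    nxt.assign(N, -1);
  }

  inline int cell_index(double x, double y, double z) const {
    int ix = (int)(x * inv_cw[0]); if (ix >= nc[0]) ix = nc[0] - 1; if (ix < 0) ix = 0;
    int iy = (int)(y * inv_cw[1]); if (iy >= nc[1]) iy = nc[1] - 1; if (iy < 0) iy = 0;
    int iz = (int)(z * inv_cw[2]); if (iz >= nc[2]) iz = nc[2] - 1; if (iz < 0) iz = 0;
    return (ix * nc[1] + iy) * nc[2] + iz;
  }

  void fill(const std::vector<double>& px, const std::vector<double>& py,
            const std::vector<double>& pz) {
    std::fill(head.begin(), head.end(), -1);
    const int N = (int)px.size();
    for (int i = 0; i < N; ++i) {
      int c = cell_index(px[i], py[i], pz[i]);
      nxt[i] = head[c];
      head[c] = i;
    }
  }
};

// Half-shell of neighbour cell offsets (13) + self handled separately.
const int HALF_OFF[13][3] = {
  {1,0,0},{0,1,0},{0,0,1},
  {1,1,0},{1,-1,0},{1,0,1},{1,0,-1},
  {0,1,1},{0,1,-1},
  {1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}
};

struct PairParams {
  const double* A;      // S x S repulsion matrix, column-major
  int S;
  double gamma, sigma, inv_sqrt_dt;
  bool thermostat;
};

struct System {
  int N;
  std::vector<double> px, py, pz, vx, vy, vz, fx, fy, fz, mass, inv_m;
  std::vector<int> sp;  // 0-based species index
  double box[3];
};

// One pair interaction; returns pair potential energy contribution.
inline double pair_force(System& S, int i, int j, const PairParams& pp,
                         std::mt19937_64& rng,
                         std::uniform_real_distribution<double>& unif) {
  double dx = min_image(S.px[i] - S.px[j], S.box[0]);
  double dy = min_image(S.py[i] - S.py[j], S.box[1]);
  double dz = min_image(S.pz[i] - S.pz[j], S.box[2]);
  double r2 = dx * dx + dy * dy + dz * dz;
  if (r2 >= 1.0) return 0.0;
  double r = std::sqrt(r2);
  double a = pp.A[S.sp[i] + pp.S * S.sp[j]];
  double ex, ey, ez;
  if (r < 1e-12) {
    // coincident soft cores: direction undefined, conservative force dropped
    return 0.5 * a;
  }
  ex = dx / r; ey = dy / r; ez = dz / r;
  double w = 1.0 - r;
  double fmag = a * w;
  if (pp.thermostat) {
    double dvx = S.vx[i] - S.vx[j];
    double dvy = S.vy[i] - S.vy[j];
    double dvz = S.vz[i] - S.vz[j];
    double ev = ex * dvx + ey * dvy + ez * dvz;
    double theta = unif(rng);  // uniform(-sqrt(3), sqrt(3)): unit variance
    fmag += -pp.gamma * w * w * ev + pp.sigma * w * theta * pp.inv_sqrt_dt;
  }
  S.fx[i] += fmag * ex; S.fy[i] += fmag * ey; S.fz[i] += fmag * ez;
  S.fx[j] -= fmag * ex; S.fy[j] -= fmag * ey; S.fz[j] -= fmag * ez;
  return 0.5 * a * w * w;
}

double compute_forces(System& S, CellGrid& grid, const PairParams& pp,
                      const std::vector<int>& b1, const std::vector<int>& b2,
                      double k_bond, double r0_bond,
                      std::mt19937_64& rng,
                      std::uniform_real_distribution<double>& unif) {
  std::fill(S.fx.begin(), S.fx.end(), 0.0);
  std::fill(S.fy.begin(), S.fy.end(), 0.0);
  std::fill(S.fz.begin(), S.fz.end(), 0.0);
  double pe = 0.0;

  if (grid.allpairs) {
    for (int i = 0; i < S.N; ++i)
      for (int j = i + 1; j < S.N; ++j)
        pe += pair_force(S, i, j, pp, rng, unif);
  } else {
    grid.fill(S.px, S.py, S.pz);
    for (int cx = 0; cx < grid.nc[0]; ++cx)
      for (int cy = 0; cy < grid.nc[1]; ++cy)
        for (int cz = 0; cz < grid.nc[2]; ++cz) {
          int c = (cx * grid.nc[1] + cy) * grid.nc[2] + cz;
          // within-cell pairs
          for (int i = grid.head[c]; i != -1; i = grid.nxt[i])
            for (int j = grid.nxt[i]; j != -1; j = grid.nxt[j])
              pe += pair_force(S, i, j, pp, rng, unif);
          // half-shell neighbour cells
          for (int k = 0; k < 13; ++k) {
            int ox = (cx + HALF_OFF[k][0] + grid.nc[0]) % grid.nc[0];
            int oy = (cy + HALF_OFF[k][1] + grid.nc[1]) % grid.nc[1];
            int oz = (cz + HALF_OFF[k][2] + grid.nc[2]) % grid.nc[2];
            int c2 = (ox * grid.nc[1] + oy) * grid.nc[2] + oz;
            for (int i = grid.head[c]; i != -1; i = grid.nxt[i])
              for (int j = grid.head[c2]; j != -1; j = grid.nxt[j])
                pe += pair_force(S, i, j, pp, rng, unif);
          }
        }
  }

  // harmonic bonds (not cutoff-limited)
  const size_t M = b1.size();
  for (size_t b = 0; b < M; ++b) {
    int i = b1[b], j = b2[b];
    double dx = min_image(S.px[i] - S.px[j], S.box[0]);
    double dy = min_image(S.py[i] - S.py[j], S.box[1]);
    double dz = min_image(S.pz[i] - S.pz[j], S.box[2]);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - r0_bond;
    pe += 0.5 * k_bond * dr * dr;
    if (r > 1e-12) {
      double fmag = -k_bond * dr / r;
      S.fx[i] += fmag * dx; S.fy[i] += fmag * dy; S.fz[i] += fmag * dz;
      S.fx[j] -= fmag * dx; S.fy[j] -= fmag * dy; S.fz[j] -= fmag * dz;
    }
  }
  return pe;
}

void load_system(System& S, const NumericMatrix& pos, const NumericMatrix& vel,
                 const IntegerVector& species, const NumericVector& mass,
                 const NumericVector& box) {
  S.N = pos.nrow();
  S.px.resize(S.N); S.py.resize(S.N); S.pz.resize(S.N);
  S.vx.resize(S.N); S.vy.resize(S.N); S.vz.resize(S.N);
  S.fx.assign(S.N, 0.0); S.fy.assign(S.N, 0.0); S.fz.assign(S.N, 0.0);
  S.mass.resize(S.N); S.inv_m.resize(S.N); S.sp.resize(S.N);
  for (int i = 0; i < S.N; ++i) {
    S.px[i] = pos(i, 0); S.py[i] = pos(i, 1); S.pz[i] = pos(i, 2);
    S.vx[i] = vel(i, 0); S.vy[i] = vel(i, 1); S.vz[i] = vel(i, 2);
    S.mass[i] = mass[i]; S.inv_m[i] = 1.0 / mass[i];
    S.sp[i] = species[i] - 1;
  }
  for (int d = 0; d < 3; ++d) S.box[d] = box[d];
}

inline void wrap_pbc(System& S) {
  for (int i = 0; i < S.N; ++i) {
    S.px[i] -= S.box[0] * std::floor(S.px[i] / S.box[0]);
    S.py[i] -= S.box[1] * std::floor(S.py[i] / S.box[1]);
    S.pz[i] -= S.box[2] * std::floor(S.pz[i] / S.box[2]);
  }
}

}  // namespace

// [[Rcpp::export]]
List cpp_dpd_run(NumericMatrix pos, NumericMatrix vel, IntegerVector species,
                 NumericVector mass, NumericVector box, NumericMatrix A,
                 IntegerVector bond_i, IntegerVector bond_j,
                 double k_bond, double r0_bond,
                 double gamma, double sigma, double dt, double lambda,
                 int n_steps, int stride, double seed, bool thermostat) {
  System S;
  load_system(S, pos, vel, species, mass, box);
  wrap_pbc(S);
  CellGrid grid;
  grid.init(S.box, 1.0, S.N);

  PairParams pp;
  pp.A = A.begin(); pp.S = A.nrow();
  pp.gamma = gamma; pp.sigma = sigma;
  pp.inv_sqrt_dt = 1.0 / std::sqrt(dt);
  pp.thermostat = thermostat;

  std::vector<int> b1(bond_i.begin(), bond_i.end());
  std::vector<int> b2(bond_j.begin(), bond_j.end());
  for (auto& v : b1) --v;
  for (auto& v : b2) --v;

  std::mt19937_64 rng((uint64_t)seed);
  const double s3 = std::sqrt(3.0);
  std::uniform_real_distribution<double> unif(-s3, s3);

  const int n_snap = n_steps / stride + 1;
  List snap_pos(n_snap), snap_vel(n_snap);
  NumericVector sc_step(n_snap), sc_kT(n_snap), sc_pnorm(n_snap),
      sc_pe(n_snap), sc_ke(n_snap);

  std::vector<double> ax(S.N), ay(S.N), az(S.N);  // f(t), per unit mass later
  double pe = compute_forces(S, grid, pp, b1, b2, k_bond, r0_bond, rng, unif);

  int isnap = 0;
  auto record = [&](int step, double pe_now) {
    NumericMatrix P(S.N, 3), V(S.N, 3);
    double ke = 0.0, Px = 0, Py = 0, Pz = 0;
    for (int i = 0; i < S.N; ++i) {
      P(i, 0) = S.px[i]; P(i, 1) = S.py[i]; P(i, 2) = S.pz[i];
      V(i, 0) = S.vx[i]; V(i, 1) = S.vy[i]; V(i, 2) = S.vz[i];
      double m = S.mass[i];
      ke += 0.5 * m * (S.vx[i] * S.vx[i] + S.vy[i] * S.vy[i] + S.vz[i] * S.vz[i]);
      Px += m * S.vx[i]; Py += m * S.vy[i]; Pz += m * S.vz[i];
    }
    int dof = 3 * S.N - 3;
    snap_pos[isnap] = P; snap_vel[isnap] = V;
    sc_step[isnap] = step;
    sc_kT[isnap] = dof > 0 ? 2.0 * ke / dof : 0.0;
    sc_pnorm[isnap] = std::sqrt(Px * Px + Py * Py + Pz * Pz);
    sc_pe[isnap] = pe_now; sc_ke[isnap] = ke;
    ++isnap;
  };
  record(0, pe);

  for (int step = 1; step <= n_steps; ++step) {
    // modified velocity-Verlet (Groot-Warren)
    for (int i = 0; i < S.N; ++i) {
      ax[i] = S.fx[i] * S.inv_m[i];
      ay[i] = S.fy[i] * S.inv_m[i];
      az[i] = S.fz[i] * S.inv_m[i];
      S.px[i] += dt * S.vx[i] + 0.5 * dt * dt * ax[i];
      S.py[i] += dt * S.vy[i] + 0.5 * dt * dt * ay[i];
      S.pz[i] += dt * S.vz[i] + 0.5 * dt * dt * az[i];
    }
    wrap_pbc(S);
    // predicted velocities for the force evaluation
    std::vector<double> vx0(S.vx), vy0(S.vy), vz0(S.vz);
    for (int i = 0; i < S.N; ++i) {
      S.vx[i] = vx0[i] + lambda * dt * S.fx[i] * S.inv_m[i];
      S.vy[i] = vy0[i] + lambda * dt * S.fy[i] * S.inv_m[i];
      S.vz[i] = vz0[i] + lambda * dt * S.fz[i] * S.inv_m[i];
    }
    pe = compute_forces(S, grid, pp, b1, b2, k_bond, r0_bond, rng, unif);
    bool bad = false;
    for (int i = 0; i < S.N; ++i) {
      S.vx[i] = vx0[i] + 0.5 * dt * (ax[i] + S.fx[i] * S.inv_m[i]);
      S.vy[i] = vy0[i] + 0.5 * dt * (ay[i] + S.fy[i] * S.inv_m[i]);
      S.vz[i] = vz0[i] + 0.5 * dt * (az[i] + S.fz[i] * S.inv_m[i]);
      if (!std::isfinite(S.px[i]) || !std::isfinite(S.vx[i])) bad = true;
    }
    if (bad) stop("numerical blow-up at step %d", step);
    if (step % stride == 0) record(step, pe);
    if (step % 200 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["pos"] = snap_pos, _["vel"] = snap_vel,
                      _["step"] = sc_step, _["kT"] = sc_kT,
                      _["pnorm"] = sc_pnorm, _["pe"] = sc_pe,
                      _["ke"] = sc_ke);
}

// Force evaluation only (deterministic part unless thermostat requested);
// used by unit tests and by single-step inspection.
// [[Rcpp::export]]
List cpp_dpd_forces(NumericMatrix pos, NumericMatrix vel, IntegerVector species,
                    NumericVector mass, NumericVector box, NumericMatrix A,
                    IntegerVector bond_i, IntegerVector bond_j,
                    double k_bond, double r0_bond,
                    double gamma, double sigma, double dt,
                    double seed, bool thermostat, bool force_allpairs) {
  System S;
  load_system(S, pos, vel, species, mass, box);
  wrap_pbc(S);
  CellGrid grid;
  grid.init(S.box, 1.0, S.N);
  if (force_allpairs) grid.allpairs = true;

  PairParams pp;
  pp.A = A.begin(); pp.S = A.nrow();
  pp.gamma = gamma; pp.sigma = sigma;
  pp.inv_sqrt_dt = 1.0 / std::sqrt(dt);
  pp.thermostat = thermostat;

  std::vector<int> b1(bond_i.begin(), bond_i.end());
  std::vector<int> b2(bond_j.begin(), bond_j.end());
  for (auto& v : b1) --v;
  for (auto& v : b2) --v;

  std::mt19937_64 rng((uint64_t)seed);
  const double s3 = std::sqrt(3.0);
  std::uniform_real_distribution<double> unif(-s3, s3);

  double pe = compute_forces(S, grid, pp, b1, b2, k_bond, r0_bond, rng, unif);
  NumericMatrix F(S.N, 3);
  for (int i = 0; i < S.N; ++i) {
    F(i, 0) = S.fx[i]; F(i, 1) = S.fy[i]; F(i, 2) = S.fz[i];
  }
  return List::create(_["forces"] = F, _["pe"] = pe);
}

// All bead pairs with minimum-image separation below `cutoff`.
// Returns 1-based index vectors; used by the cluster analysis.
// [[Rcpp::export]]
List cpp_pairs_within(NumericMatrix pos, NumericVector box, double cutoff) {
  const int N = pos.nrow();
  std::vector<double> px(N), py(N), pz(N);
  double L[3] = {box[0], box[1], box[2]};
  for (int i = 0; i < N; ++i) {
    px[i] = pos(i, 0) - L[0] * std::floor(pos(i, 0) / L[0]);
    py[i] = pos(i, 1) - L[1] * std::floor(pos(i, 1) / L[1]);
    pz[i] = pos(i, 2) - L[2] * std::floor(pos(i, 2) / L[2]);
  }
  CellGrid grid;
  grid.init(L, cutoff, N);
  std::vector<int> out_i, out_j;
  const double c2 = cutoff * cutoff;
  auto check = [&](int i, int j) {
    double dx = min_image(px[i] - px[j], L[0]);
    double dy = min_image(py[i] - py[j], L[1]);
    double dz = min_image(pz[i] - pz[j], L[2]);
    if (dx * dx + dy * dy + dz * dz < c2) {
      out_i.push_back(i + 1);
      out_j.push_back(j + 1);
    }
  };
  if (grid.allpairs) {
    for (int i = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j) check(i, j);
  } else {
    grid.fill(px, py, pz);
    for (int cx = 0; cx < grid.nc[0]; ++cx)
      for (int cy = 0; cy < grid.nc[1]; ++cy)
        for (int cz = 0; cz < grid.nc[2]; ++cz) {
          int c = (cx * grid.nc[1] + cy) * grid.nc[2] + cz;
          for (int i = grid.head[c]; i != -1; i = grid.nxt[i])
            for (int j = grid.nxt[i]; j != -1; j = grid.nxt[j]) check(i, j);
          for (int k = 0; k < 13; ++k) {
            int ox = (cx + HALF_OFF[k][0] + grid.nc[0]) % grid.nc[0];
            int oy = (cy + HALF_OFF[k][1] + grid.nc[1]) % grid.nc[1];
            int oz = (cz + HALF_OFF[k][2] + grid.nc[2]) % grid.nc[2];
            int c2i = (ox * grid.nc[1] + oy) * grid.nc[2] + oz;
            for (int i = grid.head[c]; i != -1; i = grid.nxt[i])
              for (int j = grid.head[c2i]; j != -1; j = grid.nxt[j]) check(i, j);
          }
        }
  }
  return List::create(_["i"] = wrap(out_i), _["j"] = wrap(out_j));
}
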