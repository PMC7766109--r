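// DPD force kernels and Groot-Warren modified velocity-Verlet integrator.
//
// Conventions used throughout:
//  - reduced units: m = kBT = rc = 1 (rc is the pair-force cutoff);
//  - positions are wrapped into [0, L) per axis, with integer image counts
//    carried alongside so molecules can be unwrapped exactly;
//  - species are 0-based integer codes indexing the aij matrix;
//  - bead indices arriving from R are 1-based and converted here.
//
// The pairwise random noise zeta_ij is drawn from a counter-based hash RNG
// keyed on (seed, step, unordered pair {i,j}): symmetric in i and j by
// construction, redrawn every step, and independent of the order in which a
// neighbor search enumerates the pairs — so the cell-list and the brute-force
// O(N^2) paths produce bit-identical random forces.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

static const double SQRT3 = 1.7320508075688772;

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// zero-mean, unit-variance uniform on [-sqrt(3), sqrt(3)], symmetric in (i,j)
static inline double pair_zeta(uint64_t seed, uint64_t step, int i, int j) {
  if (i > j) std::swap(i, j);
  uint64_t key = (static_cast<uint64_t>(static_cast<uint32_t>(i)) << 32) |
                 static_cast<uint64_t>(static_cast<uint32_t>(j));
  uint64_t h = splitmix64(seed ^ splitmix64(step ^ splitmix64(key)));
  double u = (h >> 11) * (1.0 / 9007199254740992.0); // 53-bit mantissa, [0,1)
  return (2.0 * u - 1.0) * SQRT3;
}

static inline double min_image(double dx, double L) {
  return dx - L * std::round(dx / L);
}

struct PairParams {
  const int *species;
  const double *a;      // flattened nsp x nsp, column-major
  int nsp;
  double gamma, sigma, inv_sqrt_dt;
  uint64_t seed, step;
};

// Accumulate DPD pair forces for one (i, j) pair separated by (dx,dy,dz), r<1.
static inline void accumulate_pair(int i, int j, double dx, double dy, double dz,
                                   double r2, const double *vel, int N,
                                   const PairParams &pp, double *f) {
  double r = std::sqrt(r2);
  double w = 1.0 - r;
  double inv_r = (r > 1e-12) ? 1.0 / r : 0.0;
  double ex = dx * inv_r, ey = dy * inv_r, ez = dz * inv_r;
  double aij = pp.a[pp.species[i] + pp.nsp * pp.species[j]];
  double fc = aij * w;
  double fd = 0.0, fr = 0.0;
  if (pp.gamma != 0.0) {
    double dvx = vel[i] - vel[j];
    double dvy = vel[i + N] - vel[j + N];
    double dvz = vel[i + 2 * N] - vel[j + 2 * N];
    double rdotv = ex * dvx + ey * dvy + ez * dvz;
    fd = -pp.gamma * w * w * rdotv;
  }
  if (pp.sigma != 0.0) {
    fr = pp.sigma * w * pair_zeta(pp.seed, pp.step, i, j) * pp.inv_sqrt_dt;
  }
  double fmag = fc + fd + fr;
  f[i] += fmag * ex;          f[j] -= fmag * ex;
  f[i + N] += fmag * ey;      f[j + N] -= fmag * ey;
  f[i + 2 * N] += fmag * ez;  f[j + 2 * N] -= fmag * ez;
}

// ---------------------------------------------------------------------------
// Cell list

// beads bucketed by cell and gathered into contiguous, cell-sorted coordinate
// arrays (cache-friendly inner loops)
struct CellGrid {
  int nx, ny, nz;
  bool usable;             // false -> caller must brute-force
  std::vector<int> start;  // per-cell range start into `order` (ncell + 1)
  std::vector<int> order;  // bead indices sorted by cell
  std::vector<double> xs, ys, zs; // gathered coordinates in sorted order
};

static CellGrid build_cells(const double *pos, int N, double Lx, double Ly,
                            double Lz, double rcut) {
  CellGrid g;
  g.nx = static_cast<int>(std::floor(Lx / rcut));
  g.ny = static_cast<int>(std::floor(Ly / rcut));
  g.nz = static_cast<int>(std::floor(Lz / rcut));
  g.usable = (g.nx >= 3 && g.ny >= 3 && g.nz >= 3);
  if (!g.usable) return g;
  size_t ncell = static_cast<size_t>(g.nx) * g.ny * g.nz;
  std::vector<int> cell_of(N);
  std::vector<int> count(ncell + 1, 0);
  for (int i = 0; i < N; ++i) {
    double x = pos[i], y = pos[i + N], z = pos[i + 2 * N];
    int cx = static_cast<int>(std::floor(x / Lx * g.nx)); if (cx >= g.nx) cx = g.nx - 1; if (cx < 0) cx = 0;
    int cy = static_cast<int>(std::floor(y / Ly * g.ny)); if (cy >= g.ny) cy = g.ny - 1; if (cy < 0) cy = 0;
    int cz = static_cast<int>(std::floor(z / Lz * g.nz)); if (cz >= g.nz) cz = g.nz - 1; if (cz < 0) cz = 0;
    int c = cx + g.nx * (cy + g.ny * cz);
    cell_of[i] = c;
    ++count[c + 1];
  }
  for (size_t c = 0; c < ncell; ++c) count[c + 1] += count[c];
  g.start = count;
  g.order.resize(N);
  g.xs.resize(N); g.ys.resize(N); g.zs.resize(N);
  std::vector<int> cursor(g.start.begin(), g.start.end() - 1);
  for (int i = 0; i < N; ++i) {
    int at = cursor[cell_of[i]]++;
    g.order[at] = i;
    g.xs[at] = pos[i];
    g.ys[at] = pos[i + N];
    g.zs[at] = pos[i + 2 * N];
  }
  return g;
}

// half stencil: 13 forward neighbor offsets + the cell itself (i<j inside)
static const int HALF_STENCIL[13][3] = {
  {1, 0, 0},  {0, 1, 0},  {1, 1, 0},  {-1, 1, 0},
  {0, 0, 1},  {1, 0, 1},  {-1, 0, 1}, {0, 1, 1},
  {1, 1, 1},  {-1, 1, 1}, {0, -1, 1}, {1, -1, 1}, {-1, -1, 1}
};

// Enumerate all pairs with r < rcut under minimum image; call fn(i,j,dx,dy,dz,r2).
// The cell-list path applies the periodic shift once per neighbor-cell visit
// (cells are at most L/3 wide, so same-cell pairs never need wrapping).
template <typename F>
static void for_each_pair(const double *pos, int N, double Lx, double Ly,
                          double Lz, double rcut, bool brute, F fn) {
  double rc2 = rcut * rcut;
  CellGrid g;
  if (!brute) g = build_cells(pos, N, Lx, Ly, Lz, rcut);
  if (brute || !g.usable) {
    for (int i = 0; i < N - 1; ++i) {
      for (int j = i + 1; j < N; ++j) {
        double dx = min_image(pos[i] - pos[j], Lx);
        double dy = min_image(pos[i + N] - pos[j + N], Ly);
        double dz = min_image(pos[i + 2 * N] - pos[j + 2 * N], Lz);
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 < rc2) fn(i, j, dx, dy, dz, r2);
      }
    }
    return;
  }
  const double *xs = g.xs.data(), *ys = g.ys.data(), *zs = g.zs.data();
  const int *ord = g.order.data(), *cs = g.start.data();
  for (int cz = 0; cz < g.nz; ++cz) {
    for (int cy = 0; cy < g.ny; ++cy) {
      for (int cx = 0; cx < g.nx; ++cx) {
        int c = cx + g.nx * (cy + g.ny * cz);
        int a0 = cs[c], a1 = cs[c + 1];
        bool interior = cx >= 1 && cx < g.nx - 1 && cy >= 1 &&
                        cy < g.ny - 1 && cz >= 1 && cz < g.nz - 1;
        if (interior) {
          // x-adjacent cells are contiguous in the sorted layout: merge the
          // self-cell and (+1,0,0) visits, and each (dy,dz) offset's three
          // x-neighbors, into single ranges (no wrap possible here)
          int jend = cs[c + 2];
          for (int a = a0; a < a1; ++a) {
            double xi = xs[a], yi = ys[a], zi = zs[a];
            for (int b = a + 1; b < jend; ++b) {
              double dx = xi - xs[b], dy = yi - ys[b], dz = zi - zs[b];
              double r2 = dx * dx + dy * dy + dz * dz;
              if (r2 < rc2) fn(ord[a], ord[b], dx, dy, dz, r2);
            }
          }
          static const int OFF4[4][2] = {{1, 0}, {0, 1}, {1, 1}, {-1, 1}};
          for (int s = 0; s < 4; ++s) {
            int c2 = c + OFF4[s][0] * g.nx + OFF4[s][1] * g.nx * g.ny;
            int b0 = cs[c2 - 1], b1 = cs[c2 + 2];
            for (int a = a0; a < a1; ++a) {
              double xi = xs[a], yi = ys[a], zi = zs[a];
              for (int b = b0; b < b1; ++b) {
                double dx = xi - xs[b], dy = yi - ys[b], dz = zi - zs[b];
                double r2 = dx * dx + dy * dy + dz * dz;
                if (r2 < rc2) fn(ord[a], ord[b], dx, dy, dz, r2);
              }
            }
          }
          continue;
        }
        // pairs within the cell: no wrap possible
        for (int a = a0; a < a1; ++a) {
          double xi = xs[a], yi = ys[a], zi = zs[a];
          for (int b = a + 1; b < a1; ++b) {
            double dx = xi - xs[b], dy = yi - ys[b], dz = zi - zs[b];
            double r2 = dx * dx + dy * dy + dz * dz;
            if (r2 < rc2) fn(ord[a], ord[b], dx, dy, dz, r2);
          }
        }
        // pairs with forward neighbor cells, shift applied per cell visit
        for (int s = 0; s < 13; ++s) {
          int ox = cx + HALF_STENCIL[s][0];
          int oy = cy + HALF_STENCIL[s][1];
          int oz = cz + HALF_STENCIL[s][2];
          double sx = 0.0, sy = 0.0, sz = 0.0;
          // a neighbor cell wrapped past the high edge sits at +L, so the
          // pair displacement xi - (xj + L) folds the shift into xi as -L
          if (ox < 0) { ox += g.nx; sx = Lx; } else if (ox >= g.nx) { ox -= g.nx; sx = -Lx; }
          if (oy < 0) { oy += g.ny; sy = Ly; } else if (oy >= g.ny) { oy -= g.ny; sy = -Ly; }
          if (oz < 0) { oz += g.nz; sz = Lz; } else if (oz >= g.nz) { oz -= g.nz; sz = -Lz; }
          int c2 = ox + g.nx * (oy + g.ny * oz);
          int b0 = cs[c2], b1 = cs[c2 + 1];
          for (int a = a0; a < a1; ++a) {
            double xi = xs[a] + sx, yi = ys[a] + sy, zi = zs[a] + sz;
            for (int b = b0; b < b1; ++b) {
              double dx = xi - xs[b], dy = yi - ys[b], dz = zi - zs[b];
              double r2 = dx * dx + dy * dy + dz * dz;
              if (r2 < rc2) fn(ord[a], ord[b], dx, dy, dz, r2);
            }
          }
        }
      }
    }
  }
}

// ---------------------------------------------------------------------------
// Bonded terms

static void add_bond_forces(const double *pos, int N, double Lx, double Ly,
                            double Lz, const NumericMatrix &bonds, double *f) {
  int nb = bonds.nrow();
  for (int b = 0; b < nb; ++b) {
    int i = static_cast<int>(bonds(b, 0)) - 1;
    int j = static_cast<int>(bonds(b, 1)) - 1;
    double ks = bonds(b, 2), rs = bonds(b, 3);
    double dx = min_image(pos[i] - pos[j], Lx);
    double dy = min_image(pos[i + N] - pos[j + N], Ly);
    double dz = min_image(pos[i + 2 * N] - pos[j + 2 * N], Lz);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-9) stop("zero-length bond between beads %d and %d", i + 1, j + 1);
    double fmag = ks * (1.0 - r / rs); // along unit vector from j to i
    double s = fmag / r;
    f[i] += s * dx;          f[j] -= s * dx;
    f[i + N] += s * dy;      f[j + N] -= s * dy;
    f[i + 2 * N] += s * dz;  f[j + 2 * N] -= s * dz;
  }
}

// harmonic angle U = ktheta * (theta - theta0)^2, j is the vertex
static void add_angle_forces(const double *pos, int N, double Lx, double Ly,
                             double Lz, const NumericMatrix &angles, double *f) {
  int na = angles.nrow();
  for (int t = 0; t < na; ++t) {
    int i = static_cast<int>(angles(t, 0)) - 1;
    int j = static_cast<int>(angles(t, 1)) - 1;
    int k = static_cast<int>(angles(t, 2)) - 1;
    double kth = angles(t, 3), th0 = angles(t, 4);
    double ux = min_image(pos[i] - pos[j], Lx);
    double uy = min_image(pos[i + N] - pos[j + N], Ly);
    double uz = min_image(pos[i + 2 * N] - pos[j + 2 * N], Lz);
    double wx = min_image(pos[k] - pos[j], Lx);
    double wy = min_image(pos[k + N] - pos[j + N], Ly);
    double wz = min_image(pos[k + 2 * N] - pos[j + 2 * N], Lz);
    double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
    double nw = std::sqrt(wx * wx + wy * wy + wz * wz);
    if (nu < 1e-9 || nw < 1e-9)
      stop("degenerate angle: zero-length arm at vertex bead %d", j + 1);
    double c = (ux * wx + uy * wy + uz * wz) / (nu * nw);
    if (c > 1.0) c = 1.0;
    if (c < -1.0) c = -1.0;
    double s = std::sqrt(1.0 - c * c);
    if (s < 1e-8) s = 1e-8;
    double theta = std::acos(c);
    double coef = 2.0 * kth * (theta - th0) / s; // -dU/dtheta * (-1/sin)
    // dcos/dri = w/(|u||w|) - c*u/|u|^2 ; F_i = coef * dcos/dri
    double fix = coef * (wx / (nu * nw) - c * ux / (nu * nu));
    double fiy = coef * (wy / (nu * nw) - c * uy / (nu * nu));
    double fiz = coef * (wz / (nu * nw) - c * uz / (nu * nu));
    double fkx = coef * (ux / (nu * nw) - c * wx / (nw * nw));
    double fky = coef * (uy / (nu * nw) - c * wy / (nw * nw));
    double fkz = coef * (uz / (nu * nw) - c * wz / (nw * nw));
    f[i] += fix;         f[i + N] += fiy;         f[i + 2 * N] += fiz;
    f[k] += fkx;         f[k + N] += fky;         f[k + 2 * N] += fkz;
    f[j] -= fix + fkx;   f[j + N] -= fiy + fky;   f[j + 2 * N] -= fiz + fkz;
  }
}

// ---------------------------------------------------------------------------
// Full force evaluation

static void compute_all_forces(const double *pos, const double *vel, int N,
                               double Lx, double Ly, double Lz,
                               const PairParams &pp, const NumericMatrix &bonds,
                               const NumericMatrix &angles,
                               const std::vector<int> &pull_idx, double pullF,
                               bool brute, double *f) {
  std::fill(f, f + 3 * N, 0.0);
  for_each_pair(pos, N, Lx, Ly, Lz, 1.0, brute,
                [&](int i, int j, double dx, double dy, double dz, double r2) {
                  accumulate_pair(i, j, dx, dy, dz, r2, vel, N, pp, f);
                });
  if (bonds.nrow() > 0) add_bond_forces(pos, N, Lx, Ly, Lz, bonds, f);
  if (angles.nrow() > 0) add_angle_forces(pos, N, Lx, Ly, Lz, angles, f);
  if (pullF != 0.0)
    for (size_t q = 0; q < pull_idx.size(); ++q) f[pull_idx[q]] += pullF;
}

// Verlet-list force evaluation used inside the integrator: `ni/nj` hold all
// pairs within rc + skin of a recent configuration; each is re-checked
// against the true cutoff with a single-branch minimum-image correction
// (valid because listed pairs are far closer than half a box edge).
static void compute_forces_nlist(const double *pos, const double *vel, int N,
                                 double Lx, double Ly, double Lz,
                                 const PairParams &pp,
                                 const NumericMatrix &bonds,
                                 const NumericMatrix &angles,
                                 const std::vector<int> &pull_idx,
                                 double pullF, const std::vector<int> &ni,
                                 const std::vector<int> &nj, double *f) {
  std::fill(f, f + 3 * N, 0.0);
  const double hx = 0.5 * Lx, hy = 0.5 * Ly, hz = 0.5 * Lz;
  const double *px = pos, *py = pos + N, *pz = pos + 2 * N;
  size_t np = ni.size();
  for (size_t q = 0; q < np; ++q) {
    int i = ni[q], j = nj[q];
    double dx = px[i] - px[j];
    if (dx > hx) dx -= Lx; else if (dx < -hx) dx += Lx;
    double dy = py[i] - py[j];
    if (dy > hy) dy -= Ly; else if (dy < -hy) dy += Ly;
    double dz = pz[i] - pz[j];
    if (dz > hz) dz -= Lz; else if (dz < -hz) dz += Lz;
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 < 1.0) accumulate_pair(i, j, dx, dy, dz, r2, vel, N, pp, f);
  }
  if (bonds.nrow() > 0) add_bond_forces(pos, N, Lx, Ly, Lz, bonds, f);
  if (angles.nrow() > 0) add_angle_forces(pos, N, Lx, Ly, Lz, angles, f);
  if (pullF != 0.0)
    for (size_t q = 0; q < pull_idx.size(); ++q) f[pull_idx[q]] += pullF;
}

static std::vector<int> to_zero_based(const IntegerVector &v) {
  std::vector<int> out(v.size());
  for (int i = 0; i < v.size(); ++i) out[i] = v[i] - 1;
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_forces(NumericMatrix pos, NumericMatrix vel,
                         NumericVector box, IntegerVector species,
                         NumericMatrix amat, NumericMatrix bonds,
                         NumericMatrix angles, IntegerVector pull_idx,
                         double pullF, double gamma, double sigma, double dt,
                         double seed, double step, bool brute) {
  int N = pos.nrow();
  PairParams pp;
  std::vector<int> sp(species.begin(), species.end());
  pp.species = sp.data();
  pp.a = amat.begin();
  pp.nsp = amat.nrow();
  pp.gamma = gamma;
  pp.sigma = sigma;
  pp.inv_sqrt_dt = 1.0 / std::sqrt(dt);
  pp.seed = static_cast<uint64_t>(seed);
  pp.step = static_cast<uint64_t>(step);
  std::vector<int> pidx = to_zero_based(pull_idx);
  NumericMatrix f(N, 3);
  compute_all_forces(pos.begin(), vel.begin(), N, box[0], box[1], box[2], pp,
                     bonds, angles, pidx, pullF, brute, f.begin());
  return f;
}

// [[Rcpp::export]]
List cpp_run(NumericMatrix pos, NumericMatrix vel, IntegerMatrix img,
             NumericVector box, IntegerVector species, NumericMatrix amat,
             NumericMatrix bonds, NumericMatrix angles, LogicalVector fixed,
             IntegerVector pull_idx, double pullF, double gamma, double sigma,
             double dt, double lambda, int nsteps, double seed, double step0,
             Nullable<NumericMatrix> forces_in) {
  int N = pos.nrow();
  double Lx = box[0], Ly = box[1], Lz = box[2];
  double maxdisp = 0.5 * std::min(Lx, std::min(Ly, Lz));

  NumericMatrix x = clone(pos);
  NumericMatrix v = clone(vel);
  IntegerMatrix im = clone(img);
  std::vector<double> vt(3 * N); // lambda-predicted velocities

  PairParams pp;
  std::vector<int> sp(species.begin(), species.end());
  pp.species = sp.data();
  pp.a = amat.begin();
  pp.nsp = amat.nrow();
  pp.gamma = gamma;
  pp.sigma = sigma;
  pp.inv_sqrt_dt = 1.0 / std::sqrt(dt);
  pp.seed = static_cast<uint64_t>(seed);
  std::vector<int> pidx = to_zero_based(pull_idx);

  double *X = x.begin(), *V = v.begin();
  int *IM = im.begin();
  double L[3] = {Lx, Ly, Lz};

  // Verlet neighbor list with a displacement-tracked skin
  const double skin = 0.4, rlist = 1.0 + skin;
  std::vector<int> ni, nj;
  ni.reserve(8 * N); nj.reserve(8 * N);
  std::vector<double> drift(3 * N, 0.0); // per-bead displacement since build
  int n_rebuilds = 0;
  auto rebuild_list = [&]() {
    ni.clear(); nj.clear();
    for_each_pair(X, N, Lx, Ly, Lz, rlist, false,
                  [&](int i, int j, double, double, double, double) {
                    ni.push_back(i);
                    nj.push_back(j);
                  });
    std::fill(drift.begin(), drift.end(), 0.0);
    ++n_rebuilds;
  };
  rebuild_list();

  NumericMatrix f(N, 3);
  double *F = f.begin();
  if (forces_in.isNotNull()) {
    NumericMatrix fin(forces_in);
    std::copy(fin.begin(), fin.end(), f.begin());
  } else {
    pp.step = static_cast<uint64_t>(step0);
    compute_forces_nlist(X, v.begin(), N, Lx, Ly, Lz, pp, bonds, angles,
                         pidx, pullF, ni, nj, F);
  }

  for (int s = 0; s < nsteps; ++s) {
    uint64_t step_id = static_cast<uint64_t>(step0) + s + 1;
    // half kick + drift + lambda prediction
    for (int i = 0; i < N; ++i) {
      if (fixed[i]) {
        vt[i] = vt[i + N] = vt[i + 2 * N] = 0.0;
        continue;
      }
      for (int d = 0; d < 3; ++d) {
        int id = i + d * N;
        double vh = V[id] + 0.5 * dt * F[id];
        double dxs = dt * vh;
        if (std::fabs(dxs) > maxdisp)
          stop("integration instability: bead %d moved %.3f rc in one step at step %llu",
               i + 1, std::fabs(dxs), (unsigned long long)step_id);
        drift[id] += dxs;
        double xn = X[id] + dxs;
        // wrap and count images
        if (xn >= L[d]) { xn -= L[d]; IM[id] += 1; }
        else if (xn < 0.0) { xn += L[d]; IM[id] -= 1; }
        if (xn >= L[d] || xn < 0.0) { // pathological large move (still < L/2)
          double sh = std::floor(xn / L[d]);
          xn -= sh * L[d];
          IM[id] += static_cast<int>(sh);
        }
        X[id] = xn;
        vt[id] = V[id] + lambda * dt * F[id];
        V[id] = vh; // store half-kicked velocity
      }
    }
    // rebuild when two beads could have closed the skin gap since the build
    double max_d2 = 0.0;
    for (int i = 0; i < N; ++i) {
      double d2 = drift[i] * drift[i] + drift[i + N] * drift[i + N] +
                  drift[i + 2 * N] * drift[i + 2 * N];
      if (d2 > max_d2) max_d2 = d2;
    }
    if (2.0 * std::sqrt(max_d2) >= 0.9 * skin) rebuild_list();
    // force at new positions with predicted velocities
    pp.step = step_id;
    compute_forces_nlist(X, vt.data(), N, Lx, Ly, Lz, pp, bonds, angles,
                         pidx, pullF, ni, nj, F);
    // final velocity correction
    for (int i = 0; i < N; ++i) {
      if (fixed[i]) continue;
      for (int d = 0; d < 3; ++d) {
        int id = i + d * N;
        V[id] += 0.5 * dt * F[id];
      }
    }
  }

  return List::create(_["positions"] = x, _["velocities"] = v,
                      _["images"] = im, _["forces"] = f,
                      _["steps_done"] = nsteps,
                      _["n_rebuilds"] = n_rebuilds,
                      _["n_pairs"] = static_cast<double>(ni.size()));
}

// [[Rcpp::export]]
IntegerMatrix cpp_pairs(NumericMatrix pos, NumericVector box, double rcut,
                        bool brute) {
  int N = pos.nrow();
  std::vector<int> ii, jj;
  for_each_pair(pos.begin(), N, box[0], box[1], box[2], rcut, brute,
                [&](int i, int j, double, double, double, double) {
                  ii.push_back(std::min(i, j) + 1);
                  jj.push_back(std::max(i, j) + 1);
                });
  IntegerMatrix out(ii.size(), 2);
  for (size_t q = 0; q < ii.size(); ++q) {
    out(q, 0) = ii[q];
    out(q, 1) = jj[q];
  }
  return out;
}

// [[Rcpp::export]]
double cpp_potential_energy(NumericMatrix pos, NumericVector box,
                            IntegerVector species, NumericMatrix amat,
                            NumericMatrix bonds, NumericMatrix angles) {
  int N = pos.nrow();
  double Lx = box[0], Ly = box[1], Lz = box[2];
  const double *P = pos.begin();
  double U = 0.0;
  int nsp = amat.nrow();
  for_each_pair(P, N, Lx, Ly, Lz, 1.0, false,
                [&](int i, int j, double, double, double, double r2) {
                  double r = std::sqrt(r2);
                  double aij = amat(species[i], species[j]);
                  (void)nsp;
                  U += 0.5 * aij * (1.0 - r) * (1.0 - r);
                });
  for (int b = 0; b < bonds.nrow(); ++b) {
    int i = static_cast<int>(bonds(b, 0)) - 1;
    int j = static_cast<int>(bonds(b, 1)) - 1;
    double ks = bonds(b, 2), rs = bonds(b, 3);
    double dx = min_image(P[i] - P[j], Lx);
    double dy = min_image(P[i + N] - P[j + N], Ly);
    double dz = min_image(P[i + 2 * N] - P[j + 2 * N], Lz);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    U += 0.5 * ks / rs * (r - rs) * (r - rs);
  }
  for (int t = 0; t < angles.nrow(); ++t) {
    int i = static_cast<int>(angles(t, 0)) - 1;
    int j = static_cast<int>(angles(t, 1)) - 1;
    int k = static_cast<int>(angles(t, 2)) - 1;
    double kth = angles(t, 3), th0 = angles(t, 4);
    double ux = min_image(P[i] - P[j], Lx);
    double uy = min_image(P[i + N] - P[j + N], Ly);
    double uz = min_image(P[i + 2 * N] - P[j + 2 * N], Lz);
    double wx = min_image(P[k] - P[j], Lx);
    double wy = min_image(P[k + N] - P[j + N], Ly);
    double wz = min_image(P[k + 2 * N] - P[j + 2 * N], Lz);
    double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
    double nw = std::sqrt(wx * wx + wy * wy + wz * wz);
    double c = (ux * wx + uy * wy + uz * wz) / (nu * nw);
    if (c > 1.0) c = 1.0;
    if (c < -1.0) c = -1.0;
    double th = std::acos(c);
    U += kth * (th - th0) * (th - th0);
  }
  return U;
}

// count pairs within rcut between two disjoint bead sets (1-based indices)
// [[Rcpp::export]]
int cpp_contacts(NumericMatrix pos, NumericVector box, IntegerVector setA,
                 IntegerVector setB, double rcut) {
  int N = pos.nrow();
  const double *P = pos.begin();
  double rc2 = rcut * rcut;
  int count = 0;
  for (int a = 0; a < setA.size(); ++a) {
    int i = setA[a] - 1;
    for (int b = 0; b < setB.size(); ++b) {
      int j = setB[b] - 1;
      double dx = min_image(P[i] - P[j], box[0]);
      double dy = min_image(P[i + N] - P[j + N], box[1]);
      double dz = min_image(P[i + 2 * N] - P[j + 2 * N], box[2]);
      if (dx * dx + dy * dy + dz * dz < rc2) ++count;
    }
  }
  return count;
}

// which candidate points lie farther than rcut from every occupied position
// [[Rcpp::export]]
LogicalVector cpp_free_points(NumericMatrix cand, NumericMatrix occ,
                              NumericVector box, double rcut) {
  int nc = cand.nrow(), no = occ.nrow();
  LogicalVector ok(nc, true);
  if (no == 0) return ok;
  double Lx = box[0], Ly = box[1], Lz = box[2];
  double rc2 = rcut * rcut;
  // grid over occupied positions, cell edge >= rcut
  int nx = std::max(1, static_cast<int>(std::floor(Lx / rcut)));
  int ny = std::max(1, static_cast<int>(std::floor(Ly / rcut)));
  int nz = std::max(1, static_cast<int>(std::floor(Lz / rcut)));
  std::vector<int> head(static_cast<size_t>(nx) * ny * nz, -1), nxt(no, -1);
  const double *O = occ.begin();
  for (int i = 0; i < no; ++i) {
    int cx = std::min(nx - 1, std::max(0, static_cast<int>(std::floor(O[i] / Lx * nx))));
    int cy = std::min(ny - 1, std::max(0, static_cast<int>(std::floor(O[i + no] / Ly * ny))));
    int cz = std::min(nz - 1, std::max(0, static_cast<int>(std::floor(O[i + 2 * no] / Lz * nz))));
    int c = cx + nx * (cy + ny * cz);
    nxt[i] = head[c];
    head[c] = i;
  }
  const double *C = cand.begin();
  for (int q = 0; q < nc; ++q) {
    double x = C[q], y = C[q + nc], z = C[q + 2 * nc];
    int cx = std::min(nx - 1, std::max(0, static_cast<int>(std::floor(x / Lx * nx))));
    int cy = std::min(ny - 1, std::max(0, static_cast<int>(std::floor(y / Ly * ny))));
    int cz = std::min(nz - 1, std::max(0, static_cast<int>(std::floor(z / Lz * nz))));
    bool free_pt = true;
    for (int ox = -1; ox <= 1 && free_pt; ++ox) {
      for (int oy = -1; oy <= 1 && free_pt; ++oy) {
        for (int oz = -1; oz <= 1 && free_pt; ++oz) {
          int gx = (cx + ox + nx) % nx, gy = (cy + oy + ny) % ny, gz = (cz + oz + nz) % nz;
          int c = gx + nx * (gy + ny * gz);
          for (int i = head[c]; i != -1; i = nxt[i]) {
            double dx = min_image(x - O[i], Lx);
            double dy = min_image(y - O[i + no], Ly);
            double dz = min_image(z - O[i + 2 * no], Lz);
            if (dx * dx + dy * dy + dz * dz < rc2) { free_pt = false; break; }
          }
        }
      }
    }
    ok[q] = free_pt;
  }
  return ok;
}

// noise samples for a fixed pair across consecutive steps (moment checks)
// [[Rcpp::export]]
NumericVector cpp_zeta_samples(double seed, int nsteps, int i, int j) {
  NumericVector out(nsteps);
  for (int s = 0; s < nsteps; ++s)
    out[s] = pair_zeta(static_cast<uint64_t>(seed),
                       static_cast<uint64_t>(s + 1), i - 1, j - 1);
  return out;
}
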