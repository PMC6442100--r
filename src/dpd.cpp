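// DPD core: pairwise soft forces with a dissipative/random thermostat,
// harmonic bonds, cell-list neighbor search, modified velocity-Verlet
// integration, and a periodic-boundary-aware percolation test used by the
// microstructure classifier. Single-threaded and bit-reproducible for a
// fixed seed.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

// splitmix64: small, fast, well-distributed; one stream per run.
struct SplitMix {
  uint64_t s;
  explicit SplitMix(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // symmetric noise, zero mean, unit variance (uniform on [-sqrt(3), sqrt(3)])
  double theta() { return (2.0 * unif() - 1.0) * 1.7320508075688772935; }
};

struct Pars {
  int n, ntype, nb;
  const double* a;       // ntype x ntype repulsion, column-major
  double L[3];
  double gamma, sigma, inv_sqrt_dt;
  const int* b1; const int* b2;  // 0-based bond partners
  double bond_k, bond_r0;
  bool use_random, use_diss;
};

inline double min_image(double d, double L) {
  if (d > 0.5 * L) d -= L;
  else if (d < -0.5 * L) d += L;
  return d;
}

inline void pair_interact(int i, int j, const double* x, const double* v,
                          const int* type, const Pars& p, SplitMix& rng,
                          double* f, double* W) {
  double dx[3];
  double r2 = 0.0;
  for (int d = 0; d < 3; ++d) {
    dx[d] = min_image(x[3 * i + d] - x[3 * j + d], p.L[d]);
    r2 += dx[d] * dx[d];
  }
  if (r2 >= 1.0 || r2 < 1e-20) return;   // r_c = 1; exact overlap has no direction
  double r = std::sqrt(r2);
  double w = 1.0 - r;
  double inv_r = 1.0 / r;
  double ex[3] = {dx[0] * inv_r, dx[1] * inv_r, dx[2] * inv_r};
  double aij = p.a[type[i] + p.ntype * type[j]];
  double fc = aij * w;                   // conservative magnitude
  double fmag = fc;
  if (p.use_diss) {
    double rv = ex[0] * (v[3 * i] - v[3 * j]) +
                ex[1] * (v[3 * i + 1] - v[3 * j + 1]) +
                ex[2] * (v[3 * i + 2] - v[3 * j + 2]);
    fmag -= p.gamma * w * w * rv;
  }
  if (p.use_random) fmag += p.sigma * w * rng.theta() * p.inv_sqrt_dt;
  for (int d = 0; d < 3; ++d) {
    double fd = fmag * ex[d];
    f[3 * i + d] += fd;
    f[3 * j + d] -= fd;
    W[d] += fc * ex[d] * dx[d];          // conservative virial only
  }
}

void bond_forces(const double* x, const Pars& p, double* f, double* W) {
  for (int b = 0; b < p.nb; ++b) {
    int i = p.b1[b], j = p.b2[b];
    double dx[3];
    double r2 = 0.0;
    for (int d = 0; d < 3; ++d) {
      dx[d] = min_image(x[3 * i + d] - x[3 * j + d], p.L[d]);
      r2 += dx[d] * dx[d];
    }
    double r = std::sqrt(r2);
    if (r < 1e-20) continue;
    double fmag = -p.bond_k * (r - p.bond_r0);
    double inv_r = 1.0 / r;
    for (int d = 0; d < 3; ++d) {
      double fd = fmag * dx[d] * inv_r;
      f[3 * i + d] += fd;
      f[3 * j + d] -= fd;
      W[d] += fd * dx[d];
    }
  }
}

// forces + conservative virial diagonal; cell list when the box allows >= 3
// cells per axis, otherwise all-pairs.
void compute_forces(const double* x, const double* v, const int* type,
                    const Pars& p, SplitMix& rng, double* f, double* W) {
  std::fill(f, f + 3 * p.n, 0.0);
  W[0] = W[1] = W[2] = 0.0;
  int nc[3];
  bool cells_ok = true;
  for (int d = 0; d < 3; ++d) {
    nc[d] = (int)std::floor(p.L[d]);
    if (nc[d] < 3) cells_ok = false;
  }
  if (!cells_ok) {
    for (int i = 0; i < p.n; ++i)
      for (int j = i + 1; j < p.n; ++j)
        pair_interact(i, j, x, v, type, p, rng, f, W);
  } else {
    int ncell = nc[0] * nc[1] * nc[2];
    std::vector<int> head(ncell, -1), nxt(p.n, -1);
    for (int i = 0; i < p.n; ++i) {
      int c[3];
      for (int d = 0; d < 3; ++d) {
        c[d] = (int)(x[3 * i + d] / p.L[d] * nc[d]);
        if (c[d] >= nc[d]) c[d] = nc[d] - 1;
        if (c[d] < 0) c[d] = 0;
      }
      int ci = c[0] + nc[0] * (c[1] + nc[1] * c[2]);
      nxt[i] = head[ci];
      head[ci] = i;
    }
    // half stencil: self + 13 neighbors
    static const int off[14][3] = {
      {0,0,0},{1,0,0},{-1,1,0},{0,1,0},{1,1,0},{-1,-1,1},{0,-1,1},{1,-1,1},
      {-1,0,1},{0,0,1},{1,0,1},{-1,1,1},{0,1,1},{1,1,1}};
    for (int cz = 0; cz < nc[2]; ++cz)
      for (int cy = 0; cy < nc[1]; ++cy)
        for (int cx = 0; cx < nc[0]; ++cx) {
          int ci = cx + nc[0] * (cy + nc[1] * cz);
          for (int s = 0; s < 14; ++s) {
            int ox = (cx + off[s][0] + nc[0]) % nc[0];
            int oy = (cy + off[s][1] + nc[1]) % nc[1];
            int oz = (cz + off[s][2] + nc[2]) % nc[2];
            int cj = ox + nc[0] * (oy + nc[1] * oz);
            for (int i = head[ci]; i >= 0; i = nxt[i]) {
              int jstart = (s == 0) ? nxt[i] : head[cj];
              for (int j = jstart; j >= 0; j = nxt[j])
                pair_interact(i, j, x, v, type, p, rng, f, W);
            }
          }
        }
  }
  bond_forces(x, p, f, W);
}

}  // namespace

// [[Rcpp::export]]
List dpd_forces_cpp(NumericMatrix pos, NumericMatrix vel, IntegerVector type,
                    IntegerMatrix bonds, NumericVector box, NumericMatrix arep,
                    double gamma, double sigma, double dt,
                    double bond_k, double bond_r0,
                    bool use_diss, bool use_random, double seed) {
  int n = pos.nrow();
  Pars p;
  p.n = n;
  p.ntype = arep.nrow();
  p.a = arep.begin();
  for (int d = 0; d < 3; ++d) p.L[d] = box[d];
  p.gamma = gamma; p.sigma = sigma;
  p.inv_sqrt_dt = 1.0 / std::sqrt(dt);
  p.nb = bonds.nrow();
  std::vector<int> b1(p.nb), b2(p.nb);
  for (int b = 0; b < p.nb; ++b) { b1[b] = bonds(b, 0); b2[b] = bonds(b, 1); }
  p.b1 = b1.data(); p.b2 = b2.data();
  p.bond_k = bond_k; p.bond_r0 = bond_r0;
  p.use_random = use_random; p.use_diss = use_diss;
  SplitMix rng((uint64_t)seed + 0x5DEECE66DULL);
  // row-major copies for locality
  std::vector<double> x(3 * n), v(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) { x[3*i+d] = pos(i, d); v[3*i+d] = vel(i, d); }
  double W[3];
  compute_forces(x.data(), v.data(), type.begin(), p, rng, f.data(), W);
  NumericMatrix F(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) F(i, d) = f[3*i+d];
  return List::create(_["forces"] = F,
                      _["virial"] = NumericVector::create(W[0], W[1], W[2]));
}

// [[Rcpp::export]]
List dpd_run_cpp(NumericMatrix pos, NumericMatrix vel, IntegerVector type,
                 IntegerMatrix bonds, NumericVector box, NumericMatrix arep,
                 double gamma, double sigma, double dt, double lambda,
                 double bond_k, double bond_r0,
                 int n_steps, int equil_steps, int sample_every,
                 double seed, bool store_velocities) {
  int n = pos.nrow();
  Pars p;
  p.n = n;
  p.ntype = arep.nrow();
  p.a = arep.begin();
  for (int d = 0; d < 3; ++d) p.L[d] = box[d];
  p.gamma = gamma; p.sigma = sigma;
  p.inv_sqrt_dt = 1.0 / std::sqrt(dt);
  p.nb = bonds.nrow();
  std::vector<int> b1(p.nb), b2(p.nb);
  for (int b = 0; b < p.nb; ++b) { b1[b] = bonds(b, 0); b2[b] = bonds(b, 1); }
  p.b1 = b1.data(); p.b2 = b2.data();
  p.bond_k = bond_k; p.bond_r0 = bond_r0;
  p.use_random = (sigma > 0.0); p.use_diss = (gamma > 0.0);
  SplitMix rng((uint64_t)seed + 0x5DEECE66DULL);

  std::vector<double> x(3 * n), xu(3 * n), v(3 * n), vp(3 * n),
      f(3 * n), fn(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      x[3*i+d] = pos(i, d); xu[3*i+d] = pos(i, d); v[3*i+d] = vel(i, d);
    }
  double W[3];
  compute_forces(x.data(), v.data(), type.begin(), p, rng, f.data(), W);

  int total = equil_steps + n_steps;
  int nframes = (sample_every > 0) ? n_steps / sample_every : 0;
  NumericVector times(nframes), Tkin(nframes);
  NumericMatrix Pdiag(nframes, 3), Mom(nframes, 3);
  List posw(nframes), posu(nframes), vels(nframes);
  double half_dt = 0.5 * dt, half_dt2 = 0.5 * dt * dt;
  double V = p.L[0] * p.L[1] * p.L[2];
  int fr = 0;

  for (int step = 1; step <= total; ++step) {
    for (int i = 0; i < 3 * n; ++i) {
      double dr = dt * v[i] + half_dt2 * f[i];
      x[i] += dr;
      xu[i] += dr;
      vp[i] = v[i] + lambda * dt * f[i];
    }
    // wrap
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) {
        double& xi = x[3*i+d];
        xi -= p.L[d] * std::floor(xi / p.L[d]);
        if (xi >= p.L[d]) xi = 0.0;
        if (!std::isfinite(xi))
          stop("non-finite coordinate at step %d", step);
      }
    compute_forces(x.data(), vp.data(), type.begin(), p, rng, fn.data(), W);
    for (int i = 0; i < 3 * n; ++i) {
      v[i] += half_dt * (f[i] + fn[i]);
      f[i] = fn[i];
    }
    if (step > equil_steps && sample_every > 0 &&
        (step - equil_steps) % sample_every == 0 && fr < nframes) {
      double ke2 = 0.0, mom[3] = {0, 0, 0}, kdiag[3] = {0, 0, 0};
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d) {
          double vd = v[3*i+d];
          ke2 += vd * vd;
          kdiag[d] += vd * vd;
          mom[d] += vd;
        }
      times[fr] = step * dt;
      Tkin[fr] = ke2 / (3.0 * n);
      for (int d = 0; d < 3; ++d) {
        Pdiag(fr, d) = (kdiag[d] + W[d]) / V;
        Mom(fr, d) = mom[d];
      }
      NumericMatrix pw(n, 3), pu(n, 3);
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d) { pw(i, d) = x[3*i+d]; pu(i, d) = xu[3*i+d]; }
      posw[fr] = pw; posu[fr] = pu;
      if (store_velocities) {
        NumericMatrix vm(n, 3);
        for (int i = 0; i < n; ++i)
          for (int d = 0; d < 3; ++d) vm(i, d) = v[3*i+d];
        vels[fr] = vm;
      }
      ++fr;
    }
    if (step % 500 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(
      _["times"] = times, _["kinetic_T"] = Tkin, _["pressure"] = Pdiag,
      _["momentum"] = Mom, _["positions_wrapped"] = posw,
      _["positions"] = posu,
      _["velocities"] = store_velocities ? (RObject)vels : (RObject)R_NilValue);
}

// Does the occupied set span the box along `axis` (1..3)? 6-connectivity,
// periodic wrap in the two transverse axes, open along the tested axis.
// [[Rcpp::export]]
bool percolates_cpp(LogicalVector grid, IntegerVector dims, int axis) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  int ax = axis - 1;
  int nd[3] = {nx, ny, nz};
  std::vector<char> occ(n), vis(n, 0);
  for (int i = 0; i < n; ++i) occ[i] = grid[i] ? 1 : 0;
  auto idx = [&](int i, int j, int k) { return i + nx * (j + ny * k); };
  std::vector<int> stack;
  // seed from layer 0 along the tested axis
  int nlay = nd[ax];
  if (nlay < 2) return false;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int c[3] = {i, j, k};
        if (c[ax] != 0) continue;
        int id = idx(i, j, k);
        if (occ[id] && !vis[id]) { vis[id] = 1; stack.push_back(id); }
      }
  bool reached = false;
  while (!stack.empty()) {
    int id = stack.back(); stack.pop_back();
    int i = id % nx, j = (id / nx) % ny, k = id / (nx * ny);
    int c[3] = {i, j, k};
    if (c[ax] == nlay - 1) reached = true;
    for (int d = 0; d < 3; ++d)
      for (int s = -1; s <= 1; s += 2) {
        int nb[3] = {c[0], c[1], c[2]};
        nb[d] += s;
        if (d == ax) {
          if (nb[d] < 0 || nb[d] >= nd[d]) continue;   // open boundary
        } else {
          nb[d] = (nb[d] + nd[d]) % nd[d];             // periodic
        }
        int nid = idx(nb[0], nb[1], nb[2]);
        if (occ[nid] && !vis[nid]) { vis[nid] = 1; stack.push_back(nid); }
      }
  }
  return reached;
}
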