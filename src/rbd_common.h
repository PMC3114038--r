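#ifndef RBD_COMMON_H
#define RBD_COMMON_H

#include <Rcpp.h>
#include <vector>
#include <cmath>

// Coulomb constant in kcal*A/mol/e^2
static const double RBD_COULOMB = 332.0636;

struct Grid {
  const double* v = nullptr;
  int nx = 0, ny = 0, nz = 0;
  double ox = 0, oy = 0, oz = 0;
  double hx = 1.0, hy = 1.0, hz = 1.0;  // per-axis spacing
  bool periodic_xy = false;             // tile-periodic in x and y
  bool empty() const { return v == nullptr; }

  inline double at(int i, int j, int k) const {
    return v[i + (size_t)nx * (j + (size_t)ny * k)];
  }

  // Trilinear interpolation; returns `outside` when the point is out of
  // bounds (non-periodic axes only). For periodic grids the tile period is
  // nx*hx (no duplicated endpoint node).
  inline double interp(double x, double y, double z, double outside) const {
    double fx, fy, fz;
    int i0, j0, k0, i1, j1;
    if (periodic_xy) {
      double rx = (x - ox) / hx; rx -= nx * std::floor(rx / nx);
      double ry = (y - oy) / hy; ry -= ny * std::floor(ry / ny);
      i0 = (int)std::floor(rx); fx = rx - i0; i0 %= nx; if (i0 < 0) i0 += nx;
      j0 = (int)std::floor(ry); fy = ry - j0; j0 %= ny; if (j0 < 0) j0 += ny;
      i1 = (i0 + 1) % nx; j1 = (j0 + 1) % ny;
    } else {
      double rx = (x - ox) / hx, ry = (y - oy) / hy;
      if (rx < 0 || rx > nx - 1 || ry < 0 || ry > ny - 1) return outside;
      i0 = (int)std::floor(rx); if (i0 > nx - 2) i0 = nx - 2;
      j0 = (int)std::floor(ry); if (j0 > ny - 2) j0 = ny - 2;
      fx = rx - i0; fy = ry - j0; i1 = i0 + 1; j1 = j0 + 1;
    }
    double rz = (z - oz) / hz;
    if (rz < 0 || rz > nz - 1) return outside;
    k0 = (int)std::floor(rz); if (k0 > nz - 2) k0 = nz - 2;
    fz = rz - k0;
    int k1 = k0 + 1;
    double c00 = at(i0, j0, k0) * (1 - fx) + at(i1, j0, k0) * fx;
    double c10 = at(i0, j1, k0) * (1 - fx) + at(i1, j1, k0) * fx;
    double c01 = at(i0, j0, k1) * (1 - fx) + at(i1, j0, k1) * fx;
    double c11 = at(i0, j1, k1) * (1 - fx) + at(i1, j1, k1) * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    return c0 * (1 - fz) + c1 * fz;
  }

  // value and gradient of the trilinear interpolant (the exact derivative of
  // the interpolated field, i.e. the h -> 0 limit of central differences of
  // the grid-mapped energy). Outside the grid both are `outside`/zero.
  inline double interp_grad(double x, double y, double z, double outside,
                            double* g) const {
    g[0] = g[1] = g[2] = 0;
    double fx, fy, fz;
    int i0, j0, k0, i1, j1;
    if (periodic_xy) {
      double rx = (x - ox) / hx; rx -= nx * std::floor(rx / nx);
      double ry = (y - oy) / hy; ry -= ny * std::floor(ry / ny);
      i0 = (int)std::floor(rx); fx = rx - i0; i0 %= nx; if (i0 < 0) i0 += nx;
      j0 = (int)std::floor(ry); fy = ry - j0; j0 %= ny; if (j0 < 0) j0 += ny;
      i1 = (i0 + 1) % nx; j1 = (j0 + 1) % ny;
    } else {
      double rx = (x - ox) / hx, ry = (y - oy) / hy;
      if (rx < 0 || rx > nx - 1 || ry < 0 || ry > ny - 1) return outside;
      i0 = (int)std::floor(rx); if (i0 > nx - 2) i0 = nx - 2;
      j0 = (int)std::floor(ry); if (j0 > ny - 2) j0 = ny - 2;
      fx = rx - i0; fy = ry - j0; i1 = i0 + 1; j1 = j0 + 1;
    }
    double rz = (z - oz) / hz;
    if (rz < 0 || rz > nz - 1) return outside;
    k0 = (int)std::floor(rz); if (k0 > nz - 2) k0 = nz - 2;
    fz = rz - k0;
    int k1 = k0 + 1;
    double v000 = at(i0, j0, k0), v100 = at(i1, j0, k0);
    double v010 = at(i0, j1, k0), v110 = at(i1, j1, k0);
    double v001 = at(i0, j0, k1), v101 = at(i1, j0, k1);
    double v011 = at(i0, j1, k1), v111 = at(i1, j1, k1);
    double c00 = v000 * (1 - fx) + v100 * fx;
    double c10 = v010 * (1 - fx) + v110 * fx;
    double c01 = v001 * (1 - fx) + v101 * fx;
    double c11 = v011 * (1 - fx) + v111 * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    g[0] = ((v100 - v000) * (1 - fy) * (1 - fz) + (v110 - v010) * fy * (1 - fz) +
            (v101 - v001) * (1 - fy) * fz + (v111 - v011) * fy * fz) / hx;
    g[1] = ((c10 - c00) * (1 - fz) + (c11 - c01) * fz) / hy;
    g[2] = (c1 - c0) / hz;
    return c0 * (1 - fz) + c1 * fz;
  }
};

struct SpeciesData {
  int n_atoms = 0;
  std::vector<double> ax, ay, az, arad, asasa;
  int n_charges = 0;
  std::vector<double> qx, qy, qz, qq;
  Grid el, ed, np, sc;
  double bound_radius = 0;   // max atom |r| + radius
  double half_extent = 0;    // largest grid half-extent
  double d_trans = 0, d_rot = 0;
  std::vector<int> patch_idx;       // atoms with sasa > 0
  bool npsc_same = false;           // np and sc share grid geometry
  bool eled_same = false;           // el and ed share grid geometry
  double cube_npsc = 0;             // half-extent of the np/sc cubes
  double cube_eled = 0;
};

// quaternion (w,x,y,z) -> rotation matrix, row-major 3x3 (body -> lab)
inline void quat_to_mat(const double* q, double* R) {
  double w = q[0], x = q[1], y = q[2], z = q[3];
  R[0] = 1 - 2 * (y * y + z * z); R[1] = 2 * (x * y - w * z); R[2] = 2 * (x * z + w * y);
  R[3] = 2 * (x * y + w * z); R[4] = 1 - 2 * (x * x + z * z); R[5] = 2 * (y * z - w * x);
  R[6] = 2 * (x * z - w * y); R[7] = 2 * (y * z + w * x); R[8] = 1 - 2 * (x * x + y * y);
}

inline void quat_mult(const double* a, const double* b, double* out) {
  out[0] = a[0] * b[0] - a[1] * b[1] - a[2] * b[2] - a[3] * b[3];
  out[1] = a[0] * b[1] + a[1] * b[0] + a[2] * b[3] - a[3] * b[2];
  out[2] = a[0] * b[2] - a[1] * b[3] + a[2] * b[0] + a[3] * b[1];
  out[3] = a[0] * b[3] + a[1] * b[2] - a[2] * b[1] + a[3] * b[0];
}

inline void quat_normalize(double* q) {
  double n = std::sqrt(q[0] * q[0] + q[1] * q[1] + q[2] * q[2] + q[3] * q[3]);
  for (int i = 0; i < 4; ++i) q[i] /= n;
}

// small rotation vector (body frame) composed onto q (right-multiplication)
inline void quat_compose_rotvec(double* q, const double* dth) {
  double ang = std::sqrt(dth[0] * dth[0] + dth[1] * dth[1] + dth[2] * dth[2]);
  double dq[4];
  if (ang < 1e-12) { dq[0] = 1; dq[1] = dq[2] = dq[3] = 0; }
  else {
    double s = std::sin(ang / 2) / ang;
    dq[0] = std::cos(ang / 2); dq[1] = dth[0] * s; dq[2] = dth[1] * s; dq[3] = dth[2] * s;
  }
  double out[4];
  quat_mult(q, dq, out);
  for (int i = 0; i < 4; ++i) q[i] = out[i];
  quat_normalize(q);
}

// shared cell lookup on a non-periodic grid geometry
inline bool grid_cell(const Grid& g, double x, double y, double z,
                      size_t& base, double& fx, double& fy, double& fz) {
  double rx = (x - g.ox) / g.hx, ry = (y - g.oy) / g.hy, rz = (z - g.oz) / g.hz;
  if (rx < 0 || rx > g.nx - 1 || ry < 0 || ry > g.ny - 1 ||
      rz < 0 || rz > g.nz - 1) return false;
  int i0 = (int)rx; if (i0 > g.nx - 2) i0 = g.nx - 2;
  int j0 = (int)ry; if (j0 > g.ny - 2) j0 = g.ny - 2;
  int k0 = (int)rz; if (k0 > g.nz - 2) k0 = g.nz - 2;
  fx = rx - i0; fy = ry - j0; fz = rz - k0;
  base = i0 + (size_t)g.nx * (j0 + (size_t)g.ny * k0);
  return true;
}

// accumulate w * gradient of g's trilinear interpolant at a precomputed cell
inline void cell_grad(const Grid& g, size_t base, double fx, double fy,
                      double fz, double w, double* gs) {
  const double* v = g.v;
  size_t sy = g.nx, sz = (size_t)g.nx * g.ny;
  double v000 = v[base], v100 = v[base + 1];
  double v010 = v[base + sy], v110 = v[base + 1 + sy];
  double v001 = v[base + sz], v101 = v[base + 1 + sz];
  double v011 = v[base + sy + sz], v111 = v[base + 1 + sy + sz];
  double gx = ((v100 - v000) * (1 - fy) + (v110 - v010) * fy) * (1 - fz) +
              ((v101 - v001) * (1 - fy) + (v111 - v011) * fy) * fz;
  double c00 = v000 * (1 - fx) + v100 * fx, c10 = v010 * (1 - fx) + v110 * fx;
  double c01 = v001 * (1 - fx) + v101 * fx, c11 = v011 * (1 - fx) + v111 * fx;
  double gy = (c10 - c00) * (1 - fz) + (c11 - c01) * fz;
  double gz = (c01 * (1 - fy) + c11 * fy) - (c00 * (1 - fy) + c10 * fy);
  gs[0] += w * gx / g.hx;
  gs[1] += w * gy / g.hy;
  gs[2] += w * gz / g.hz;
}

inline bool same_geometry(const Grid& a, const Grid& b) {
  return !a.empty() && !b.empty() && !a.periodic_xy && !b.periodic_xy &&
    a.nx == b.nx && a.ny == b.ny && a.nz == b.nz &&
    a.ox == b.ox && a.oy == b.oy && a.oz == b.oz &&
    a.hx == b.hx && a.hy == b.hy && a.hz == b.hz;
}

inline double grid_cube(const Grid& g) {
  if (g.empty()) return 0;
  double m = 0;
  m = std::max(m, std::max(std::fabs(g.ox), std::fabs(g.ox + (g.nx - 1) * g.hx)));
  m = std::max(m, std::max(std::fabs(g.oy), std::fabs(g.oy + (g.ny - 1) * g.hy)));
  m = std::max(m, std::max(std::fabs(g.oz), std::fabs(g.oz + (g.nz - 1) * g.hz)));
  return m;
}

Grid grid_from_list(Rcpp::List g);
SpeciesData species_from_list(Rcpp::List sp);

#endif
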