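#include "rbd_common.h"
using namespace Rcpp;

Grid grid_from_list(List g) {
  Grid out;
  if (g.size() == 0) return out;
  NumericVector v = g["values"];
  IntegerVector dims = g["dims"];
  NumericVector origin = g["origin"];
  out.v = REAL(v);
  out.nx = dims[0]; out.ny = dims[1]; out.nz = dims[2];
  out.ox = origin[0]; out.oy = origin[1]; out.oz = origin[2];
  NumericVector h = g["spacing"];
  if (h.size() == 1) { out.hx = out.hy = out.hz = h[0]; }
  else { out.hx = h[0]; out.hy = h[1]; out.hz = h[2]; }
  out.periodic_xy = g.containsElementNamed("periodic_xy") &&
    as<bool>(g["periodic_xy"]);
  return out;
}

SpeciesData species_from_list(List sp) {
  SpeciesData s;
  NumericMatrix apos = sp["apos"];       // n x 3, body frame
  NumericVector arad = sp["arad"], asasa = sp["asasa"];
  s.n_atoms = apos.nrow();
  s.ax.resize(s.n_atoms); s.ay.resize(s.n_atoms); s.az.resize(s.n_atoms);
  s.arad.assign(arad.begin(), arad.end());
  s.asasa.assign(asasa.begin(), asasa.end());
  for (int i = 0; i < s.n_atoms; ++i) {
    s.ax[i] = apos(i, 0); s.ay[i] = apos(i, 1); s.az[i] = apos(i, 2);
  }
  NumericMatrix cpos = sp["cpos"];
  NumericVector q = sp["q"];
  s.n_charges = cpos.nrow();
  s.qx.resize(s.n_charges); s.qy.resize(s.n_charges); s.qz.resize(s.n_charges);
  s.qq.assign(q.begin(), q.end());
  for (int i = 0; i < s.n_charges; ++i) {
    s.qx[i] = cpos(i, 0); s.qy[i] = cpos(i, 1); s.qz[i] = cpos(i, 2);
  }
  List grids = sp["grids"];
  if (grids.containsElementNamed("el")) s.el = grid_from_list(grids["el"]);
  if (grids.containsElementNamed("ed")) s.ed = grid_from_list(grids["ed"]);
  if (grids.containsElementNamed("np")) s.np = grid_from_list(grids["np"]);
  if (grids.containsElementNamed("sc")) s.sc = grid_from_list(grids["sc"]);
  s.bound_radius = as<double>(sp["bound_radius"]);
  s.half_extent = as<double>(sp["half_extent"]);
  s.d_trans = as<double>(sp["d_trans"]);
  s.d_rot = as<double>(sp["d_rot"]);
  for (int i = 0; i < s.n_atoms; ++i)
    if (s.asasa[i] > 0) s.patch_idx.push_back(i);
  s.npsc_same = same_geometry(s.np, s.sc);
  s.eled_same = same_geometry(s.el, s.ed);
  s.cube_npsc = std::max(grid_cube(s.np), grid_cube(s.sc));
  s.cube_eled = std::max(grid_cube(s.el), grid_cube(s.ed));
  return s;
}

static inline void node_xyz(size_t idx, const IntegerVector& dims,
                            const NumericVector& origin,
                            const NumericVector& h,
                            double& x, double& y, double& z) {
  size_t nx = dims[0], ny = dims[1];
  size_t i = idx % nx, j = (idx / nx) % ny, k = idx / (nx * ny);
  double hx = h[0], hy = h.size() == 1 ? h[0] : h[1],
         hz = h.size() == 1 ? h[0] : h[2];
  x = origin[0] + i * hx; y = origin[1] + j * hy; z = origin[2] + k * hz;
}

// Debye-Hueckel screened Coulomb superposition over point charges.
// [[Rcpp::export]]
NumericVector cpp_grid_el(NumericMatrix sites, NumericVector q,
                          NumericVector origin, NumericVector spacing,
                          IntegerVector dims, double kappa, double eps_s,
                          double clamp_d) {
  size_t n = (size_t)dims[0] * dims[1] * dims[2];
  NumericVector out((R_xlen_t)n);
  int ns = sites.nrow();
  for (size_t idx = 0; idx < n; ++idx) {
    double x, y, z, v = 0;
    node_xyz(idx, dims, origin, spacing, x, y, z);
    for (int s = 0; s < ns; ++s) {
      double dx = x - sites(s, 0), dy = y - sites(s, 1), dz = z - sites(s, 2);
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d < clamp_d) d = clamp_d;
      v += q[s] * RBD_COULOMB * std::exp(-kappa * d) / (eps_s * d);
    }
    out[idx] = v;
  }
  return out;
}

// Electrostatic desolvation penalty field acting on squared partner charges:
// alpha * (eps_s - eps_p) / (eps_s * (2 eps_s + eps_p)) *
//   sum_i a_i^3 exp(-2 kappa d_i) / d_i^4,  d_i clamped at a_i inside atoms.
// [[Rcpp::export]]
NumericVector cpp_grid_ed(NumericMatrix apos, NumericVector arad,
                          NumericVector origin, NumericVector spacing,
                          IntegerVector dims, double kappa, double eps_s,
                          double eps_p, double alpha) {
  size_t n = (size_t)dims[0] * dims[1] * dims[2];
  NumericVector out((R_xlen_t)n);
  int na = apos.nrow();
  double pref = alpha * RBD_COULOMB * (eps_s - eps_p) /
    (eps_s * (2 * eps_s + eps_p));
  for (size_t idx = 0; idx < n; ++idx) {
    double x, y, z, v = 0;
    node_xyz(idx, dims, origin, spacing, x, y, z);
    for (int i = 0; i < na; ++i) {
      double dx = x - apos(i, 0), dy = y - apos(i, 1), dz = z - apos(i, 2);
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d < arad[i]) d = arad[i];
      double a3 = arad[i] * arad[i] * arad[i];
      v += a3 * std::exp(-2 * kappa * d) / (d * d * d * d);
    }
    out[idx] = pref * v;
  }
  return out;
}

// Non-polar desolvation field: beta * burial fraction b(r), with b = 1 inside
// the solvent-excluded region and a linear ramp to 0 over `ramp` angstroms
// beyond the closest atom surface.
// [[Rcpp::export]]
NumericVector cpp_grid_np(NumericMatrix apos, NumericVector arad,
                          NumericVector origin, NumericVector spacing,
                          IntegerVector dims, double beta, double ramp) {
  size_t n = (size_t)dims[0] * dims[1] * dims[2];
  NumericVector out((R_xlen_t)n);
  int na = apos.nrow();
  for (size_t idx = 0; idx < n; ++idx) {
    double x, y, z;
    node_xyz(idx, dims, origin, spacing, x, y, z);
    double dmin = R_PosInf;
    for (int i = 0; i < na; ++i) {
      double dx = x - apos(i, 0), dy = y - apos(i, 1), dz = z - apos(i, 2);
      double d = std::sqrt(dx * dx + dy * dy + dz * dz) - arad[i];
      if (d < dmin) dmin = d;
    }
    double b = (dmin <= 0) ? 1.0 : (dmin >= ramp ? 0.0 : 1.0 - dmin / ramp);
    out[idx] = beta * b;
  }
  return out;
}

// Soft-core repulsion: gamma * sum_i a_i^nexp / (d^nexp + sigma^nexp).
// [[Rcpp::export]]
NumericVector cpp_grid_sc(NumericMatrix apos, NumericVector arad,
                          NumericVector origin, NumericVector spacing,
                          IntegerVector dims, double gamma, double sigma,
                          int nexp) {
  size_t n = (size_t)dims[0] * dims[1] * dims[2];
  NumericVector out((R_xlen_t)n);
  int na = apos.nrow();
  double sig_n = std::pow(sigma, nexp);
  std::vector<double> a_n(na);
  for (int i = 0; i < na; ++i) a_n[i] = std::pow((double)arad[i], nexp);
  for (size_t idx = 0; idx < n; ++idx) {
    double x, y, z, v = 0;
    node_xyz(idx, dims, origin, spacing, x, y, z);
    for (int i = 0; i < na; ++i) {
      double dx = x - apos(i, 0), dy = y - apos(i, 1), dz = z - apos(i, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      double dn = std::pow(d2, nexp / 2.0);
      v += a_n[i] / (dn + sig_n);
    }
    out[idx] = gamma * v;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_trilinear(List grid, NumericMatrix points, double outside) {
  Grid g = grid_from_list(grid);
  int n = points.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = g.interp(points(i, 0), points(i, 1), points(i, 2), outside);
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_in_grid(List grid, NumericMatrix points) {
  Grid g = grid_from_list(grid);
  int n = points.nrow();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    double x = points(i, 0), y = points(i, 1), z = points(i, 2);
    bool ok = true;
    if (!g.periodic_xy) {
      ok = ok && x >= g.ox && x <= g.ox + (g.nx - 1) * g.hx;
      ok = ok && y >= g.oy && y <= g.oy + (g.ny - 1) * g.hy;
    }
    ok = ok && z >= g.oz && z <= g.oz + (g.nz - 1) * g.hz;
    out[i] = ok;
  }
  return out;
}
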