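#include "rbd_common.h"
using namespace Rcpp;

// Pairwise interaction free energy, grid-mapped form. Fields of the grid
// owner are evaluated at the partner's sites after transforming those sites
// into the owner's body frame. The electrostatic potential term carries the
// usual factor 1/2 on each half-sum; desolvation and soft-core terms are
// summed once per direction.
static void pair_energy_halves(const SpeciesData& s1, const double* c1,
                               const double* R1, const SpeciesData& s2,
                               const double* c2, const double* R2,
                               double* terms) {
  // terms: el1,ed1,np1,sc1, el2,ed2,np2,sc2
  for (int t = 0; t < 8; ++t) terms[t] = 0;
  for (int dir = 0; dir < 2; ++dir) {
    const SpeciesData& own = dir == 0 ? s1 : s2;
    const SpeciesData& par = dir == 0 ? s2 : s1;
    const double* co = dir == 0 ? c1 : c2;
    const double* cp = dir == 0 ? c2 : c1;
    const double* Ro = dir == 0 ? R1 : R2;
    const double* Rp = dir == 0 ? R2 : R1;
    double* T = terms + 4 * dir;
    // charge sites of partner in owner frame
    if ((!own.el.empty() || !own.ed.empty()) && par.n_charges > 0) {
      for (int s = 0; s < par.n_charges; ++s) {
        double bx = par.qx[s], by = par.qy[s], bz = par.qz[s];
        double lx = cp[0] + Rp[0] * bx + Rp[1] * by + Rp[2] * bz - co[0];
        double ly = cp[1] + Rp[3] * bx + Rp[4] * by + Rp[5] * bz - co[1];
        double lz = cp[2] + Rp[6] * bx + Rp[7] * by + Rp[8] * bz - co[2];
        double ux = Ro[0] * lx + Ro[3] * ly + Ro[6] * lz;
        double uy = Ro[1] * lx + Ro[4] * ly + Ro[7] * lz;
        double uz = Ro[2] * lx + Ro[5] * ly + Ro[8] * lz;
        double q = par.qq[s];
        if (q != 0 && !own.el.empty())
          T[0] += 0.5 * own.el.interp(ux, uy, uz, 0.0) * q;
        if (!own.ed.empty())
          T[1] += own.ed.interp(ux, uy, uz, 0.0) * q * q;
      }
    }
    if (!own.np.empty() || !own.sc.empty()) {
      for (int a = 0; a < par.n_atoms; ++a) {
        double bx = par.ax[a], by = par.ay[a], bz = par.az[a];
        double lx = cp[0] + Rp[0] * bx + Rp[1] * by + Rp[2] * bz - co[0];
        double ly = cp[1] + Rp[3] * bx + Rp[4] * by + Rp[5] * bz - co[1];
        double lz = cp[2] + Rp[6] * bx + Rp[7] * by + Rp[8] * bz - co[2];
        double ux = Ro[0] * lx + Ro[3] * ly + Ro[6] * lz;
        double uy = Ro[1] * lx + Ro[4] * ly + Ro[7] * lz;
        double uz = Ro[2] * lx + Ro[5] * ly + Ro[8] * lz;
        if (!own.np.empty() && par.asasa[a] > 0)
          T[2] += own.np.interp(ux, uy, uz, 0.0) * par.asasa[a];
        if (!own.sc.empty())
          T[3] += own.sc.interp(ux, uy, uz, 0.0);
      }
    }
  }
}

// Gradient-based forces/torques of one pair, accumulated into F (lab frame,
// kcal/mol/A) and T (body frame of each body, kcal/mol). This is the exact
// derivative of the trilinearly interpolated pair energy (the h -> 0 limit
// of the central finite differences).
static void accum_pair_forces_grad(const SpeciesData& s1, const double* c1,
                                   const double* R1, const SpeciesData& s2,
                                   const double* c2, const double* R2,
                                   double* F1, double* T1,
                                   double* F2, double* T2) {
  for (int dir = 0; dir < 2; ++dir) {
    const SpeciesData& own = dir == 0 ? s1 : s2;
    const SpeciesData& par = dir == 0 ? s2 : s1;
    const double* co = dir == 0 ? c1 : c2;
    const double* cp = dir == 0 ? c2 : c1;
    const double* Ro = dir == 0 ? R1 : R2;
    const double* Rp = dir == 0 ? R2 : R1;
    double* Fo = dir == 0 ? F1 : F2;
    double* To = dir == 0 ? T1 : T2;
    double* Fp = dir == 0 ? F2 : F1;
    double* Tp = dir == 0 ? T2 : T1;

    // u = M b + t maps partner body-frame sites into the owner frame;
    // M = Ro^T Rp, t = Ro^T (cp - co). M^T gs gives the partner-frame
    // gradient used for its torque.
    double dx = cp[0] - co[0], dy = cp[1] - co[1], dz = cp[2] - co[2];
    double t0 = Ro[0] * dx + Ro[3] * dy + Ro[6] * dz;
    double t1 = Ro[1] * dx + Ro[4] * dy + Ro[7] * dz;
    double t2 = Ro[2] * dx + Ro[5] * dy + Ro[8] * dz;
    double M[9];
    for (int r = 0; r < 3; ++r)
      for (int c = 0; c < 3; ++c)
        M[3 * r + c] = Ro[r] * Rp[c] + Ro[3 + r] * Rp[3 + c] +
                       Ro[6 + r] * Rp[6 + c];
    double Fsum[3] = {0, 0, 0};

    // accumulate one site's owner-frame gradient gs at owner-frame point u
    auto add = [&](double bx, double by, double bz,
                   double ux, double uy, double uz, const double* gs) {
      Fsum[0] += gs[0]; Fsum[1] += gs[1]; Fsum[2] += gs[2];
      To[0] += uy * gs[2] - uz * gs[1];
      To[1] += uz * gs[0] - ux * gs[2];
      To[2] += ux * gs[1] - uy * gs[0];
      double p0 = M[0] * gs[0] + M[3] * gs[1] + M[6] * gs[2];
      double p1 = M[1] * gs[0] + M[4] * gs[1] + M[7] * gs[2];
      double p2 = M[2] * gs[0] + M[5] * gs[1] + M[8] * gs[2];
      Tp[0] -= by * p2 - bz * p1;
      Tp[1] -= bz * p0 - bx * p2;
      Tp[2] -= bx * p1 - by * p0;
    };

    if ((!own.np.empty() || !own.sc.empty()) && par.n_atoms > 0) {
      double cube = own.cube_npsc + 1e-9;
      for (int a = 0; a < par.n_atoms; ++a) {
        double bx = par.ax[a], by = par.ay[a], bz = par.az[a];
        double ux = M[0] * bx + M[1] * by + M[2] * bz + t0;
        double uy = M[3] * bx + M[4] * by + M[5] * bz + t1;
        double uz = M[6] * bx + M[7] * by + M[8] * bz + t2;
        if (std::fabs(ux) > cube || std::fabs(uy) > cube ||
            std::fabs(uz) > cube) continue;
        double gs[3] = {0, 0, 0};
        if (own.npsc_same) {
          size_t base; double fx, fy, fz;
          if (!grid_cell(own.sc, ux, uy, uz, base, fx, fy, fz)) continue;
          cell_grad(own.sc, base, fx, fy, fz, 1.0, gs);
          if (par.asasa[a] > 0)
            cell_grad(own.np, base, fx, fy, fz, par.asasa[a], gs);
        } else {
          double g[3];
          if (!own.sc.empty()) {
            own.sc.interp_grad(ux, uy, uz, 0.0, g);
            gs[0] += g[0]; gs[1] += g[1]; gs[2] += g[2];
          }
          if (par.asasa[a] > 0 && !own.np.empty()) {
            own.np.interp_grad(ux, uy, uz, 0.0, g);
            gs[0] += par.asasa[a] * g[0];
            gs[1] += par.asasa[a] * g[1];
            gs[2] += par.asasa[a] * g[2];
          }
        }
        if (gs[0] != 0 || gs[1] != 0 || gs[2] != 0)
          add(bx, by, bz, ux, uy, uz, gs);
      }
    }
    if ((!own.el.empty() || !own.ed.empty()) && par.n_charges > 0) {
      double cube = own.cube_eled + 1e-9;
      for (int s = 0; s < par.n_charges; ++s) {
        double bx = par.qx[s], by = par.qy[s], bz = par.qz[s];
        double q = par.qq[s];
        double ux = M[0] * bx + M[1] * by + M[2] * bz + t0;
        double uy = M[3] * bx + M[4] * by + M[5] * bz + t1;
        double uz = M[6] * bx + M[7] * by + M[8] * bz + t2;
        if (std::fabs(ux) > cube || std::fabs(uy) > cube ||
            std::fabs(uz) > cube) continue;
        double gs[3] = {0, 0, 0}, g[3];
        if (q != 0 && !own.el.empty()) {
          own.el.interp_grad(ux, uy, uz, 0.0, g);
          gs[0] += 0.5 * q * g[0]; gs[1] += 0.5 * q * g[1]; gs[2] += 0.5 * q * g[2];
        }
        if (!own.ed.empty()) {
          own.ed.interp_grad(ux, uy, uz, 0.0, g);
          gs[0] += q * q * g[0]; gs[1] += q * q * g[1]; gs[2] += q * q * g[2];
        }
        if (gs[0] != 0 || gs[1] != 0 || gs[2] != 0)
          add(bx, by, bz, ux, uy, uz, gs);
      }
    }
    // lab-frame force on the owner: Ro * Fsum (opposite on the partner)
    double gl[3] = {Ro[0] * Fsum[0] + Ro[1] * Fsum[1] + Ro[2] * Fsum[2],
                    Ro[3] * Fsum[0] + Ro[4] * Fsum[1] + Ro[5] * Fsum[2],
                    Ro[6] * Fsum[0] + Ro[7] * Fsum[1] + Ro[8] * Fsum[2]};
    for (int d = 0; d < 3; ++d) { Fo[d] += gl[d]; Fp[d] -= gl[d]; }
  }
}

// Protein-surface energy: non-polar desolvation + soft-core repulsion (plus
// optionally the electrostatic desolvation of the protein's charges by the
// low-dielectric slab). Surface grids are periodic in x,y.
static double surface_energy_body(const Grid& snp, const Grid& ssc,
                                  const Grid& sed, bool use_ed,
                                  const SpeciesData& sp, const double* c,
                                  const double* R) {
  double e = 0;
  for (int a = 0; a < sp.n_atoms; ++a) {
    double bx = sp.ax[a], by = sp.ay[a], bz = sp.az[a];
    double x = c[0] + R[0] * bx + R[1] * by + R[2] * bz;
    double y = c[1] + R[3] * bx + R[4] * by + R[5] * bz;
    double z = c[2] + R[6] * bx + R[7] * by + R[8] * bz;
    if (!snp.empty() && sp.asasa[a] > 0) e += snp.interp(x, y, z, 0.0) * sp.asasa[a];
    if (!ssc.empty()) e += ssc.interp(x, y, z, 0.0);
  }
  if (use_ed && !sed.empty()) {
    for (int s = 0; s < sp.n_charges; ++s) {
      double bx = sp.qx[s], by = sp.qy[s], bz = sp.qz[s];
      double x = c[0] + R[0] * bx + R[1] * by + R[2] * bz;
      double y = c[1] + R[3] * bx + R[4] * by + R[5] * bz;
      double z = c[2] + R[6] * bx + R[7] * by + R[8] * bz;
      e += sed.interp(x, y, z, 0.0) * sp.qq[s] * sp.qq[s];
    }
  }
  return e;
}

static void accum_surface_force_grad(const Grid& snp, const Grid& ssc,
                                     const Grid& sed, bool use_ed,
                                     const SpeciesData& sp, const double* c,
                                     const double* R, double* F, double* T) {
  auto site = [&](double bx, double by, double bz, bool charge_site,
                  double q, double A) {
    double x = c[0] + R[0] * bx + R[1] * by + R[2] * bz;
    double y = c[1] + R[3] * bx + R[4] * by + R[5] * bz;
    double z = c[2] + R[6] * bx + R[7] * by + R[8] * bz;
    double gl[3] = {0, 0, 0}, g[3];
    if (charge_site) {
      if (use_ed && !sed.empty()) {
        sed.interp_grad(x, y, z, 0.0, g);
        for (int d = 0; d < 3; ++d) gl[d] += q * q * g[d];
      }
    } else {
      if (A > 0 && !snp.empty()) {
        snp.interp_grad(x, y, z, 0.0, g);
        for (int d = 0; d < 3; ++d) gl[d] += A * g[d];
      }
      if (!ssc.empty()) {
        ssc.interp_grad(x, y, z, 0.0, g);
        for (int d = 0; d < 3; ++d) gl[d] += g[d];
      }
    }
    if (gl[0] == 0 && gl[1] == 0 && gl[2] == 0) return;
    for (int d = 0; d < 3; ++d) F[d] -= gl[d];
    double gb[3] = {R[0] * gl[0] + R[3] * gl[1] + R[6] * gl[2],
                    R[1] * gl[0] + R[4] * gl[1] + R[7] * gl[2],
                    R[2] * gl[0] + R[5] * gl[1] + R[8] * gl[2]};
    T[0] -= by * gb[2] - bz * gb[1];
    T[1] -= bz * gb[0] - bx * gb[2];
    T[2] -= bx * gb[1] - by * gb[0];
  };
  for (int a = 0; a < sp.n_atoms; ++a)
    site(sp.ax[a], sp.ay[a], sp.az[a], false, 0.0, sp.asasa[a]);
  if (use_ed && !sed.empty())
    for (int s = 0; s < sp.n_charges; ++s)
      site(sp.qx[s], sp.qy[s], sp.qz[s], true, sp.qq[s], 0.0);
}

struct System {
  std::vector<SpeciesData> species;
  std::vector<int> bsp;
  int N = 0;
  std::vector<double> cx, cy, cz, quat; // quat: 4 per body
  double box[3] = {0, 0, 0};
  bool periodic_z = true;
  bool has_surface = false;
  Grid snp, ssc, sed;
  bool surf_ed = false;
  double surf_zmax = 0;     // top of surface grids
  double kT = 0.5962;
  bool harmonic = false;
  double hk = 0, hc[3] = {0, 0, 0};
  double h_t = 0.5, h_r = 0.02;
  double force_range = R_PosInf;

  void minimg(double& dx, double& dy, double& dz) const {
    dx -= box[0] * std::round(dx / box[0]);
    dy -= box[1] * std::round(dy / box[1]);
    if (periodic_z) dz -= box[2] * std::round(dz / box[2]);
  }

  double pair_cutoff(int si, int sj) const {
    const SpeciesData& a = species[si];
    const SpeciesData& b = species[sj];
    double c1 = a.half_extent + b.bound_radius;
    double c2 = b.half_extent + a.bound_radius;
    return std::max(c1, c2);
  }

  // energy of pair (i, j) with optional pose override for one body
  double pair_e(int i, int j, const double* ci_ov, const double* qi_ov) const {
    double c1[3] = {cx[i], cy[i], cz[i]};
    double q1[4] = {quat[4 * i], quat[4 * i + 1], quat[4 * i + 2], quat[4 * i + 3]};
    if (ci_ov) { c1[0] = ci_ov[0]; c1[1] = ci_ov[1]; c1[2] = ci_ov[2]; }
    if (qi_ov) { for (int t = 0; t < 4; ++t) q1[t] = qi_ov[t]; }
    double c2[3] = {cx[j], cy[j], cz[j]};
    double dx = c2[0] - c1[0], dy = c2[1] - c1[1], dz = c2[2] - c1[2];
    minimg(dx, dy, dz);
    double cut = pair_cutoff(bsp[i], bsp[j]);
    if (dx * dx + dy * dy + dz * dz > cut * cut) return 0.0;
    double c2e[3] = {c1[0] + dx, c1[1] + dy, c1[2] + dz};
    double R1[9], R2[9];
    quat_to_mat(q1, R1);
    quat_to_mat(&quat[4 * j], R2);
    double terms[8];
    pair_energy_halves(species[bsp[i]], c1, R1, species[bsp[j]], c2e, R2, terms);
    double e = 0;
    for (int t = 0; t < 8; ++t) e += terms[t];
    return e;
  }

  double surf_e(int i, const double* ci_ov, const double* qi_ov) const {
    if (!has_surface) return 0.0;
    double c1[3] = {cx[i], cy[i], cz[i]};
    double q1[4] = {quat[4 * i], quat[4 * i + 1], quat[4 * i + 2], quat[4 * i + 3]};
    if (ci_ov) { c1[0] = ci_ov[0]; c1[1] = ci_ov[1]; c1[2] = ci_ov[2]; }
    if (qi_ov) { for (int t = 0; t < 4; ++t) q1[t] = qi_ov[t]; }
    const SpeciesData& sp = species[bsp[i]];
    if (c1[2] - sp.bound_radius > surf_zmax) return 0.0;
    double R1[9];
    quat_to_mat(q1, R1);
    return surface_energy_body(snp, ssc, sed, surf_ed, sp, c1, R1);
  }

  double harmonic_e(const double* c) const {
    if (!harmonic) return 0.0;
    double dx = c[0] - hc[0], dy = c[1] - hc[1], dz = c[2] - hc[2];
    return 0.5 * hk * (dx * dx + dy * dy + dz * dz);
  }

  // energy of body i against a neighbour list, with pose override
  double body_energy(int i, const std::vector<int>& nb, const double* ci_ov,
                     const double* qi_ov) const {
    double e = 0;
    for (int j : nb) e += pair_e(i, j, ci_ov, qi_ov);
    e += surf_e(i, ci_ov, qi_ov);
    double c1[3] = {ci_ov ? ci_ov[0] : cx[i], ci_ov ? ci_ov[1] : cy[i],
                    ci_ov ? ci_ov[2] : cz[i]};
    e += harmonic_e(c1);
    return e;
  }

  // central finite-difference force (lab frame) and torque (body frame)
  void force_torque_fd(int i, const std::vector<int>& nb, double* F,
                       double* T) const {
    double c0[3] = {cx[i], cy[i], cz[i]};
    for (int d = 0; d < 3; ++d) {
      double cp[3] = {c0[0], c0[1], c0[2]}, cm[3] = {c0[0], c0[1], c0[2]};
      cp[d] += h_t; cm[d] -= h_t;
      F[d] = -(body_energy(i, nb, cp, nullptr) -
               body_energy(i, nb, cm, nullptr)) / (2 * h_t);
    }
    const double* q0 = &quat[4 * i];
    for (int d = 0; d < 3; ++d) {
      double dth[3] = {0, 0, 0};
      double qp[4] = {q0[0], q0[1], q0[2], q0[3]};
      double qm[4] = {q0[0], q0[1], q0[2], q0[3]};
      dth[d] = h_r;  quat_compose_rotvec(qp, dth);
      dth[d] = -h_r; quat_compose_rotvec(qm, dth);
      T[d] = -(body_energy(i, nb, nullptr, qp) -
               body_energy(i, nb, nullptr, qm)) / (2 * h_r);
    }
  }

  // gradient forces for the whole system (F: 3N lab, T: 3N body frames)
  void forces_grad(double* F, double* T) const {
    for (int d = 0; d < 3 * N; ++d) { F[d] = 0; T[d] = 0; }
    for (int i = 0; i < N; ++i) {
      double ci[3] = {cx[i], cy[i], cz[i]};
      double Ri[9];
      quat_to_mat(&quat[4 * i], Ri);
      for (int j = i + 1; j < N; ++j) {
        double dx = cx[j] - ci[0], dy = cy[j] - ci[1], dz = cz[j] - ci[2];
        minimg(dx, dy, dz);
        double cut = std::min(pair_cutoff(bsp[i], bsp[j]), force_range);
        if (dx * dx + dy * dy + dz * dz > cut * cut) continue;
        double cj[3] = {ci[0] + dx, ci[1] + dy, ci[2] + dz};
        double Rj[9];
        quat_to_mat(&quat[4 * j], Rj);
        accum_pair_forces_grad(species[bsp[i]], ci, Ri, species[bsp[j]], cj,
                               Rj, F + 3 * i, T + 3 * i, F + 3 * j, T + 3 * j);
      }
      if (has_surface &&
          ci[2] - species[bsp[i]].bound_radius <= surf_zmax)
        accum_surface_force_grad(snp, ssc, sed, surf_ed, species[bsp[i]], ci,
                                 Ri, F + 3 * i, T + 3 * i);
      if (harmonic)
        for (int d = 0; d < 3; ++d)
          F[3 * i + d] -= hk * (ci[d] - hc[d]);
    }
  }

  double total_energy() const {
    double e = 0;
    for (int i = 0; i < N; ++i) {
      for (int j = i + 1; j < N; ++j) e += pair_e(i, j, nullptr, nullptr);
      e += surf_e(i, nullptr, nullptr);
    }
    return e;
  }
};

static System system_from_args(List species_list, IntegerVector body_species,
                               NumericMatrix centers, NumericMatrix quats,
                               NumericVector box, bool periodic_z,
                               List surface_grids, bool surf_ed, double kT,
                               double h_t, double h_r, double harmonic_k,
                               NumericVector harmonic_center) {
  System sys;
  for (int s = 0; s < species_list.size(); ++s)
    sys.species.push_back(species_from_list(species_list[s]));
  sys.N = centers.nrow();
  sys.bsp.assign(body_species.begin(), body_species.end()); // 0-based
  sys.cx.resize(sys.N); sys.cy.resize(sys.N); sys.cz.resize(sys.N);
  sys.quat.resize(4 * sys.N);
  for (int i = 0; i < sys.N; ++i) {
    sys.cx[i] = centers(i, 0); sys.cy[i] = centers(i, 1); sys.cz[i] = centers(i, 2);
    for (int t = 0; t < 4; ++t) sys.quat[4 * i + t] = quats(i, t);
  }
  for (int d = 0; d < 3; ++d) sys.box[d] = box[d];
  sys.periodic_z = periodic_z;
  sys.kT = kT; sys.h_t = h_t; sys.h_r = h_r;
  if (surface_grids.size() > 0) {
    sys.has_surface = true;
    if (surface_grids.containsElementNamed("np"))
      sys.snp = grid_from_list(surface_grids["np"]);
    if (surface_grids.containsElementNamed("sc"))
      sys.ssc = grid_from_list(surface_grids["sc"]);
    if (surface_grids.containsElementNamed("ed"))
      sys.sed = grid_from_list(surface_grids["ed"]);
    sys.surf_ed = surf_ed;
    double zm = 0;
    if (!sys.snp.empty()) zm = std::max(zm, sys.snp.oz + (sys.snp.nz - 1) * sys.snp.hz);
    if (!sys.ssc.empty()) zm = std::max(zm, sys.ssc.oz + (sys.ssc.nz - 1) * sys.ssc.hz);
    sys.surf_zmax = zm;
  }
  if (harmonic_k > 0 && harmonic_center.size() == 3) {
    sys.harmonic = true;
    sys.hk = harmonic_k;
    for (int d = 0; d < 3; ++d) sys.hc[d] = harmonic_center[d];
  }
  return sys;
}

// [[Rcpp::export]]
NumericVector cpp_pair_energy_terms(List sp1, NumericVector c1, NumericVector q1,
                                    List sp2, NumericVector c2, NumericVector q2) {
  SpeciesData s1 = species_from_list(sp1), s2 = species_from_list(sp2);
  double R1[9], R2[9];
  quat_to_mat(REAL(q1), R1);
  quat_to_mat(REAL(q2), R2);
  double terms[8];
  pair_energy_halves(s1, REAL(c1), R1, s2, REAL(c2), R2, terms);
  NumericVector out(8);
  for (int t = 0; t < 8; ++t) out[t] = terms[t];
  out.attr("names") = CharacterVector::create("el1", "ed1", "np1", "sc1",
                                              "el2", "ed2", "np2", "sc2");
  return out;
}

// [[Rcpp::export]]
double cpp_surface_energy(List surface_grids, bool use_ed, List sp,
                          NumericVector c, NumericVector q) {
  Grid snp, ssc, sed;
  if (surface_grids.containsElementNamed("np"))
    snp = grid_from_list(surface_grids["np"]);
  if (surface_grids.containsElementNamed("sc"))
    ssc = grid_from_list(surface_grids["sc"]);
  if (surface_grids.containsElementNamed("ed"))
    sed = grid_from_list(surface_grids["ed"]);
  SpeciesData s = species_from_list(sp);
  double R[9];
  quat_to_mat(REAL(q), R);
  return surface_energy_body(snp, ssc, sed, use_ed, s, REAL(c), R);
}

// [[Rcpp::export]]
List cpp_system_forces(List species_list, IntegerVector body_species,
                       NumericMatrix centers, NumericMatrix quats,
                       NumericVector box, bool periodic_z, List surface_grids,
                       bool surf_ed, double kT, double h_t, double h_r,
                       double harmonic_k, NumericVector harmonic_center,
                       bool use_grad) {
  System sys = system_from_args(species_list, body_species, centers, quats,
                                box, periodic_z, surface_grids, surf_ed, kT,
                                h_t, h_r, harmonic_k, harmonic_center);
  NumericMatrix F(sys.N, 3), T(sys.N, 3);
  if (use_grad) {
    std::vector<double> Fv(3 * sys.N), Tv(3 * sys.N);
    sys.forces_grad(Fv.data(), Tv.data());
    for (int i = 0; i < sys.N; ++i)
      for (int d = 0; d < 3; ++d) { F(i, d) = Fv[3 * i + d]; T(i, d) = Tv[3 * i + d]; }
  } else {
    for (int i = 0; i < sys.N; ++i) {
      std::vector<int> nb;
      for (int j = 0; j < sys.N; ++j) {
        if (j == i) continue;
        double dx = sys.cx[j] - sys.cx[i], dy = sys.cy[j] - sys.cy[i],
               dz = sys.cz[j] - sys.cz[i];
        sys.minimg(dx, dy, dz);
        double cut = sys.pair_cutoff(sys.bsp[i], sys.bsp[j]) + sys.h_t + 1.0;
        if (dx * dx + dy * dy + dz * dz < cut * cut) nb.push_back(j);
      }
      double Fi[3], Ti[3];
      sys.force_torque_fd(i, nb, Fi, Ti);
      for (int d = 0; d < 3; ++d) { F(i, d) = Fi[d]; T(i, d) = Ti[d]; }
    }
  }
  for (int i = 0; i < sys.N; ++i)
    for (int d = 0; d < 3; ++d)
      if (!R_finite(F(i, d)) || !R_finite(T(i, d)))
        stop("non-finite force/torque on body %d", i + 1);
  return List::create(_["force"] = F, _["torque"] = T);
}

// [[Rcpp::export]]
double cpp_total_energy(List species_list, IntegerVector body_species,
                        NumericMatrix centers, NumericMatrix quats,
                        NumericVector box, bool periodic_z, List surface_grids,
                        bool surf_ed) {
  System sys = system_from_args(species_list, body_species, centers, quats,
                                box, periodic_z, surface_grids, surf_ed,
                                0.5962, 0.5, 0.02, 0, NumericVector(0));
  return sys.total_energy();
}

// Ermak-McCammon propagation. Random displacements are drawn from R's RNG in
// a fixed order (per body: 3 translational then 3 rotational normals), so a
// run is reproducible given set.seed(). Forces are the analytic gradients of
// the grid-interpolated energies. Returns snapshots at a fixed cadence
// including the initial state.
// [[Rcpp::export]]
List cpp_bd_run(List species_list, IntegerVector body_species,
                NumericMatrix centers, NumericMatrix quats, NumericVector box,
                bool periodic_z, List surface_grids, bool surf_ed,
                double dt_ns, double n_steps_d, int snap_every, double kT,
                double h_t, double h_r, double harmonic_k,
                NumericVector harmonic_center, bool forces_on,
                bool record_energy, bool wrap, double force_range) {
  System sys = system_from_args(species_list, body_species, centers, quats,
                                box, periodic_z, surface_grids, surf_ed, kT,
                                h_t, h_r, harmonic_k, harmonic_center);
  sys.force_range = force_range > 0 ? force_range : R_PosInf;
  long n_steps = (long)n_steps_d;
  int N = sys.N;
  long n_snap = n_steps / snap_every + 1;
  NumericVector times(n_snap), energies(n_snap);
  NumericVector snap_c((R_xlen_t)n_snap * N * 3), snap_q((R_xlen_t)n_snap * N * 4);
  std::vector<double> sd_t(N), sd_r(N), mob_t(N), mob_r(N);
  for (int i = 0; i < N; ++i) {
    const SpeciesData& sp = sys.species[sys.bsp[i]];
    sd_t[i] = std::sqrt(2.0 * sp.d_trans * dt_ns);
    sd_r[i] = std::sqrt(2.0 * sp.d_rot * dt_ns);
    mob_t[i] = sp.d_trans * dt_ns / kT;
    mob_r[i] = sp.d_rot * dt_ns / kT;
  }
  std::vector<double> F(3 * N), T(3 * N);

  auto record = [&](long isnap, double t) {
    times[isnap] = t;
    for (int i = 0; i < N; ++i) {
      snap_c[isnap + n_snap * (i + (R_xlen_t)N * 0)] = sys.cx[i];
      snap_c[isnap + n_snap * (i + (R_xlen_t)N * 1)] = sys.cy[i];
      snap_c[isnap + n_snap * (i + (R_xlen_t)N * 2)] = sys.cz[i];
      for (int tq = 0; tq < 4; ++tq)
        snap_q[isnap + n_snap * (i + (R_xlen_t)N * tq)] = sys.quat[4 * i + tq];
    }
    energies[isnap] = (record_energy && forces_on) ? sys.total_energy() : 0.0;
  };
  record(0, 0.0);

  for (long step = 1; step <= n_steps; ++step) {
    if (forces_on) {
      sys.forces_grad(F.data(), T.data());
      for (int i = 0; i < 3 * N; ++i)
        if (!R_finite(F[i]) || !R_finite(T[i]))
          stop("non-finite force at step %ld (body %d)", step, i / 3 + 1);
    }
    for (int i = 0; i < N; ++i) {
      double g1 = norm_rand(), g2 = norm_rand(), g3 = norm_rand();
      double g4 = norm_rand(), g5 = norm_rand(), g6 = norm_rand();
      if (forces_on) {
        sys.cx[i] += mob_t[i] * F[3 * i] + sd_t[i] * g1;
        sys.cy[i] += mob_t[i] * F[3 * i + 1] + sd_t[i] * g2;
        sys.cz[i] += mob_t[i] * F[3 * i + 2] + sd_t[i] * g3;
        double dth[3] = {mob_r[i] * T[3 * i] + sd_r[i] * g4,
                         mob_r[i] * T[3 * i + 1] + sd_r[i] * g5,
                         mob_r[i] * T[3 * i + 2] + sd_r[i] * g6};
        quat_compose_rotvec(&sys.quat[4 * i], dth);
      } else {
        sys.cx[i] += sd_t[i] * g1;
        sys.cy[i] += sd_t[i] * g2;
        sys.cz[i] += sd_t[i] * g3;
        double dth[3] = {sd_r[i] * g4, sd_r[i] * g5, sd_r[i] * g6};
        quat_compose_rotvec(&sys.quat[4 * i], dth);
      }
      // boundaries: periodic wrap in x,y (and z without surface);
      // specular reflection at top and bottom when a surface is present
      if (wrap) {
        sys.cx[i] -= sys.box[0] * std::floor(sys.cx[i] / sys.box[0]);
        sys.cy[i] -= sys.box[1] * std::floor(sys.cy[i] / sys.box[1]);
        if (sys.periodic_z) {
          sys.cz[i] -= sys.box[2] * std::floor(sys.cz[i] / sys.box[2]);
        } else {
          if (sys.cz[i] > sys.box[2]) sys.cz[i] = 2 * sys.box[2] - sys.cz[i];
          if (sys.cz[i] < 0) sys.cz[i] = -sys.cz[i];
        }
      }
    }
    if (step % snap_every == 0) record(step / snap_every, step * dt_ns);
  }

  snap_c.attr("dim") = IntegerVector::create((int)n_snap, N, 3);
  snap_q.attr("dim") = IntegerVector::create((int)n_snap, N, 4);
  return List::create(_["times"] = times, _["centers"] = snap_c,
                      _["quats"] = snap_q, _["energies"] = energies);
}
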