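#' Energy model for coarse-grained toy runs
#'
#' The published parameter sets with two coarse-graining adjustments, chosen
#' once from pair potential-of-mean-force inspection: the soft-core
#' magnitude gamma is rescaled to 24 kcal/mol (the published 64 kcal/mol is
#' calibrated for all-atom densities; summing the 1/d^6 tails of a whole
#' bead shell at 64 leaves no bound state) and the non-polar burial ramp is
#' widened to 10 Angstrom (probe 5 Angstrom), the scale of the hydrophobic
#' attraction range for bead-resolution surfaces.
#'
#' @param regime `"solution"` or `"surface"` (sigma 3.0 -> 1.5 and beta
#'   -0.018 -> -0.013 as in the published setup; protein-protein behaviour
#'   stays consistent between the regimes, as in the published calibration).
#'   The graphite slab's own burial field uses a wider ramp, set in
#'   [surface_grid_set()].
#' @return an [energy_model()].
#' @export
toy_energy_model <- function(regime = c("solution", "surface")) {
  energy_model(match.arg(regime), gamma = 24, probe_radius = 5, ramp = 10)
}

#' Contact criterion at bead resolution
#'
#' The atomic encounter criterion (d_c 4.5, d_min 6.0 Angstrom) scaled to
#' 3 Angstrom beads: contacts within 10 Angstrom (about one bead diameter
#' beyond touching), independence beyond 12 Angstrom. Protein-surface
#' contacts use a slightly tighter cutoff, mirroring the published 4.0 vs
#' 4.5 Angstrom distinction.
#'
#' @param target `"protein"` or `"surface"`.
#' @export
toy_contact_criterion <- function(target = c("protein", "surface")) {
  target <- match.arg(target)
  if (target == "protein") contact_criterion(2, 10, 12)
  else contact_criterion(2, 9, 12)
}

#' Build the interaction grids of a toy species
#'
#' Grid extents follow the published protein setup scaled to the toy
#' interaction ranges: electrostatic fields on a 50 Angstrom cube at 1.0
#' Angstrom spacing, non-polar and soft-core fields on matching 56 Angstrom
#' cubes at 0.75 Angstrom spacing (identical geometry lets the engine
#' evaluate both in one pass).
#'
#' @param species an [rbd_species()] from [make_toy_protein()].
#' @param model an [energy_model()], typically [toy_energy_model()].
#' @return the species with grids attached.
#' @export
prepare_toy_species <- function(species, model = toy_energy_model()) {
  build_species_grids(species, model, size_el = 50, size_np = 56,
                      size_sc = 56, spacing = 0.75, spacing_el = 1.0)
}

#' Translational diffusion validation
#'
#' Free single-body run; the mean squared displacement slope is fitted over
#' short lags and compared with the Einstein relation MSD = 6 D_t t.
#'
#' @param d_trans translational diffusion coefficient, Angstrom^2/ns.
#' @param n_steps number of 0.5 ps steps.
#' @param seed RNG seed.
#' @return list with `slope` (fitted, Angstrom^2/ns), `expected` (6 D_t)
#'   and `rel_err`.
#' @export
diffusion_msd_check <- function(d_trans = 13.91, n_steps = 1e5, seed = 1) {
  sp <- make_toy_protein("free", n_beads = 8)
  sp$d_trans <- d_trans
  dt <- 0.5e-3                        # ns
  record_every <- 5L
  p <- sim_params(t_total = n_steps * dt, box = c(1000, 1000, 1000),
                  species_counts = c(free = 1), t_equil = 0,
                  snapshot_interval = record_every * dt, seed = seed)
  traj <- run_simulation(list(sp), p, forces_on = FALSE, wrap = FALSE,
                         record_energy = FALSE)
  msd <- trajectory_msd(traj, max_lag = 20)
  fit <- stats::lm(msd ~ 0 + lag_ns, data = msd)
  slope <- unname(stats::coef(fit)[1])
  expected <- 6 * d_trans
  list(slope = slope, expected = expected,
       rel_err = abs(slope - expected) / expected)
}

#' Rotational diffusion validation
#'
#' Free rotational diffusion of many independent bodies; the body-axis
#' autocorrelation at t = 1/(2 D_r) is compared with exp(-2 D_r t) = 1/e.
#'
#' @param d_rot rotational diffusion coefficient, rad^2/ns.
#' @param n_bodies independent bodies averaged over.
#' @param t_total simulated time per body, ns.
#' @param timestep ps (pure rotational diffusion is exact at any step).
#' @param seed RNG seed.
#' @return list with `corr` (measured), `expected` (1/e), `rel_err`, `t_star`.
#' @export
rotation_correlation_check <- function(d_rot = 4.04e-2, n_bodies = 16,
                                       t_total = 5000, timestep = 5,
                                       seed = 1) {
  sp <- make_toy_protein("free", n_beads = 8)
  sp$d_rot <- d_rot
  t_star <- 1 / (2 * d_rot)
  dt <- timestep * 1e-3
  snap <- 10 * dt                      # record every 10 steps
  p <- sim_params(t_total = t_total, box = c(1e4, 1e4, 1e4),
                  species_counts = c(free = n_bodies), t_equil = 0,
                  snapshot_interval = snap, timestep = timestep, seed = seed)
  traj <- run_simulation(list(sp), p, forces_on = FALSE, wrap = FALSE,
                         record_energy = FALSE)
  lag <- round(t_star / snap)
  oc <- orientation_correlation(traj, lag)
  expected <- exp(-2 * d_rot * lag * snap)
  list(corr = oc$corr, expected = expected,
       rel_err = abs(oc$corr - expected) / expected,
       t_star = lag * snap)
}

#' Boltzmann sampling validation in a harmonic well
#'
#' One body in an external harmonic test potential; the sampled position
#' variance per axis is compared with k_B T / k (fluctuation-dissipation
#' pairing of the propagation step).
#'
#' @param k spring constant, kcal/mol/Angstrom^2.
#' @param n_steps number of 0.5 ps steps.
#' @param temperature K.
#' @param seed RNG seed.
#' @return list with `variance` (pooled over axes), `expected`, `rel_err`.
#' @export
harmonic_sampling_check <- function(k = 0.1, n_steps = 2e6,
                                    temperature = 300, seed = 1) {
  sp <- make_toy_protein("probe", n_beads = 8)
  dt <- 0.5e-3
  ctr <- c(500, 500, 500)
  p <- sim_params(t_total = n_steps * dt, box = c(1000, 1000, 1000),
                  species_counts = c(probe = 1), t_equil = 0.02 * n_steps * dt,
                  snapshot_interval = 10 * dt, temperature = temperature,
                  seed = seed)
  traj <- run_simulation(list(sp), p, wrap = FALSE, record_energy = FALSE,
                         harmonic = list(k = k, center = ctr))
  fr <- production_frames(traj)
  dev <- sweep(traj$centers[fr, 1, ], 2, ctr)
  v <- mean(apply(dev, 2, stats::var))
  expected <- 0.0019872041 * temperature / k
  list(variance = v, expected = expected,
       rel_err = abs(v - expected) / expected)
}

#' Soft-core grid fidelity check
#'
#' Builds the soft-core field of a single atom on a 1.0 Angstrom grid and
#' compares grid values (nodes) and interpolated values (random off-node
#' probe points) against direct evaluation of
#' gamma a^nexp / (d^nexp + sigma^nexp).
#'
#' @param a atom radius, Angstrom.
#' @param gamma,sigma,nexp soft-core parameters.
#' @param n_points random probe points.
#' @param seed RNG seed.
#' @return list with `node_max_rel_err`, `interp_max_rel_err`,
#'   `interp_rms_rel_err` and the probe distance range.
#' @export
softcore_grid_check <- function(a = 3.0, gamma = 64, sigma = 3.0, nexp = 6,
                                n_points = 500, seed = 1) {
  set.seed(seed)
  sp <- rbd_species("atom", data.frame(x = 0, y = 0, z = 0, radius = a,
                                       charge = 0))
  g <- softcore_grid(sp, list(gamma = gamma, sigma = sigma, nexp = nexp),
                     size = 24, spacing = 1.0)
  direct <- function(p) gamma * a^nexp / (rowSums(p^2)^(nexp / 2) + sigma^nexp)
  # node subset
  idx <- as.matrix(expand.grid(seq(1, g$dims[1], by = 2),
                               seq(1, g$dims[2], by = 2),
                               seq(1, g$dims[3], by = 2)))
  nodes <- sweep((idx - 1) * g$spacing, 2, g$origin, `+`)
  nv <- g$values[idx]
  node_err <- abs(nv - direct(nodes)) / pmax(direct(nodes), 1e-12)
  # random off-node probes at d in [0, 10]
  u <- matrix(stats::rnorm(3 * n_points), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  pts <- u * stats::runif(n_points, 0, 10)
  iv <- trilinear_interpolate(g, pts)
  dv <- direct(pts)
  rel <- abs(iv - dv) / pmax(dv, 1e-12)
  list(node_max_rel_err = max(node_err),
       interp_max_rel_err = max(rel),
       interp_rms_rel_err = sqrt(mean(rel^2)))
}

# shared toy solution run (all toy species share one molecular mass)
.toy_solution_run <- function(species, counts, concentration, seed,
                              t_total, force_range = 42) {
  mass <- species[[1]]$mass_kda
  box <- box_from_concentration(mass, sum(counts), concentration)
  p <- sim_params(t_total = t_total, box = box, species_counts = counts,
                  t_equil = 0.1 * t_total, seed = seed)
  run_simulation(species, p, force_range = force_range)
}

#' Oligomerization across protein concentrations
#'
#' The concentration scan of the solution study at desk scale: `n_bodies`
#' dipolar toy proteins at each concentration, several seeds, 1 mus each
#' (0.5 ps steps, first 10% discarded as equilibration). Reports the
#' time-averaged oligomer fractions under the bead-scale contact criterion.
#'
#' @param concentrations g/L.
#' @param seeds one run per seed at each concentration.
#' @param n_bodies bodies per run.
#' @param t_total ns per run.
#' @param keep_traj also return the trajectories (memory permitting).
#' @return data.frame with columns `concentration`, `seed`, `chi1`, `chi2`,
#'   `chi3plus`, `tetramers_per_frame`; trajectories in attribute
#'   `"trajectories"` when requested.
#' @export
oligomer_concentration_scan <- function(concentrations = c(2, 5, 10, 20),
                                        seeds = 1:3, n_bodies = 16,
                                        t_total = 1000, keep_traj = FALSE) {
  A <- prepare_toy_species(make_toy_protein("toyA"))
  crit <- toy_contact_criterion()
  rows <- list()
  trajs <- list()
  for (conc in concentrations) {
    for (seed in seeds) {
      traj <- .toy_solution_run(list(A), c(toyA = n_bodies), conc,
                                seed = seed * 1000 + round(conc), t_total)
      of <- oligomer_fractions(traj, list(A), crit)
      sizes <- attr(of, "sizes_per_frame")
      tet <- mean(vapply(sizes, function(s) sum(s == 4), 0))
      chi <- function(n) sum(of$chi[of$n == n])
      rows[[length(rows) + 1]] <- data.frame(
        concentration = conc, seed = seed, chi1 = chi(1), chi2 = chi(2),
        chi3plus = sum(of$chi[of$n >= 3]), tetramers_per_frame = tet)
      if (keep_traj) trajs[[paste(conc, seed, sep = "_")]] <- traj
    }
  }
  out <- do.call(rbind, rows)
  if (keep_traj) attr(out, "trajectories") <- trajs
  out
}

#' Tetramer formation: pure dipolar vs 50/50 dipolar/quadrupolar mixture
#'
#' Compares the average number of 4-mers per frame between a pure dipolar
#' system and an equal mixture with the quadrupolar conformer, at equal
#' total concentration -- the desk-scale analogue of comparing
#' single-conformer with mixed-conformer solutions.
#'
#' @param seeds one run pair per seed.
#' @param concentration g/L.
#' @param n_bodies total bodies per run.
#' @param t_total ns per run; tetramers are rare events at this system
#'   size, so the comparison samples 1 mus per run at a fixed cadence.
#' @return data.frame with `system` ("pure" or "mixed"), `seed`,
#'   `tetramers_per_frame` and `mixed_classes` attribute with the tetramer
#'   composition counts of the mixed runs.
#' @export
mixture_tetramer_comparison <- function(seeds = 1:3, concentration = 20,
                                        n_bodies = 16, t_total = 1000) {
  A <- prepare_toy_species(make_toy_protein("toyA"))
  B <- prepare_toy_species(make_toy_protein("toyB",
                                            charge_pattern = "quadrupolar"))
  crit <- toy_contact_criterion()
  rows <- list()
  classes <- NULL
  for (seed in seeds) {
    tp <- .toy_solution_run(list(A), c(toyA = n_bodies), concentration,
                            seed = 70000 + seed, t_total)
    op <- oligomer_fractions(tp, list(A), crit)
    np_ <- mean(vapply(attr(op, "sizes_per_frame"),
                       function(s) sum(s == 4), 0))
    rows[[length(rows) + 1]] <- data.frame(system = "pure", seed = seed,
                                           tetramers_per_frame = np_)
    tm <- .toy_solution_run(list(A, B),
                            c(toyA = n_bodies / 2, toyB = n_bodies / 2),
                            concentration, seed = 80000 + seed, t_total)
    tc <- tetramer_counts(tm, list(A, B), crit,
                          label_a = "toyA", label_b = "toyB")
    rows[[length(rows) + 1]] <- data.frame(system = "mixed", seed = seed,
                                           tetramers_per_frame = sum(tc$mean_count))
    classes <- if (is.null(classes)) tc else
      transform(classes, mean_count = classes$mean_count + tc$mean_count)
  }
  out <- do.call(rbind, rows)
  if (!is.null(classes)) {
    classes$mean_count <- classes$mean_count / length(seeds)
    attr(out, "mixed_classes") <- classes
  }
  out
}

#' Surface adsorption profile of toy proteins over graphite
#'
#' Desk-scale analogue of the slab study: `n_bodies` toy proteins at the
#' given concentration above an HOPG slab (periodic sides, reflective top),
#' surface-regime parameters. Returns the surface-normal density profile
#' (normalized by the bulk density) and its first-peak statistics.
#'
#' @param seed RNG seed.
#' @param concentration g/L.
#' @param n_bodies bodies.
#' @param t_total ns.
#' @param bin_width profile bin, Angstrom.
#' @return list with `profile` (an `rbd_profile`), `peak_z` (bin center of
#'   the global maximum, Angstrom above the surface plane), `peak_ratio`
#'   (peak/bulk), `traj`.
#' @export
surface_enrichment_profile <- function(seed = 1, concentration = 20,
                                       n_bodies = 16, t_total = 1000,
                                       bin_width = 2) {
  model <- toy_energy_model("surface")
  A <- prepare_toy_species(make_toy_protein("toyA"), model)
  surf <- build_hopg_layer(200, 200, 3)
  surf <- surface_grid_set(surf, model, z_max = 60, spacing = 0.5)
  vol <- prod(box_from_concentration(A$mass_kda, n_bodies, concentration))
  box <- c(surf$extent_x, surf$extent_y,
           vol / (surf$extent_x * surf$extent_y))
  p <- sim_params(t_total = t_total, box = box,
                  species_counts = c(toyA = n_bodies),
                  t_equil = 0.1 * t_total, boundary_z = "surface",
                  seed = seed)
  traj <- run_simulation(list(A), p, surface = surf, force_range = 42)
  prof <- z_distribution(traj, bin_width = bin_width)
  pk <- which.max(prof$values)
  list(profile = prof,
       peak_z = profile_midpoints(prof)[pk],
       peak_ratio = max(prof$values),
       traj = traj)
}
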