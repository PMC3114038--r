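#' Simulation parameters
#'
#' @param t_total total simulated time, ns.
#' @param box 3-vector box dimensions, Angstrom (see
#'   [box_from_concentration()]).
#' @param species_counts named integer vector: bodies per species label.
#' @param timestep integration timestep, ps.
#' @param temperature K.
#' @param t_equil equilibration time excluded from analysis, ns.
#' @param snapshot_interval recording cadence, ns.
#' @param boundary_z `"periodic"` (solution runs) or `"surface"` (slab at the
#'   bottom, specular reflection at the top).
#' @param seed RNG seed for initialization and propagation.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(t_total, box, species_counts,
                       timestep = 0.5, temperature = 300,
                       t_equil = 0.1 * t_total, snapshot_interval = 0.5,
                       boundary_z = c("periodic", "surface"), seed = 1) {
  boundary_z <- match.arg(boundary_z)
  if (timestep <= 0) stop("timestep must be > 0")
  if (t_equil >= t_total) stop("t_equil must be smaller than t_total")
  if (snapshot_interval <= 0) stop("snapshot_interval must be > 0")
  if (any(box <= 0) || length(box) != 3) stop("box must be 3 positive lengths")
  p <- list(t_total = t_total, box = as.numeric(box),
            species_counts = species_counts, timestep = timestep,
            temperature = temperature, t_equil = t_equil,
            snapshot_interval = snapshot_interval, boundary_z = boundary_z,
            seed = as.integer(seed))
  class(p) <- "sim_params"
  p
}

#' Cubic box side from protein concentration
#'
#' @param mass_per_molecule molecular mass, kDa.
#' @param count number of molecules.
#' @param concentration g/L.
#' @return 3-vector of equal box sides, Angstrom.
#' @export
box_from_concentration <- function(mass_per_molecule, count, concentration) {
  if (mass_per_molecule <= 0 || count <= 0 || concentration <= 0)
    stop("mass, count and concentration must be positive")
  mass_g <- mass_per_molecule * 1000 / 6.02214076e23
  vol_a3 <- count * mass_g / concentration * 1e27
  rep(vol_a3^(1 / 3), 3)
}

#' Random non-overlapping initial configuration
#'
#' Bodies are placed uniformly in the box with uniform random orientations;
#' a placement is rejected when bounding spheres overlap and an atom-level
#' check confirms a clash. Uses the current RNG state (seed it for
#' reproducibility).
#'
#' @param species list of [rbd_species()].
#' @param params a [sim_params()].
#' @param max_attempts placement attempts per body before giving up.
#' @return list with `centers`, `quats`, `body_species` (1-based index),
#'   `labels`, `box`, `time`.
#' @export
initialize_random <- function(species, params, max_attempts = 2000) {
  labels <- vapply(species, `[[`, "", "label")
  counts <- params$species_counts
  if (!all(names(counts) %in% labels))
    stop("species_counts labels not found: ",
         paste(setdiff(names(counts), labels), collapse = ", "))
  body_species <- unlist(lapply(names(counts), function(nm)
    rep(match(nm, labels), counts[[nm]])))
  n <- length(body_species)
  box <- params$box
  brad <- vapply(species, `[[`, 0, "bound_radius")
  if (2 * max(brad[body_species]) > min(box) / 2)
    stop("box too small for the bodies (minimum image invalid)")
  has_surface <- params$boundary_z == "surface"
  centers <- matrix(0, n, 3)
  quats <- matrix(0, n, 4)
  apos <- lapply(species, function(s) as.matrix(s$atoms[, c("x", "y", "z")]))
  amax <- vapply(species, function(s) max(s$atoms$radius), 0)
  for (i in seq_len(n)) {
    si <- body_species[i]
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      cz <- if (has_surface)
        stats::runif(1, brad[si], box[3] - brad[si]) else stats::runif(1, 0, box[3])
      ci <- c(stats::runif(1, 0, box[1]), stats::runif(1, 0, box[2]), cz)
      qi <- stats::rnorm(4); qi <- qi / sqrt(sum(qi^2))
      clash <- FALSE
      if (i > 1) {
        for (j in seq_len(i - 1)) {
          sj <- body_species[j]
          d <- centers[j, ] - ci
          d <- d - box * round(d / box)
          if (sqrt(sum(d^2)) < brad[si] + brad[sj]) {
            # atom-level confirmation
            Ai <- apos[[si]] %*% t(quat_matrix(qi))
            Aj <- sweep(apos[[sj]] %*% t(quat_matrix(quats[j, ])), 2, d, `+`)
            if (cpp_min_cross_dist(Ai, Aj) < amax[si] + amax[sj]) {
              clash <- TRUE
              break
            }
          }
        }
      }
      if (!clash) { centers[i, ] <- ci; quats[i, ] <- qi; ok <- TRUE; break }
    }
    if (!ok) stop("could not place body ", i, " without overlap (packing too dense?)")
  }
  list(centers = centers, quats = quats, body_species = body_species,
       labels = labels[body_species], box = box, time = 0)
}

#' One Ermak-McCammon step (reference implementation)
#'
#' Propagates centers and orientations given forces and torques:
#' dr = (D_t dt / k_B T) F + R with R isotropic Gaussian of variance
#' 2 D_t dt per axis (6 D_t dt total), and the analogous body-frame rotation
#' composed onto the quaternion. No boundary conditions are applied here
#' (see [apply_boundaries()]).
#'
#' @param state list with `centers` (n x 3), `quats` (n x 4), `time` (ns).
#' @param species list of species (for D_t, D_r).
#' @param body_species 1-based species index per body.
#' @param forces,torques n x 3 matrices (kcal/mol/Angstrom; kcal/mol,
#'   torques in the body frame).
#' @param timestep ps.
#' @param temperature K.
#' @param noise optional n x 6 matrix of standard normals (3 translational,
#'   3 rotational per body); drawn from the RNG when `NULL`. A zero matrix
#'   makes the step deterministic.
#' @return updated state.
#' @export
bd_step <- function(state, species, body_species, forces, torques,
                    timestep = 0.5, temperature = 300, noise = NULL) {
  if (any(!is.finite(forces)) || any(!is.finite(torques))) {
    bad <- which(rowSums(!is.finite(cbind(forces, torques))) > 0)[1]
    stop("non-finite force/torque on body ", bad)
  }
  n <- nrow(state$centers)
  dt <- timestep * 1e-3                       # ns
  kbt <- 0.0019872041 * temperature
  if (is.null(noise)) noise <- matrix(stats::rnorm(6 * n), n, 6, byrow = TRUE)
  dtr <- vapply(species, `[[`, 0, "d_trans")[body_species]
  drot <- vapply(species, `[[`, 0, "d_rot")[body_species]
  state$centers <- state$centers + (dtr * dt / kbt) * forces +
    sqrt(2 * dtr * dt) * noise[, 1:3, drop = FALSE]
  for (i in seq_len(n)) {
    dth <- (drot[i] * dt / kbt) * torques[i, ] +
      sqrt(2 * drot[i] * dt) * noise[i, 4:6]
    state$quats[i, ] <- quat_compose(state$quats[i, ], dth)
  }
  state$time <- state$time + dt
  state
}

#' Apply periodic / reflective boundary conditions
#'
#' Periodic wrap in x,y (and z without a surface); with a surface present,
#' specular reflection at the top plane `z = box[3]` and at the bottom
#' `z = 0`.
#'
#' @param state list with `centers` and `box`.
#' @param surface logical: is a surface present at the bottom?
#' @return state with wrapped/reflected centers.
#' @export
apply_boundaries <- function(state, surface = FALSE) {
  b <- state$box
  cc <- state$centers
  cc[, 1] <- cc[, 1] %% b[1]
  cc[, 2] <- cc[, 2] %% b[2]
  if (!surface) {
    cc[, 3] <- cc[, 3] %% b[3]
  } else {
    over <- cc[, 3] > b[3]
    cc[over, 3] <- 2 * b[3] - cc[over, 3]
    under <- cc[, 3] < 0
    cc[under, 3] <- -cc[under, 3]
  }
  state$centers <- cc
  state
}

#' Minimum-image displacement
#' @param d displacement vector (or n x 3 matrix).
#' @param box periodic box, 3-vector.
#' @export
minimum_image <- function(d, box) {
  if (is.null(dim(d))) return(d - box * round(d / box))
  sweep(d, 2, box, function(x, b) x - b * round(x / b))
}

#' Run a Brownian dynamics simulation
#'
#' Propagates all bodies with the Ermak-McCammon algorithm (compiled core),
#' with forces from the grid-mapped interaction energies by central finite
#' differences. Snapshots (positions, orientations, total energy) are
#' recorded at a fixed cadence including the initial state. The run is
#' deterministic given `params$seed`.
#'
#' @param species list of [rbd_species()] with grids attached (grids may be
#'   omitted when `forces_on = FALSE`).
#' @param params a [sim_params()].
#' @param surface optional `rbd_surface` with grids; implies
#'   `boundary_z = "surface"`.
#' @param init optional initial state (as from [initialize_random()]).
#' @param forces_on `FALSE` runs free diffusion (no interactions).
#' @param record_energy recompute the total system energy at every snapshot.
#' @param wrap apply boundary conditions (disable to record unwrapped
#'   coordinates for diffusion analysis).
#' @param harmonic optional external harmonic test potential: list with
#'   spring constant `k` (kcal/mol/Angstrom^2) and `center` (3-vector).
#' @param h_t,h_r finite-difference steps (Angstrom; rad) used by the
#'   force-operation contract; the engine itself propagates with the exact
#'   gradient of the interpolated energy.
#' @param force_range pairs farther apart than this (centers, Angstrom) are
#'   skipped in the force loop (the fields there are negligible); `Inf`
#'   disables the optimization. Recorded energies always use the full grid
#'   range.
#' @return object of class `rbd_trajectory`: snapshot `times` (ns), `centers`
#'   (frames x bodies x 3), `quats` (frames x bodies x 4), `energies`
#'   (kcal/mol), body bookkeeping and the run parameters.
#' @export
run_simulation <- function(species, params, surface = NULL, init = NULL,
                           forces_on = TRUE, record_energy = TRUE,
                           wrap = TRUE, harmonic = NULL,
                           h_t = 0.5, h_r = 0.02, force_range = Inf) {
  if (!is.null(surface) && params$boundary_z != "surface")
    stop("surface given but boundary_z is not 'surface'")
  set.seed(params$seed)
  if (is.null(init)) init <- initialize_random(species, params)
  dt_ns <- params$timestep * 1e-3
  n_steps <- round(params$t_total / dt_ns)
  snap_every <- max(1L, as.integer(round(params$snapshot_interval / dt_ns)))
  kbt <- 0.0019872041 * params$temperature
  sgrids <- if (!is.null(surface)) lapply(surface$grids, unclass) else list()
  hk <- if (!is.null(harmonic)) harmonic$k else 0
  hc <- if (!is.null(harmonic)) as.numeric(harmonic$center) else numeric(0)
  res <- cpp_bd_run(lapply(species, species_runtime),
                    as.integer(init$body_species) - 1L,
                    init$centers, init$quats, params$box,
                    params$boundary_z == "periodic", sgrids, FALSE,
                    dt_ns, n_steps, snap_every, kbt, h_t, h_r,
                    hk, hc, forces_on, record_energy, wrap, force_range)
  traj <- list(times = res$times, centers = res$centers, quats = res$quats,
               energies = res$energies, box = params$box,
               body_species = init$body_species, labels = init$labels,
               params = params, has_surface = !is.null(surface),
               species_labels = vapply(species, `[[`, "", "label"))
  class(traj) <- "rbd_trajectory"
  traj
}

#' @export
print.rbd_trajectory <- function(x, ...) {
  cat(sprintf("BD trajectory: %d bodies, %d frames (%.3g ns, cadence %.3g ns)%s\n",
              dim(x$centers)[2], length(x$times), max(x$times),
              x$params$snapshot_interval,
              if (x$has_surface) ", surface at z = 0" else ""))
  invisible(x)
}

#' Frame indices of the production segment (time >= t_equil)
#' @param traj an `rbd_trajectory`.
#' @export
production_frames <- function(traj) {
  which(traj$times >= traj$params$t_equil)
}

#' Pose of all bodies at one frame
#' @param traj an `rbd_trajectory`.
#' @param frame frame index.
#' @return list with `centers`, `quats`, `box`, `time`.
#' @export
trajectory_state <- function(traj, frame) {
  list(centers = traj$centers[frame, , , drop = TRUE],
       quats = traj$quats[frame, , , drop = TRUE],
       box = traj$box, time = traj$times[frame])
}

#' Mean squared displacement over lag times
#'
#' Averages over all bodies and overlapping time origins. Only meaningful on
#' trajectories recorded with `wrap = FALSE`.
#'
#' @param traj an `rbd_trajectory`.
#' @param max_lag maximum lag in frames.
#' @return data.frame with `lag_ns` and `msd` (Angstrom^2).
#' @export
trajectory_msd <- function(traj, max_lag = 50) {
  cc <- traj$centers
  nf <- dim(cc)[1]
  stopifnot(max_lag < nf)
  dt <- diff(traj$times[1:2])
  msd <- vapply(seq_len(max_lag), function(lag) {
    d <- cc[(lag + 1):nf, , , drop = FALSE] - cc[1:(nf - lag), , , drop = FALSE]
    mean(apply(d, c(1, 2), function(v) sum(v^2)))
  }, 0)
  data.frame(lag_ns = seq_len(max_lag) * dt, msd = msd)
}

#' Orientation autocorrelation of the body z-axis
#'
#' C(t) = < u(0) . u(t) > for the body-frame z axis, averaged over bodies and
#' overlapping origins; for free rotational diffusion C(t) = exp(-2 D_r t).
#'
#' @param traj an `rbd_trajectory`.
#' @param lags vector of lags in frames.
#' @return data.frame with `lag_ns` and `corr`.
#' @export
orientation_correlation <- function(traj, lags) {
  qq <- traj$quats
  nf <- dim(qq)[1]; nb <- dim(qq)[2]
  dt <- diff(traj$times[1:2])
  # body z-axis in the lab frame per frame/body
  u <- array(0, c(nf, nb, 3))
  for (i in seq_len(nb)) {
    w <- qq[, i, 1]; x <- qq[, i, 2]; y <- qq[, i, 3]; z <- qq[, i, 4]
    u[, i, 1] <- 2 * (x * z + w * y)
    u[, i, 2] <- 2 * (y * z - w * x)
    u[, i, 3] <- 1 - 2 * (x^2 + y^2)
  }
  corr <- vapply(lags, function(lag) {
    s <- u[1:(nf - lag), , , drop = FALSE] * u[(lag + 1):nf, , , drop = FALSE]
    mean(apply(s, c(1, 2), sum))
  }, 0)
  data.frame(lag_ns = lags * dt, corr = corr)
}
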