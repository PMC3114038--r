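# ---- quaternion helpers (w, x, y, z) ---------------------------------------

#' Quaternion from axis and angle
#' @param axis 3-vector (normalized internally).
#' @param angle radians.
#' @return unit quaternion `c(w, x, y, z)`.
#' @export
quat_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), sin(angle / 2) * axis)
}

#' Rotation matrix of a unit quaternion (body frame to lab frame)
#' @param q unit quaternion `c(w, x, y, z)`.
#' @export
quat_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Compose a small body-frame rotation vector onto a quaternion
#' @param q unit quaternion.
#' @param dtheta rotation vector in the body frame, radians.
#' @return renormalized unit quaternion.
#' @export
quat_compose <- function(q, dtheta) {
  ang <- sqrt(sum(dtheta^2))
  dq <- if (ang < 1e-12) c(1, 0, 0, 0) else quat_axis_angle(dtheta, ang)
  out <- c(q[1] * dq[1] - sum(q[2:4] * dq[2:4]),
           q[1] * dq[2:4] + dq[1] * q[2:4] +
             c(q[3] * dq[4] - q[4] * dq[3],
               q[4] * dq[2] - q[2] * dq[4],
               q[2] * dq[3] - q[3] * dq[2]))
  out / sqrt(sum(out^2))
}

# ---- runtime form of a species (plain lists consumed by the C++ core) ------

species_runtime <- function(species) {
  a <- species$atoms
  grids <- lapply(species$grids, unclass)
  half_extent <- 0
  for (g in grids) {
    ext <- (g$dims - 1) * rep_len(g$spacing, 3)
    if (!isTRUE(g$periodic_xy)) half_extent <- max(half_extent, max(ext) / 2)
  }
  list(apos = as.matrix(a[, c("x", "y", "z")]),
       arad = a$radius, asasa = a$sasa,
       cpos = as.matrix(species$charges[, c("x", "y", "z"), drop = FALSE]),
       q = species$charges$q,
       grids = grids,
       bound_radius = species$bound_radius,
       half_extent = half_extent,
       d_trans = species$d_trans, d_rot = species$d_rot)
}

.state_pose <- function(state, i) {
  list(center = state$centers[i, ], quat = state$quats[i, ])
}

#' Pairwise interaction free energy of two posed bodies
#'
#' Grid-mapped evaluation of the eight-term interaction free energy: the
#' electrostatic potential of each body acting on the partner's effective
#' charges (factor 1/2 per half-sum), the electrostatic desolvation fields
#' acting on squared partner charges, the non-polar desolvation fields acting
#' on partner solvent-accessible areas, and the soft-core repulsion fields
#' acting on all partner atoms. Both directions (grids of body 1 on sites of
#' body 2 and vice versa) are summed.
#'
#' @param species1,species2 [rbd_species()] objects with grids attached.
#' @param center1,center2 body centers in the lab frame, Angstrom.
#' @param quat1,quat2 unit quaternions (body to lab orientation).
#' @param box optional periodic box (3-vector); when given, the minimum-image
#'   displacement between centers is used.
#' @param terms return the eight individual terms instead of their sum.
#' @return energy in kcal/mol (or named 8-vector when `terms = TRUE`).
#' @export
pair_energy <- function(species1, center1, quat1, species2, center2, quat2,
                        box = NULL, terms = FALSE) {
  if (!length(species1$grids) || !length(species2$grids))
    stop("both species need grids (see build_species_grids)")
  d <- center2 - center1
  if (!is.null(box)) d <- d - box * round(d / box)
  tv <- cpp_pair_energy_terms(species_runtime(species1), center1, quat1,
                              species_runtime(species2), center1 + d, quat2)
  if (terms) tv else sum(tv)
}

#' Protein-surface interaction energy
#'
#' Non-polar desolvation plus soft-core repulsion of a body above the slab
#' (the electrostatic desolvation of the body's charges by the low-dielectric
#' slab can be included when the surface carries an `ed` grid).
#'
#' @param surface an `rbd_surface` with grids ([surface_grid_set()]).
#' @param species an [rbd_species()].
#' @param center,quat pose of the body.
#' @param include_ed include the slab's electrostatic desolvation field.
#' @return energy in kcal/mol; 0 when the body is above the grid top.
#' @export
surface_energy <- function(surface, species, center,
                           quat = c(1, 0, 0, 0), include_ed = FALSE) {
  if (!length(surface$grids)) stop("surface has no grids (see surface_grid_set)")
  cpp_surface_energy(lapply(surface$grids, unclass), include_ed,
                     species_runtime(species), center, quat)
}

#' Forces and torques by central finite differences
#'
#' Forces are finite-difference derivatives of the pairwise (and surface)
#' free energies: displacement `h_t` along each lab axis for the force and
#' rotation `h_r` about each body axis for the torque.
#'
#' @param species list of [rbd_species()] (with grids) present in the system.
#' @param body_species integer index into `species` for every body.
#' @param centers n x 3 matrix of body centers.
#' @param quats n x 4 matrix of unit quaternions.
#' @param box periodic box, 3-vector, Angstrom.
#' @param surface optional `rbd_surface` with grids (implies reflective z).
#' @param h_t translational step, Angstrom (default 0.5).
#' @param h_r rotational step, rad (default 0.02).
#' @param temperature K (enters only through bookkeeping, not the values).
#' @param method `"fd"` (central finite differences with steps `h_t`, `h_r`)
#'   or `"grad"` (exact gradient of the interpolated energy, the h -> 0
#'   limit of the finite differences; this is what the propagation engine
#'   uses).
#' @return list with `force` (n x 3, kcal/mol/Angstrom, lab frame) and
#'   `torque` (n x 3, kcal/mol, body frame).
#' @export
force_torque <- function(species, body_species, centers, quats, box,
                         surface = NULL, h_t = 0.5, h_r = 0.02,
                         temperature = 300, method = c("fd", "grad")) {
  method <- match.arg(method)
  centers <- rbind(centers)
  quats <- rbind(quats)
  sgrids <- if (!is.null(surface)) lapply(surface$grids, unclass) else list()
  cpp_system_forces(lapply(species, species_runtime),
                    as.integer(body_species) - 1L, centers, quats,
                    as.numeric(box), is.null(surface), sgrids, FALSE,
                    0.0019872041 * temperature, h_t, h_r, 0, numeric(0),
                    method == "grad")
}

#' Total system energy (sum over unique pairs plus surface terms)
#'
#' @inheritParams force_torque
#' @param surface optional surface with grids.
#' @return total energy, kcal/mol.
#' @export
system_energy <- function(species, body_species, centers, quats, box,
                          surface = NULL) {
  sgrids <- if (!is.null(surface)) lapply(surface$grids, unclass) else list()
  cpp_total_energy(lapply(species, species_runtime),
                   as.integer(body_species) - 1L, rbind(centers), rbind(quats),
                   as.numeric(box), is.null(surface), sgrids, FALSE)
}
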