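#' Synthetic amphipathic toy protein
#'
#' Builds a rigid spherical shell of beads (Fibonacci lattice) with a
#' contiguous hydrophobic cap and a simple charge arrangement, emulating the
#' phenomenology of a small amphipathic protein: a solvent-exposed
#' hydrophobic patch plus either a predominantly dipolar or a quadrupolar
#' electrostatic potential. The patch beads carry the solvent-accessible
#' area that the non-polar desolvation term rewards on burial; polar beads
#' carry none. Diffusion coefficients follow Stokes-Einstein at the given
#' temperature with solvent viscosity 1 cP.
#'
#' @param label species label.
#' @param n_beads beads on the shell.
#' @param body_radius shell radius, Angstrom (HFBI-scale default 15).
#' @param bead_radius bead radius, Angstrom.
#' @param patch_fraction fraction of beads in the hydrophobic cap (0-1,
#'   exclusive); the cap is contiguous around the +z pole.
#' @param charge_pattern `"dipolar"` (+q/-q on the patch axis),
#'   `"quadrupolar"` (four alternating charges in four sectors around the
#'   patch axis, placed near the patch rim; zero dipole) or `"neutral"`.
#'   The quadrupolar ring sits close to the hydrophobic cap so that a tight
#'   patch-to-patch contact brings its charges next to the partner's
#'   low-dielectric volume, which the electrostatic desolvation term
#'   penalizes -- the mechanism by which this conformer disfavours compact
#'   oligomers.
#' @param charge_magnitude site charge magnitude, elementary charges.
#' @param sasa_per_bead solvent accessible area carried by each patch bead,
#'   Angstrom^2; the default divides a 750 Angstrom^2 hydrophobic patch
#'   (HFBI scale) evenly over the cap beads.
#' @param polar_sasa_fraction fraction of `sasa_per_bead` carried by the
#'   polar beads. The parent all-atom model converts the buried
#'   solvent-accessible area of every atom via beta, not just the patch;
#'   a zero value makes face-to-face dimers absorbing end states (no
#'   residual attraction, hence no tetramers), while a modest value
#'   restores the weak non-specific burial attraction that lets dimers
#'   grow into the higher encounter complexes the solution study reports.
#' @param mass_kda molecular mass used for concentration/box conversions.
#' @param temperature K (for the diffusion constants).
#' @param flat_patch flatten the hydrophobic cap onto the plane tangent at
#'   its boundary (default). Amphipathic surface-active proteins expose a
#'   flat hydrophobic face, and a flat face is what lets the patch bury
#'   against a partner patch or a planar surface; a purely spherical cap
#'   makes only point contact and cannot reproduce either behaviour.
#' @param seed retained for interface completeness; the construction is
#'   deterministic.
#' @return an [rbd_species()] with `mass_kda` attached.
#' @export
make_toy_protein <- function(label = "toyA", n_beads = 64, body_radius = 15,
                             bead_radius = 3.0, patch_fraction = 0.27,
                             charge_pattern = c("dipolar", "quadrupolar",
                                                "neutral"),
                             charge_magnitude = 2.0, sasa_per_bead = NULL,
                             polar_sasa_fraction = 0.3,
                             mass_kda = 7.5, temperature = 300,
                             flat_patch = TRUE, seed = 1) {
  charge_pattern <- match.arg(charge_pattern)
  if (patch_fraction <= 0 || patch_fraction >= 1)
    stop("patch_fraction must be in (0, 1)")
  pts <- fibonacci_sphere(n_beads) * body_radius   # z descending: cap first
  k <- round(n_beads * patch_fraction)
  if (is.null(sasa_per_bead)) sasa_per_bead <- 750 / max(k, 1)
  z_cut <- if (k >= 1 && k < n_beads) as.numeric(pts[k, 3]) else 0
  if (flat_patch && k >= 1) {
    # project the cap onto the plane through the cap boundary
    pts[seq_len(k), 3] <- z_cut
  }
  is_patch <- seq_len(n_beads) <= k
  atoms <- data.frame(id = seq_len(n_beads),
                      residue_name = ifelse(is_patch, "HPB", "POL"),
                      residue_number = seq_len(n_beads),
                      atom_name = "BD",
                      x = pts[, 1], y = pts[, 2], z = pts[, 3],
                      radius = bead_radius, charge = 0,
                      sasa = ifelse(is_patch, sasa_per_bead,
                                    polar_sasa_fraction * sasa_per_bead))
  q <- charge_magnitude
  # dipolar sites sit on the patch axis, buried below the face; the
  # quadrupolar ring sits in four sectors at the rim of the hydrophobic
  # face, where a tight patch-patch contact exposes it to the partner's
  # low-dielectric volume (electrostatic desolvation penalty)
  r_face <- 0.8 * sqrt(max(body_radius^2 - z_cut^2, 0))
  charges <- switch(charge_pattern,
    dipolar = data.frame(x = 0, y = 0, z = c(0.35, -0.35) * body_radius,
                         q = c(q, -q)),
    quadrupolar = data.frame(x = c(r_face, 0, -r_face, 0),
                             y = c(0, r_face, 0, -r_face),
                             z = z_cut, q = c(q, -q, q, -q)),
    neutral = data.frame(x = numeric(), y = numeric(), z = numeric(),
                         q = numeric()))
  kb <- 1.380649e-23
  eta <- 1e-3                                        # Pa s
  r_m <- body_radius * 1e-10
  d_trans <- kb * temperature / (6 * pi * eta * r_m) * 1e11   # A^2/ns
  d_rot <- kb * temperature / (8 * pi * eta * r_m^3) * 1e-9   # rad^2/ns
  sp <- rbd_species(label, atoms, charges, d_trans = d_trans, d_rot = d_rot)
  sp$mass_kda <- mass_kda
  sp$patch_axis <- c(0, 0, 1)
  sp
}

#' Two-faced test bead
#'
#' A single shell body whose lower hemisphere (-z) carries all the
#' solvent-accessible area: a maximally anisotropic probe for surface
#' orientation preference.
#'
#' @param radius body radius, Angstrom.
#' @param n_beads beads on the shell.
#' @param sasa_per_bead area per hydrophobic bead, Angstrom^2.
#' @return an [rbd_species()]; the hydrophobic face points along -z.
#' @export
make_two_faced_bead <- function(radius = 15, n_beads = 32, sasa_per_bead = 90) {
  sp <- make_toy_protein(label = "twoface", n_beads = n_beads,
                         body_radius = radius, patch_fraction = 0.5,
                         charge_pattern = "neutral",
                         sasa_per_bead = sasa_per_bead,
                         polar_sasa_fraction = 0)
  # flip so the hydrophobic face is the -z hemisphere
  sp$atoms$z <- -sp$atoms$z
  sp
}

# 4-atom square plate used for planted configurations: contacts are easy to
# reason about and the atoms are mutually independent (side > d_min).
.plant_species <- function(label, side = 7, bead_radius = 1.5) {
  atoms <- data.frame(id = 1:4, residue_name = "PLT", residue_number = 1:4,
                      atom_name = "BD",
                      x = c(-1, 1, 1, -1) * side / 2,
                      y = c(-1, -1, 1, 1) * side / 2,
                      z = 0, radius = bead_radius, charge = 0, sasa = 25)
  rbd_species(label, atoms, d_trans = 20, d_rot = 0.05)
}

#' Planted configuration with known oligomer ground truth
#'
#' Places small rigid bodies so that a declared contact graph holds with a
#' margin of at least 0.3 Angstrom on every satisfied and violated distance
#' constraint, then verifies that the declared partition is recovered under
#' the given criterion.
#'
#' @param kind `"monomers"` (5 singletons), `"dimer"` (one dimer plus a
#'   monomer), `"linear-trimer"` (chain of 3: 1-2 and 2-3 in contact, 1-3
#'   not) or `"tetramer-2x2"` (connected group of 4 with species labels
#'   A,B,A,B).
#' @param criterion a [contact_criterion()].
#' @return list: `species`, `body_species`, `labels`, `state` (centers,
#'   quats, box, time), `truth` (list of index groups).
#' @export
make_planted_configuration <- function(kind = c("monomers", "dimer",
                                                "linear-trimer",
                                                "tetramer-2x2"),
                                       criterion = contact_criterion()) {
  kind <- match.arg(kind)
  dz_contact <- criterion$d_c - 0.7          # stacked plates: contact distance
  if (dz_contact <= 0.3) stop("infeasible geometry for this criterion")
  spA <- .plant_species("plantA")
  spB <- .plant_species("plantB")
  far <- 4 * (criterion$d_c + spA$bound_radius)
  place <- switch(kind,
    "monomers" = list(centers = cbind(seq(0, by = far, length.out = 5), 0, 0),
                      bs = rep(1, 5),
                      truth = as.list(1:5)),
    "dimer" = list(centers = rbind(c(0, 0, 0), c(0, 0, dz_contact),
                                   c(far, 0, 0)),
                   bs = rep(1, 3),
                   truth = list(c(1, 2), 3)),
    "linear-trimer" = list(centers = rbind(c(0, 0, 0), c(0, 0, dz_contact),
                                           c(0, 0, 2 * dz_contact)),
                           bs = rep(1, 3),
                           truth = list(c(1, 2, 3))),
    "tetramer-2x2" = list(centers = cbind(0, 0, (0:3) * dz_contact),
                          bs = c(1, 2, 1, 2),
                          truth = list(1:4)))
  n <- nrow(place$centers)
  state <- list(centers = place$centers,
                quats = matrix(rep(c(1, 0, 0, 0), n), n, 4, byrow = TRUE),
                box = rep(10 * far, 3), time = 0)
  species <- list(spA, spB)
  labels <- c("plantA", "plantB")[place$bs]
  # verify margins: every declared edge has contacts at <= d_c - 0.3 and
  # intra-atom independence at >= d_min + 0.3; non-edges clear d_c + 0.3
  apos <- as.matrix(spA$atoms[, c("x", "y", "z")])
  intra <- stats::dist(apos)
  if (min(intra) < criterion$d_min + 0.3)
    stop("infeasible geometry: plate side too small for d_min")
  truth_edges <- do.call(rbind, lapply(place$truth, function(g)
    if (length(g) > 1) cbind(g[-length(g)], g[-1]) else NULL))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dd <- cpp_min_cross_dist(
      sweep(apos, 2, place$centers[i, ], `+`),
      sweep(apos, 2, place$centers[j, ], `+`))
    is_edge <- !is.null(truth_edges) &&
      any(truth_edges[, 1] == i & truth_edges[, 2] == j)
    if (is_edge && dd > criterion$d_c - 0.3)
      stop("planted edge without margin")
    if (!is_edge && dd < criterion$d_c + 0.3)
      stop("planted non-edge without margin")
  }
  part <- partition_oligomers(state, species, place$bs, criterion)
  got <- lapply(part$groups, function(g) sort(as.integer(g)))
  want <- lapply(place$truth, function(g) sort(as.integer(g)))
  if (!identical(got[order(vapply(got, min, 0L))],
                 want[order(vapply(want, min, 0L))]))
    stop("planted configuration does not reproduce its ground truth")
  list(species = species, body_species = place$bs, labels = labels,
       state = state, truth = lapply(place$truth, as.integer),
       criterion = criterion)
}
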