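#' Rigid-body species
#'
#' Bundle an atom table with effective charge sites and diffusion constants
#' into the rigid-body description used throughout the simulator. Atom
#' positions are re-centered on their geometric center (the body frame origin);
#' the same shift is applied to the charge sites so the electrostatic moments
#' are preserved.
#'
#' @param label species label, e.g. `"chainA"` or `"toyA"`.
#' @param atoms data.frame with columns `id`, `residue_name`, `residue_number`,
#'   `atom_name`, `x`, `y`, `z` (Angstrom), `radius` (Angstrom), `charge`
#'   (elementary charges) and optionally `sasa` (Angstrom^2, computed in the
#'   unbound body).
#' @param charges optional data.frame of effective charge sites with columns
#'   `x`, `y`, `z`, `q`. When `NULL`, sites are derived from the atom table
#'   with [effective_charges()].
#' @param d_trans translational diffusion coefficient, Angstrom^2/ns.
#' @param d_rot rotational diffusion coefficient, rad^2/ns.
#' @return object of class `rbd_species`.
#' @export
rbd_species <- function(label, atoms, charges = NULL,
                        d_trans = 13.91, d_rot = 4.04e-2) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1)
  needed <- c("x", "y", "z", "radius", "charge")
  miss <- setdiff(needed, names(atoms))
  if (length(miss))
    stop("atoms table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom positions")
  if (any(atoms$radius <= 0)) stop("atom radii must be positive")
  if (!"sasa" %in% names(atoms)) atoms$sasa <- 0
  if (any(atoms$sasa < 0)) stop("negative SASA")
  if (!"id" %in% names(atoms)) atoms$id <- seq_len(nrow(atoms))
  if (!"atom_name" %in% names(atoms)) atoms$atom_name <- "X"
  if (!"residue_name" %in% names(atoms)) atoms$residue_name <- "UNK"
  if (!"residue_number" %in% names(atoms))
    atoms$residue_number <- seq_len(nrow(atoms))
  if (d_trans <= 0 || d_rot <= 0) stop("diffusion coefficients must be > 0")

  ctr <- colMeans(atoms[, c("x", "y", "z")])
  atoms$x <- atoms$x - ctr[1]
  atoms$y <- atoms$y - ctr[2]
  atoms$z <- atoms$z - ctr[3]
  if (is.null(charges)) {
    charges <- effective_charges(atoms)
  } else {
    stopifnot(all(c("x", "y", "z", "q") %in% names(charges)))
    charges$x <- charges$x - ctr[1]
    charges$y <- charges$y - ctr[2]
    charges$z <- charges$z - ctr[3]
    if (abs(sum(charges$q) - sum(atoms$charge)) > 1e-6)
      stop("effective charge sites do not preserve the net charge")
  }
  sp <- list(label = label, atoms = atoms, charges = charges,
             d_trans = d_trans, d_rot = d_rot, grids = list(),
             bound_radius = max(sqrt(atoms$x^2 + atoms$y^2 + atoms$z^2) +
                                  atoms$radius))
  class(sp) <- "rbd_species"
  sp
}

#' @export
print.rbd_species <- function(x, ...) {
  cat(sprintf("rigid-body species '%s': %d atoms, %d residues, net charge %+0.3f e\n",
              x$label, nrow(x$atoms),
              length(unique(x$atoms$residue_number)), sum(x$atoms$charge)))
  cat(sprintf("  Rg %.2f A | bounding radius %.2f A | D_t %.3g A^2/ns | D_r %.3g rad^2/ns\n",
              radius_of_gyration(x), x$bound_radius, x$d_trans, x$d_rot))
  cat(sprintf("  %d effective charge sites | grids: %s\n",
              nrow(x$charges),
              if (length(x$grids)) paste(names(x$grids), collapse = ",") else "none"))
  invisible(x)
}

# atoms whose centroid defines the charge site of an ionizable group
.charge_group_atoms <- list(
  ASP = c("CG", "OD1", "OD2"), GLU = c("CD", "OE1", "OE2"),
  LYS = "NZ", ARG = "CZ",
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  HID = c("CG", "ND1", "CD2", "CE1", "NE2"),
  HIE = c("CG", "ND1", "CD2", "CE1", "NE2"),
  HIP = c("CG", "ND1", "CD2", "CE1", "NE2"))

#' Effective charge sites from partial charges
#'
#' Collapse the per-atom partial charges of each residue carrying a net charge
#' into a single site located at the residue's charged group (carboxyl
#' centroid for Asp/Glu, Lys NZ, Arg CZ, His ring center; absolute-charge
#' weighted centroid otherwise, which also covers charged termini). The summed
#' site charges reproduce the molecule's net charge exactly; residues that are
#' internally neutral contribute no site.
#'
#' @param atoms atom table as in [rbd_species()] (already centered or not).
#' @param tol residues with |net charge| below `tol` are dropped.
#' @return data.frame with columns `x`, `y`, `z`, `q`.
#' @export
effective_charges <- function(atoms, tol = 1e-6) {
  out <- do.call(rbind, lapply(split(atoms, atoms$residue_number), function(res) {
    qtot <- sum(res$charge)
    if (abs(qtot) <= tol) return(NULL)
    grp <- .charge_group_atoms[[toupper(res$residue_name[1])]]
    sel <- if (!is.null(grp)) res$atom_name %in% grp else rep(FALSE, nrow(res))
    if (any(sel)) {
      pos <- colMeans(res[sel, c("x", "y", "z")])
    } else {
      w <- abs(res$charge)
      if (sum(w) == 0) w <- rep(1, nrow(res))
      pos <- c(sum(res$x * w), sum(res$y * w), sum(res$z * w)) / sum(w)
    }
    data.frame(x = pos[1], y = pos[2], z = pos[3], q = qtot)
  }))
  if (is.null(out)) out <- data.frame(x = numeric(), y = numeric(),
                                      z = numeric(), q = numeric())
  rownames(out) <- NULL
  out
}

#' Read a PQR file into a rigid-body species
#'
#' Parses the whitespace-delimited PQR dialect (as written by pdb2pqr and
#' kin): `ATOM`/`HETATM` records with fields id, atom name, residue name,
#' optional chain identifier, residue number, x, y, z, charge, radius.
#'
#' @param path file path.
#' @param label species label; defaults to the file name.
#' @param d_trans,d_rot diffusion coefficients to attach (simulation inputs).
#' @return an [rbd_species()] with atoms centered on the geometric center.
#' @export
load_pqr <- function(path, label = NULL,
                     d_trans = 13.91, d_rot = 4.04e-2) {
  lines <- readLines(path, warn = FALSE)
  recs <- grep("^(ATOM|HETATM)", lines)
  if (!length(recs)) stop("no ATOM/HETATM records in '", path, "'")
  rows <- vector("list", length(recs))
  for (k in seq_along(recs)) {
    ln <- recs[k]
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(tok) == 11) {
      tok <- tok[-5]  # drop chain identifier
    } else if (length(tok) != 10) {
      stop(sprintf("malformed PQR line %d: expected 10 or 11 fields, got %d",
                   ln, length(tok)))
    }
    num <- suppressWarnings(as.numeric(tok[c(2, 5:10)]))
    if (any(is.na(num)))
      stop(sprintf("malformed PQR line %d: non-numeric field", ln))
    rows[[k]] <- data.frame(id = num[1], atom_name = tok[3],
                            residue_name = tok[4], residue_number = num[2],
                            x = num[3], y = num[4], z = num[5],
                            charge = num[6], radius = num[7])
  }
  atoms <- do.call(rbind, rows)
  if (is.null(label)) label <- sub("\\.pqr$", "", basename(path))
  rbd_species(label, atoms, d_trans = d_trans, d_rot = d_rot)
}

#' Write a species back to PQR (whitespace dialect)
#' @param species an [rbd_species()].
#' @param path output file.
#' @export
write_pqr <- function(species, path) {
  a <- species$atoms
  lines <- sprintf("ATOM %6d %-4s %-4s %5d %11.4f %11.4f %11.4f %8.4f %7.4f",
                   a$id, a$atom_name, a$residue_name, a$residue_number,
                   a$x, a$y, a$z, a$charge, a$radius)
  writeLines(lines, path)
  invisible(path)
}

#' Radius of gyration
#'
#' Root-mean-square distance of the atoms from their geometric center, with
#' uniform (geometric) weighting.
#'
#' @param species an [rbd_species()] or an n x 3 coordinate matrix.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(species) {
  xyz <- if (inherits(species, "rbd_species"))
    as.matrix(species$atoms[, c("x", "y", "z")]) else as.matrix(species)
  if (nrow(xyz) < 1) stop("no atoms")
  ctr <- colMeans(xyz)
  sqrt(mean(rowSums(sweep(xyz, 2, ctr)^2)))
}

# quasi-uniform points on the unit sphere (Fibonacci lattice); deterministic
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Per-atom solvent accessible surface area
#'
#' Deterministic Shrake-Rupley style SASA: each atom's solvent sphere (radius
#' `r_i + probe`) is sampled with a fixed Fibonacci point set and points buried
#' inside any neighbour's solvent sphere are discarded.
#'
#' @param species an [rbd_species()] or atom table with `x,y,z,radius`.
#' @param probe_radius solvent probe radius in Angstrom (water: 1.4).
#' @param n_points sphere sample points per atom.
#' @return numeric vector of per-atom SASA (Angstrom^2); `sum()` gives the
#'   total SASA.
#' @export
compute_sasa <- function(species, probe_radius = 1.4, n_points = 960) {
  a <- if (inherits(species, "rbd_species")) species$atoms else species
  stopifnot(probe_radius >= 0, all(a$radius > 0))
  n <- nrow(a)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rs <- a$radius + probe_radius       # solvent sphere radii
  pts <- fibonacci_sphere(n_points)
  out <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (rs + rs[i])^2 & seq_len(n) != i)
    p <- sweep(pts * rs[i], 2, xyz[i, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj <- (p[acc, 1] - xyz[j, 1])^2 + (p[acc, 2] - xyz[j, 2])^2 +
        (p[acc, 3] - xyz[j, 3])^2
      acc[acc] <- dj > rs[j]^2
    }
    out[i] <- 4 * pi * rs[i]^2 * mean(acc)
  }
  out
}

#' One-line JSON summary of a species
#'
#' @param species an [rbd_species()].
#' @param path optional file to write the JSON to.
#' @return the summary list, invisibly when writing.
#' @export
species_summary <- function(species, path = NULL) {
  s <- list(label = species$label,
            n_atoms = nrow(species$atoms),
            n_residues = length(unique(species$atoms$residue_number)),
            net_charge = sum(species$atoms$charge),
            rg = radius_of_gyration(species),
            total_sasa = sum(species$atoms$sasa),
            bound_radius = species$bound_radius,
            d_trans = species$d_trans, d_rot = species$d_rot)
  if (!is.null(path)) {
    jsonlite::write_json(s, path, auto_unbox = TRUE, digits = NA)
    return(invisible(s))
  }
  s
}
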