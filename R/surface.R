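# graphite constants: C-C bond 1.42 A, interlayer 3.35 A, AB stacking
.hopg_bond <- 1.42
.hopg_interlayer <- 3.35
.hopg_cell <- c(2.46, 3 * 1.42)   # rectangular cell, 4 atoms
.hopg_cell_atoms <- matrix(c(0, 0,
                             1.23, 0.71,
                             1.23, 2.13,
                             0, 2.84), ncol = 2, byrow = TRUE)
.hopg_ab_shift <- c(1.23, 0.71)   # AB stacking offset (one bond vector)
.hopg_radius <- 1.7               # carbon van der Waals radius

#' Build a Highly Ordered Pyrolytic Graphite (HOPG) slab
#'
#' Generates an AB-stacked honeycomb carbon lattice (C-C bond 1.42 Angstrom,
#' interlayer spacing 3.35 Angstrom) filling `extent_x` by `extent_y` in the
#' plane, with the topmost layer at z = 0. The in-plane extents are snapped
#' down to whole rectangular unit cells (2.46 x 4.26 Angstrom) so that the
#' slab tiles periodically.
#'
#' @param extent_x,extent_y requested in-plane extents, Angstrom.
#' @param n_layers number of graphene layers (>= 1).
#' @return object of class `rbd_surface` with the lattice positions (n x 3
#'   matrix), carbon radius, snapped extents and the periodic cell.
#' @export
build_hopg_layer <- function(extent_x = 200, extent_y = 200, n_layers = 3) {
  if (n_layers < 1) stop("n_layers must be >= 1")
  ncx <- floor(extent_x / .hopg_cell[1])
  ncy <- floor(extent_y / .hopg_cell[2])
  if (ncx < 1 || ncy < 1) stop("extent smaller than one graphite unit cell")
  ex <- ncx * .hopg_cell[1]
  ey <- ncy * .hopg_cell[2]
  shifts <- expand.grid(ix = seq_len(ncx) - 1, iy = seq_len(ncy) - 1)
  one_layer <- function(offset2d) {
    base <- sweep(.hopg_cell_atoms, 2, offset2d, `+`)
    xy <- do.call(rbind, lapply(seq_len(nrow(shifts)), function(k) {
      cbind(base[, 1] + shifts$ix[k] * .hopg_cell[1],
            base[, 2] + shifts$iy[k] * .hopg_cell[2])
    }))
    xy[, 1] <- xy[, 1] %% ex
    xy[, 2] <- xy[, 2] %% ey
    xy
  }
  lat <- do.call(rbind, lapply(seq_len(n_layers) - 1, function(l) {
    off <- if (l %% 2 == 1) .hopg_ab_shift else c(0, 0)
    cbind(one_layer(off), z = -l * .hopg_interlayer)
  }))
  colnames(lat) <- c("x", "y", "z")
  surf <- list(lattice = lat, atom_radius = .hopg_radius,
               extent_x = ex, extent_y = ey, n_layers = n_layers,
               z_top = 0, cell = .hopg_cell, grids = list())
  class(surf) <- "rbd_surface"
  surf
}

#' @export
print.rbd_surface <- function(x, ...) {
  cat(sprintf("HOPG slab: %d atoms, %d layer(s), %.1f x %.1f A, top layer at z = %g\n",
              nrow(x$lattice), x$n_layers, x$extent_x, x$extent_y, x$z_top))
  invisible(x)
}

#' Write a surface lattice as PDB for visualization
#' @param surface an `rbd_surface`.
#' @param path output PDB path.
#' @export
write_surface_pdb <- function(surface, path) {
  lat <- surface$lattice
  n <- nrow(lat)
  lines <- sprintf(
    "ATOM  %5d  C   GRA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(n) %% 100000, (seq_len(n) - 1) %/% 4 %% 10000,
    lat[, 1], lat[, 2], lat[, 3])
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Interaction grids for the surface
#'
#' Maps the non-polar desolvation and soft-core repulsion fields of the slab
#' (plus optionally the electrostatic desolvation field) onto a grid that is
#' periodic over one rectangular graphite cell in x,y and extends from the top
#' atom plane (z = 0) up to `z_max`. Periodicity makes the tile exact for the
#' infinite slab: lattice atoms of neighbouring tiles are included out to the
#' interaction range of each field.
#'
#' @param surface an `rbd_surface` from [build_hopg_layer()].
#' @param model an [energy_model()]; the surface regime values are typical.
#' @param z_max grid height above the surface plane, Angstrom.
#' @param spacing target node spacing, Angstrom (snapped in x,y so that the
#'   cell period is a whole number of nodes).
#' @param include_ed also build the electrostatic desolvation field of the
#'   slab (off by default: protein-graphite interactions are non-polar +
#'   soft-core only).
#' @param np_ramp burial ramp of the slab's non-polar field, Angstrom.
#'   The slab's dense soft-core holds protein sites at a stand-off of
#'   several Angstrom above the top carbon plane, so the slab ramp is wider
#'   than the protein-protein one: a site at stand-off is about half
#'   buried. `NULL` uses the model's ramp.
#' @return the surface with `$grids` filled (fields `np`, `sc`, optionally
#'   `ed`), each a [grid3d()] with `periodic_xy = TRUE`.
#' @export
surface_grid_set <- function(surface, model = energy_model("surface"),
                             z_max = 60, spacing = 0.5, include_ed = FALSE,
                             np_ramp = 14) {
  if (!is.null(np_ramp)) model$nonpolar$ramp <- np_ramp
  cell <- surface$cell
  nx <- max(2L, as.integer(round(cell[1] / spacing)))
  ny <- max(2L, as.integer(round(cell[2] / spacing)))
  nz <- as.integer(round(z_max / spacing)) + 1L
  h <- c(cell[1] / nx, cell[2] / ny, spacing)
  dims <- c(nx, ny, nz)
  origin <- c(0, 0, 0)

  # replicate lattice atoms in neighbouring tiles out to the field range
  rep_atoms <- function(range) {
    kx <- ceiling(range / cell[1]); ky <- ceiling(range / cell[2])
    reps <- expand.grid(ix = -kx:kx, iy = -ky:ky)
    lat <- surface$lattice
    # base tile atoms only (those within one cell), then replicate
    base <- lat[lat[, 1] < cell[1] - 1e-6 & lat[, 2] < cell[2] - 1e-6, , drop = FALSE]
    out <- do.call(rbind, lapply(seq_len(nrow(reps)), function(k) {
      cbind(base[, 1] + reps$ix[k] * cell[1],
            base[, 2] + reps$iy[k] * cell[2], base[, 3])
    }))
    out[out[, 1] > -range & out[, 1] < cell[1] + range &
          out[, 2] > -range & out[, 2] < cell[2] + range, , drop = FALSE]
  }

  sc <- model$softcore
  npp <- model$nonpolar
  # soft-core: negligible beyond a * (gamma/tol)^(1/nexp)
  rng_sc <- surface$atom_radius * (sc$gamma / 1e-4)^(1 / sc$nexp)
  at_sc <- rep_atoms(rng_sc)
  v_sc <- cpp_grid_sc(at_sc[, 1:3, drop = FALSE],
                      rep(surface$atom_radius, nrow(at_sc)),
                      origin, h, as.integer(dims),
                      sc$gamma, sc$sigma, as.integer(sc$nexp))
  rng_np <- surface$atom_radius + npp$ramp + 1
  at_np <- rep_atoms(rng_np)
  v_np <- cpp_grid_np(at_np[, 1:3, drop = FALSE],
                      rep(surface$atom_radius, nrow(at_np)),
                      origin, h, as.integer(dims), npp$beta, npp$ramp)
  g <- list(
    np = grid3d(origin, h, dims, array(v_np, dims), periodic_xy = TRUE,
                field = "np"),
    sc = grid3d(origin, h, dims, array(v_sc, dims), periodic_xy = TRUE,
                field = "sc"))
  if (include_ed) {
    el <- model$electro
    rng_ed <- 25
    at_ed <- rep_atoms(rng_ed)
    v_ed <- cpp_grid_ed(at_ed[, 1:3, drop = FALSE],
                        rep(surface$atom_radius, nrow(at_ed)),
                        origin, h, as.integer(dims), el$kappa,
                        el$solvent_dielectric, el$solute_dielectric,
                        model$alpha_ed)
    g$ed <- grid3d(origin, h, dims, array(v_ed, dims), periodic_xy = TRUE,
                   field = "ed")
  }
  surface$grids <- g
  surface
}
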