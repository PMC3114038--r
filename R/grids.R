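#' Regular 3-D scalar grid
#'
#' @param origin 3-vector, position of node (1,1,1), Angstrom.
#' @param spacing node spacing, Angstrom; a scalar for uniform grids or a
#'   3-vector (the tile-periodic surface grids use per-axis spacing so that
#'   the graphite cell is a whole number of nodes).
#' @param dims 3 integers, nodes per axis (>= 2).
#' @param values array of dimension `dims`.
#' @param periodic_xy logical; when TRUE the grid tiles periodically in x,y
#'   with period `dims * spacing` (no duplicated end node).
#' @param field field kind tag: "el", "ed", "np" or "sc".
#' @return object of class `grid3d`.
#' @export
grid3d <- function(origin, spacing, dims, values, periodic_xy = FALSE,
                   field = "") {
  dims <- as.integer(dims)
  stopifnot(length(origin) == 3, length(dims) == 3, all(dims >= 2),
            all(spacing > 0), length(spacing) %in% c(1, 3))
  if (!all(dim(values) == dims)) stop("values dimension does not match dims")
  if (any(!is.finite(values))) stop("non-finite grid values")
  g <- list(origin = as.numeric(origin), spacing = as.numeric(spacing),
            dims = dims, values = values, periodic_xy = isTRUE(periodic_xy),
            field = field)
  class(g) <- "grid3d"
  g
}

#' @export
print.grid3d <- function(x, ...) {
  cat(sprintf("grid3d [%s]: %d x %d x %d nodes, spacing %s A%s, origin (%g, %g, %g)\n",
              if (nzchar(x$field)) x$field else "?", x$dims[1], x$dims[2],
              x$dims[3], paste(signif(x$spacing, 4), collapse = "/"),
              if (x$periodic_xy) ", periodic in x,y" else "",
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Node counts for a cube of a given size
#'
#' The convention used throughout: "grid size L at spacing h" means inclusive
#' end nodes, i.e. `round(L/h) + 1` nodes per axis, centered on the body
#' origin (so an 80 Angstrom grid at 1.0 Angstrom spacing has 81 nodes).
#'
#' @param size edge length(s), Angstrom (scalar or 3-vector).
#' @param spacing node spacing, Angstrom.
#' @return integer 3-vector of node counts.
#' @export
grid_dims <- function(size, spacing) {
  size <- rep_len(size, 3)
  as.integer(round(size / spacing)) + 1L
}

.centered_geometry <- function(size, spacing) {
  dims <- grid_dims(size, spacing)
  origin <- -(dims - 1) * spacing / 2
  list(origin = origin, dims = dims)
}

.check_grid_covers <- function(species, size) {
  if (min(rep_len(size, 3)) / 2 < species$bound_radius)
    stop("grid smaller than the molecule bounding sphere (size ", min(size),
         " A, bounding radius ", round(species$bound_radius, 1), " A)")
}

#' Electrostatic model parameters
#'
#' The Debye screening parameter follows from the ionic strength and
#' temperature via kappa^2 = 8 pi l_B n_ion for a 1:1 electrolyte, with the
#' Bjerrum length l_B = 332.0636 / (eps_s k_B T) Angstrom.
#'
#' @param ionic_strength mM.
#' @param temperature K.
#' @param solvent_dielectric,solute_dielectric relative dielectric constants.
#' @return list with the inputs plus `kappa` (1/Angstrom).
#' @export
electrostatic_params <- function(ionic_strength = 50, temperature = 300,
                                 solvent_dielectric = 78.0,
                                 solute_dielectric = 2.0) {
  kbt <- 0.0019872041 * temperature               # kcal/mol
  lb <- 332.0636 / (solvent_dielectric * kbt)     # Bjerrum length, A
  nion <- ionic_strength * 1e-3 * 6.02214076e23 * 1e-27  # ions/A^3
  kappa <- sqrt(8 * pi * lb * nion)
  list(ionic_strength = ionic_strength, temperature = temperature,
       solvent_dielectric = solvent_dielectric,
       solute_dielectric = solute_dielectric, kappa = kappa)
}

#' Interaction energy model (parameter sets)
#'
#' The two regimes bundle the published parameterizations: `"solution"`
#' (protein-only runs: soft-core sigma 3.0 Angstrom, beta -0.018
#' kcal/mol/Angstrom^2) and `"surface"` (runs with the graphite slab:
#' sigma rescaled to 1.5 Angstrom for smoothness, beta -0.013
#' kcal/mol/Angstrom^2). gamma = 64 kcal/mol and nexp = 6 in both.
#'
#' @param regime `"solution"` or `"surface"`.
#' @param electro an [electrostatic_params()] list.
#' @param gamma,sigma,nexp soft-core repulsion parameters (kcal/mol,
#'   Angstrom, exponent); defaults depend on `regime`.
#' @param beta non-polar desolvation conversion factor, kcal/mol/Angstrom^2
#'   (negative: burial of area is favourable); default depends on `regime`.
#' @param probe_radius solvent probe, Angstrom.
#' @param ramp width of the linear burial ramp beyond the solvent-excluded
#'   region; defaults to one probe diameter.
#' @param alpha_ed scaling constant of the electrostatic desolvation field.
#' @return list of class `energy_model`.
#' @export
energy_model <- function(regime = c("solution", "surface"),
                         electro = electrostatic_params(),
                         gamma = 64, sigma = NULL, nexp = 6,
                         beta = NULL, probe_radius = 1.4, ramp = NULL,
                         alpha_ed = 1.67) {
  regime <- match.arg(regime)
  if (is.null(sigma)) sigma <- if (regime == "surface") 1.5 else 3.0
  if (is.null(beta)) beta <- if (regime == "surface") -0.013 else -0.018
  if (is.null(ramp)) ramp <- 2 * probe_radius
  stopifnot(gamma > 0, sigma > 0, nexp >= 2, beta < 0, probe_radius >= 0)
  m <- list(regime = regime, electro = electro,
            softcore = list(gamma = gamma, sigma = sigma, nexp = as.integer(nexp)),
            nonpolar = list(beta = beta, probe_radius = probe_radius, ramp = ramp),
            alpha_ed = alpha_ed)
  class(m) <- "energy_model"
  m
}

#' Electrostatic potential grid (screened Coulomb fallback)
#'
#' Debye-Hueckel superposition over the species' effective charge sites:
#' Phi(r) = sum_j q_j C exp(-kappa d_j) / (eps_s d_j), C = 332.0636
#' kcal Angstrom / mol / e^2. An externally solved Poisson-Boltzmann grid in
#' OpenDX format can be used instead via [read_dx()] and
#' [attach_species_grids()].
#'
#' @param species an [rbd_species()].
#' @param params an [electrostatic_params()] list.
#' @param size cubic grid edge, Angstrom.
#' @param spacing node spacing, Angstrom.
#' @param clamp_d distances below this are clamped when evaluating the
#'   superposition (keeps the fallback finite at the sites).
#' @return a [grid3d()] in kcal/mol/e, body frame, centered on the origin.
#' @export
electrostatic_grid <- function(species, params = electrostatic_params(),
                               size = 80, spacing = 1.0, clamp_d = 1.0) {
  stopifnot(spacing > 0)
  .check_grid_covers(species, size)
  geo <- .centered_geometry(size, spacing)
  sites <- as.matrix(species$charges[, c("x", "y", "z"), drop = FALSE])
  q <- species$charges$q
  if (nrow(sites) == 0) { sites <- matrix(0, 0, 3); q <- numeric() }
  v <- cpp_grid_el(sites, q, geo$origin, spacing, geo$dims, params$kappa,
                   params$solvent_dielectric, clamp_d)
  grid3d(geo$origin, spacing, geo$dims, array(v, geo$dims), field = "el")
}

#' Electrostatic desolvation grid
#'
#' Penalty field acting on the squared charges of the partner:
#' Phi_ed(r) = alpha C (eps_s - eps_p) / (eps_s (2 eps_s + eps_p)) *
#' sum_i a_i^3 exp(-2 kappa d_i) / d_i^4, clamped inside atoms (d_i < a_i
#' treated as a_i).
#'
#' @inheritParams electrostatic_grid
#' @param alpha scaling constant (default 1.67).
#' @return a [grid3d()] in kcal/mol/e^2.
#' @export
electrostatic_desolvation_grid <- function(species,
                                           params = electrostatic_params(),
                                           size = 80, spacing = 1.0,
                                           alpha = 1.67) {
  stopifnot(spacing > 0)
  .check_grid_covers(species, size)
  geo <- .centered_geometry(size, spacing)
  a <- species$atoms
  v <- cpp_grid_ed(as.matrix(a[, c("x", "y", "z")]), a$radius, geo$origin,
                   spacing, geo$dims, params$kappa, params$solvent_dielectric,
                   params$solute_dielectric, alpha)
  grid3d(geo$origin, spacing, geo$dims, array(v, geo$dims), field = "ed")
}

#' Non-polar (hydrophobic) desolvation grid
#'
#' Field value beta * b(r): a partner atom of solvent accessible area A placed
#' at r contributes beta * A * b(r), where the burial fraction b is 1 inside
#' the species' solvent-excluded region and decays linearly to 0 over `ramp`
#' Angstrom beyond the closest atom surface.
#'
#' @inheritParams electrostatic_grid
#' @param np non-polar parameters (`beta`, `probe_radius`, `ramp`), e.g.
#'   `energy_model("solution")$nonpolar`.
#' @return a [grid3d()] in kcal/mol/Angstrom^2.
#' @export
nonpolar_grid <- function(species, np = energy_model("solution")$nonpolar,
                          size = 80, spacing = 1.0) {
  stopifnot(spacing > 0, np$beta < 0)
  .check_grid_covers(species, size)
  geo <- .centered_geometry(size, spacing)
  a <- species$atoms
  ramp <- if (!is.null(np$ramp)) np$ramp else 2 * np$probe_radius
  v <- cpp_grid_np(as.matrix(a[, c("x", "y", "z")]), a$radius, geo$origin,
                   spacing, geo$dims, np$beta, ramp)
  grid3d(geo$origin, spacing, geo$dims, array(v, geo$dims), field = "np")
}

#' Soft-core repulsion grid
#'
#' E_sc(r) = gamma sum_i a_i^nexp / (|r - r_i|^nexp + sigma^nexp): finite at
#' atom centers (the sigma^nexp term removes the singularity), smoothness set
#' by sigma, decay by nexp, magnitude by gamma.
#'
#' @inheritParams electrostatic_grid
#' @param sc soft-core parameters (`gamma`, `sigma`, `nexp`), e.g.
#'   `energy_model("solution")$softcore`.
#' @return a [grid3d()] in kcal/mol.
#' @export
softcore_grid <- function(species, sc = energy_model("solution")$softcore,
                          size = 60, spacing = 1.0) {
  stopifnot(spacing > 0, sc$gamma > 0, sc$sigma > 0, sc$nexp >= 2)
  .check_grid_covers(species, size)
  geo <- .centered_geometry(size, spacing)
  a <- species$atoms
  v <- cpp_grid_sc(as.matrix(a[, c("x", "y", "z")]), a$radius, geo$origin,
                   spacing, geo$dims, sc$gamma, sc$sigma, as.integer(sc$nexp))
  grid3d(geo$origin, spacing, geo$dims, array(v, geo$dims), field = "sc")
}

#' Build and attach the four interaction grids of a species
#'
#' @param species an [rbd_species()].
#' @param model an [energy_model()].
#' @param size_el,size_np,size_sc grid edges, Angstrom (defaults follow the
#'   published setup: 80 Angstrom electrostatic/non-polar, 60 Angstrom
#'   soft-core).
#' @param spacing node spacing, Angstrom, for the short-ranged np/sc fields.
#' @param spacing_el spacing of the smooth el/ed fields (defaults to
#'   `spacing`).
#' @param skip_electro skip the el/ed fields (species with no charge sites
#'   skip the el field automatically).
#' @return the species with `$grids` filled.
#' @export
build_species_grids <- function(species, model = energy_model("solution"),
                                size_el = 80, size_np = 80, size_sc = 60,
                                spacing = 1.0, spacing_el = spacing,
                                skip_electro = FALSE) {
  g <- list()
  if (!skip_electro) {
    if (nrow(species$charges) > 0 && any(species$charges$q != 0))
      g$el <- electrostatic_grid(species, model$electro, size_el, spacing_el)
    g$ed <- electrostatic_desolvation_grid(species, model$electro, size_el,
                                           spacing_el, model$alpha_ed)
  }
  g$np <- nonpolar_grid(species, model$nonpolar, size_np, spacing)
  g$sc <- softcore_grid(species, model$softcore, size_sc, spacing)
  species$grids <- g
  species
}

#' Attach externally computed grids (e.g. an imported Poisson-Boltzmann map)
#'
#' @param species an [rbd_species()].
#' @param ... named [grid3d()] objects among `el`, `ed`, `np`, `sc`.
#' @export
attach_species_grids <- function(species, ...) {
  g <- list(...)
  stopifnot(all(names(g) %in% c("el", "ed", "np", "sc")))
  for (nm in names(g)) species$grids[[nm]] <- g[[nm]]
  species
}

#' Trilinear interpolation on a grid
#'
#' Exact at grid nodes and for multilinear fields. Points outside the grid
#' either raise an error or evaluate to `0` (the convention used by the
#' energy evaluation: all fields vanish beyond their grids).
#'
#' @param grid a [grid3d()].
#' @param points n x 3 matrix (or length-3 vector) of query points.
#' @param outside `"error"` or `"zero"`.
#' @return numeric vector of interpolated values.
#' @export
trilinear_interpolate <- function(grid, points, outside = c("error", "zero")) {
  outside <- match.arg(outside)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  points <- as.matrix(points)
  if (outside == "error") {
    inside <- cpp_in_grid(unclass(grid), points)
    if (!all(inside))
      stop("point(s) outside the grid: rows ",
           paste(utils::head(which(!inside), 5), collapse = ", "))
  }
  cpp_trilinear(unclass(grid), points, 0.0)
}

# ---- OpenDX scalar grid I/O -------------------------------------------------

#' Write a grid in OpenDX scalar format
#'
#' @param grid a [grid3d()].
#' @param path output file.
#' @param comment optional comment line(s) written as `#` header.
#' @export
write_dx <- function(grid, path, comment = NULL) {
  d <- grid$dims
  h <- rep_len(grid$spacing, 3)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste("#", comment), con)
  writeLines(sprintf("object 1 class gridpositions counts %d %d %d",
                     d[1], d[2], d[3]), con)
  writeLines(sprintf("origin %.17g %.17g %.17g",
                     grid$origin[1], grid$origin[2], grid$origin[3]), con)
  writeLines(sprintf("delta %.17g 0 0", h[1]), con)
  writeLines(sprintf("delta 0 %.17g 0", h[2]), con)
  writeLines(sprintf("delta 0 0 %.17g", h[3]), con)
  writeLines(sprintf("object 2 class gridconnections counts %d %d %d",
                     d[1], d[2], d[3]), con)
  writeLines(sprintf("object 3 class array type double rank 0 items %d data follows",
                     prod(d)), con)
  # DX data order: last index (z) varies fastest
  v <- as.vector(aperm(grid$values, c(3, 2, 1)))
  n3 <- (length(v) %/% 3) * 3
  if (n3 > 0) {
    m <- matrix(v[seq_len(n3)], nrow = 3)
    writeLines(apply(m, 2, function(r) paste(sprintf("%.17g", r), collapse = " ")),
               con)
  }
  if (n3 < length(v))
    writeLines(paste(sprintf("%.17g", v[(n3 + 1):length(v)]), collapse = " "), con)
  writeLines(c('attribute "dep" string "positions"',
               'object "regular positions regular connections" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}

#' Read an OpenDX scalar grid
#'
#' @param path DX file (as written by [write_dx()], APBS or UHBD exporters).
#' @param field field kind tag to attach.
#' @return a [grid3d()].
#' @export
read_dx <- function(path, field = "") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  gp <- grep("class gridpositions counts", lines, value = TRUE)[1]
  if (is.na(gp)) stop("not an OpenDX grid: no gridpositions object")
  dims <- as.integer(utils::tail(strsplit(trimws(gp), "\\s+")[[1]], 3))
  org <- grep("^origin", lines, value = TRUE)[1]
  origin <- as.numeric(strsplit(trimws(org), "\\s+")[[1]][2:4])
  deltas <- grep("^delta", lines, value = TRUE)[1:3]
  dm <- t(vapply(deltas, function(s)
    as.numeric(strsplit(trimws(s), "\\s+")[[1]][2:4]), numeric(3)))
  if (any(abs(dm[upper.tri(dm)]) > 0) || any(abs(dm[lower.tri(dm)]) > 0))
    stop("only axis-aligned grids are supported")
  spacing <- diag(dm)
  if (isTRUE(all.equal(spacing, rep(spacing[1], 3), tolerance = 1e-12)))
    spacing <- spacing[1]
  istart <- grep("data follows", lines)[1]
  iend <- grep("^attribute|^object \"", lines)
  iend <- min(iend[iend > istart], length(lines) + 1)
  v <- as.numeric(unlist(strsplit(trimws(lines[(istart + 1):(iend - 1)]), "\\s+")))
  v <- v[!is.na(v)]
  if (length(v) != prod(dims)) stop("DX data length does not match counts")
  vals <- aperm(array(v, rev(dims)), c(3, 2, 1))
  grid3d(origin, spacing, dims, vals, field = field)
}
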