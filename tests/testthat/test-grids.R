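# soft-core, electrostatic, desolvation and non-polar fields against their
# closed forms, plus interpolation and OpenDX round trips

one_atom <- function(radius = 3) rbd_species("a", atoms_df(c(0, 0, 0), radius = radius))

test_that("soft-core field matches gamma a^n / (d^n + sigma^n)", {
  g <- softcore_grid(one_atom(3), list(gamma = 64, sigma = 3, nexp = 6),
                     size = 20, spacing = 1)
  expect_equal(trilinear_interpolate(g, c(0, 0, 0)), 64)
  expect_equal(trilinear_interpolate(g, c(6, 0, 0)), 64 * 3^6 / (6^6 + 3^6))
  # strictly decreasing along a ray (node values)
  vals <- trilinear_interpolate(g, cbind(0:9, 0, 0))
  expect_true(all(diff(vals) < 0))
})

test_that("screened Coulomb field matches closed forms and limits", {
  spq <- rbd_species("q", atoms_df(c(0, 0, 0), radius = 1, charge = 1))
  p0 <- electrostatic_params(ionic_strength = 0, solvent_dielectric = 78)
  g <- electrostatic_grid(spq, p0, size = 30, spacing = 1)
  expect_equal(trilinear_interpolate(g, c(10, 0, 0)), 332.0636 / (78 * 10),
               tolerance = 1e-9)
  # strong screening kills the field off-site
  ph <- electrostatic_params(ionic_strength = 5e6)
  gh <- electrostatic_grid(spq, ph, size = 30, spacing = 1)
  expect_lt(abs(trilinear_interpolate(gh, c(5, 0, 0))), 1e-6)
  # dipole antisymmetry along its axis
  dip <- rbd_species("d", atoms_df(rbind(c(0, 0, 2), c(0, 0, -2)),
                                   radius = 1, charge = c(1, -1)))
  gd <- electrostatic_grid(dip, electrostatic_params(), size = 30, spacing = 1)
  expect_equal(trilinear_interpolate(gd, c(0, 0, 8)),
               -trilinear_interpolate(gd, c(0, 0, -8)), tolerance = 1e-9)
})

test_that("Debye parameter follows from ionic strength and temperature", {
  p <- electrostatic_params(ionic_strength = 50, temperature = 300,
                            solvent_dielectric = 78)
  expect_equal(1 / p$kappa, 13.6, tolerance = 0.02)  # ~13.6 A at 50 mM
  expect_equal(electrostatic_params(ionic_strength = 200)$kappa / p$kappa, 2,
               tolerance = 1e-9)
})

test_that("electrostatic desolvation field decays, scales as a^3 and superposes", {
  p <- electrostatic_params()
  ed1 <- electrostatic_desolvation_grid(one_atom(2), p, size = 30, spacing = 1)
  vals <- trilinear_interpolate(ed1, cbind(3:12, 0, 0))
  expect_true(all(diff(vals) < 0))
  ed2 <- electrostatic_desolvation_grid(one_atom(4), p, size = 30, spacing = 1)
  # doubling the radius multiplies the far field by 8 (modulo the clamp region)
  expect_equal(trilinear_interpolate(ed2, c(10, 0, 0)) /
                 trilinear_interpolate(ed1, c(10, 0, 0)), 8, tolerance = 1e-6)
  # two-atom field equals the sum of one-atom fields
  two <- rbd_species("t", atoms_df(rbind(c(-2, 0, 0), c(2, 0, 0)), radius = 2))
  edt <- electrostatic_desolvation_grid(two, p, size = 30, spacing = 1)
  pts <- cbind(c(5, 7, 9), c(1, -2, 3), 0)
  direct <- sapply(seq_len(3), function(k) {
    d1 <- sqrt(sum((pts[k, ] - c(-2, 0, 0))^2))
    d2 <- sqrt(sum((pts[k, ] - c(2, 0, 0))^2))
    pref <- 1.67 * 332.0636 * (78 - 2) / (78 * (2 * 78 + 2))
    pref * 8 * (exp(-2 * p$kappa * d1) / d1^4 + exp(-2 * p$kappa * d2) / d2^4)
  })
  # compare at nodes (pts chosen on nodes)
  expect_equal(trilinear_interpolate(edt, pts), direct, tolerance = 1e-9)
})

test_that("non-polar burial field is beta inside, zero far, non-positive", {
  np <- list(beta = -0.018, probe_radius = 1.4, ramp = 2.8)
  g <- nonpolar_grid(one_atom(3), np, size = 20, spacing = 0.5)
  expect_equal(trilinear_interpolate(g, c(0, 0, 0)), -0.018)  # deep inside
  expect_equal(trilinear_interpolate(g, c(9, 0, 0)), 0)       # beyond ramp
  expect_true(all(g$values <= 0))
  # contribution of a partner atom with area A is beta * A inside
  expect_equal(trilinear_interpolate(g, c(1, 0, 0)) * 100, -1.8)
})

test_that("trilinear interpolation is exact at nodes and for linear fields", {
  set.seed(11)
  vals <- array(rnorm(5^3), c(5, 5, 5))
  g <- grid3d(c(-2, -2, -2), 1, c(5, 5, 5), vals)
  expect_equal(trilinear_interpolate(g, c(0, 1, -1)), vals[3, 4, 2])
  const <- grid3d(c(0, 0, 0), 1, c(4, 4, 4), array(7, c(4, 4, 4)))
  expect_equal(trilinear_interpolate(const, c(1.3, 2.7, 0.2)), 7)
  lin <- array(0, c(6, 6, 6))
  for (i in 1:6) for (j in 1:6) for (k in 1:6)
    lin[i, j, k] <- 2 * (i - 1) + 3 * (j - 1) - (k - 1)
  gl <- grid3d(c(0, 0, 0), 1, c(6, 6, 6), lin)
  pts <- matrix(runif(30, 0.1, 4.9), ncol = 3)
  expect_equal(trilinear_interpolate(gl, pts),
               2 * pts[, 1] + 3 * pts[, 2] - pts[, 3], tolerance = 1e-12)
  # out-of-grid handling
  expect_error(trilinear_interpolate(gl, c(10, 0, 0)), "outside")
  expect_equal(trilinear_interpolate(gl, c(10, 0, 0), outside = "zero"), 0)
})

test_that("OpenDX round trip is value-identical", {
  g <- softcore_grid(one_atom(2), list(gamma = 64, sigma = 3, nexp = 6),
                     size = 10, spacing = 1)
  path <- tempfile(fileext = ".dx")
  write_dx(g, path, comment = "test field")
  g2 <- read_dx(path, field = "sc")
  expect_identical(g2$values, g$values)
  expect_identical(g2$dims, g$dims)
  expect_equal(g2$origin, g$origin)
  expect_equal(g2$spacing, g$spacing)
  # second write is byte-identical
  path2 <- tempfile(fileext = ".dx")
  write_dx(g2, path2, comment = "test field")
  expect_identical(readLines(path), readLines(path2))
})

test_that("grid node convention: size L at spacing h means round(L/h)+1 nodes", {
  expect_equal(grid_dims(80, 1.0), rep(81L, 3))
  expect_equal(grid_dims(60, 1.0), rep(61L, 3))
  expect_equal(grid_dims(c(200, 200, 60), 0.5), c(401L, 401L, 121L))
})

test_that("grid energies converge: halving the spacing changes the pair energy < 2%", {
  A1 <- build_species_grids(make_toy_protein("cvA"), toy_energy_model(),
                            size_el = 50, size_np = 56, size_sc = 56,
                            spacing = 1.0, spacing_el = 1.0)
  A2 <- build_species_grids(make_toy_protein("cvA"), toy_energy_model(),
                            size_el = 50, size_np = 56, size_sc = 56,
                            spacing = 0.5, spacing_el = 1.0)
  # probe bound-basin configurations (the physically operative region;
  # the steep repulsive wall converges more slowly but only needs to repel)
  qflip <- quat_axis_angle(c(1, 0, 0), pi)
  for (D in c(25, 26)) {
    e1 <- pair_energy(A1, c(0, 0, 0), c(1, 0, 0, 0), A1, c(0, 0, D), qflip)
    e2 <- pair_energy(A2, c(0, 0, 0), c(1, 0, 0, 0), A2, c(0, 0, D), qflip)
    expect_lt(abs(e1 - e2) / abs(e2), 0.02)
  }
})

test_that("a zero-charge species produces no electrostatic terms", {
  N <- prepare_toy_species(make_toy_protein("neut", charge_pattern = "neutral"))
  expect_null(N$grids$el)
  qflip <- quat_axis_angle(c(1, 0, 0), pi)
  tv <- pair_energy(N, c(0, 0, 0), c(1, 0, 0, 0), N, c(0, 0, 25), qflip,
                    terms = TRUE)
  expect_equal(unname(tv[c("el1", "ed1", "el2", "ed2")]), rep(0, 4))
})

test_that("grids refuse to be smaller than the molecule", {
  expect_error(softcore_grid(make_toy_protein("big"), size = 20), "bounding")
})
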