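test_that("PQR parsing preserves atoms, charges and bookkeeping", {
  path <- write_tmp_pqr(c(
    pqr_line(1, "N", "ALA", 1, 0, 0, 0, 1, 1.5),
    pqr_line(2, "CA", "ALA", 1, 1.5, 0, 0, -1, 1.7),
    pqr_line(3, "C", "ALA", 1, 3, 0, 0, 0, 1.7)))
  sp <- load_pqr(path)
  expect_equal(nrow(sp$atoms), 3)
  expect_equal(sum(sp$atoms$charge), 0)
  expect_equal(length(unique(sp$atoms$residue_number)), 1)
  # net charge of the effective sites equals the summed partial charges
  expect_lt(abs(sum(sp$charges$q) - sum(sp$atoms$charge)), 1e-6)
})

test_that("PQR atoms are re-centered on the geometric center", {
  path <- write_tmp_pqr(c(
    pqr_line(1, "X", "GLY", 1, 4, 5, 5, 0.3, 1.5),
    pqr_line(2, "Y", "GLY", 2, 6, 5, 5, -0.3, 1.5)))
  sp <- load_pqr(path)
  expect_lt(max(abs(colMeans(sp$atoms[, c("x", "y", "z")]))), 1e-9)
})

test_that("malformed PQR lines are reported with their line number", {
  path <- write_tmp_pqr(c(
    pqr_line(1, "X", "GLY", 1, 0, 0, 0, 0, 1.5),
    "ATOM 2 X GLY 2 1.0 oops 0.0 0.0 1.5"))
  expect_error(load_pqr(path), "line 2")
  expect_error(load_pqr(write_tmp_pqr("REMARK nothing")), "no ATOM")
})

test_that("PQR round trip preserves coordinates, charges and radii", {
  sp <- make_toy_protein("rt", n_beads = 16)
  path <- tempfile(fileext = ".pqr")
  write_pqr(sp, path)
  sp2 <- load_pqr(path)
  expect_equal(as.matrix(sp2$atoms[, c("x", "y", "z")]),
               as.matrix(sp$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(sp2$atoms$radius, sp$atoms$radius, tolerance = 1e-3)
})

test_that("effective charge sites sit on charged groups and conserve charge", {
  atoms <- rbind(
    atoms_df(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), charge = c(0, -0.5, -0.5),
             residue_number = 1),
    atoms_df(rbind(c(5, 0, 0), c(6, 0, 0)), charge = c(0.1, -0.1),
             residue_number = 2))
  atoms$residue_name <- c(rep("ASP", 3), rep("GLY", 2))
  atoms$atom_name <- c("CB", "OD1", "OD2", "N", "C")
  atoms$id <- 1:5
  ec <- effective_charges(atoms)
  expect_equal(nrow(ec), 1)           # GLY residue is internally neutral
  expect_equal(ec$q, -1)
  # Asp site at the carboxyl centroid (OD1, OD2 present; CG absent -> their mean)
  expect_equal(unlist(ec[1, c("x", "y", "z")]), c(1, 0.5, 0),
               ignore_attr = TRUE)
})

test_that("radius of gyration matches closed forms and is rigid-motion invariant", {
  d <- 7.3
  two <- atoms_df(rbind(c(-d / 2, 0, 0), c(d / 2, 0, 0)))
  expect_equal(radius_of_gyration(rbd_species("two", two)), d / 2)
  cube <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  expect_equal(radius_of_gyration(rbd_species("cube", atoms_df(cube))), sqrt(3))
  # invariance under rotation + translation
  set.seed(4)
  pts <- matrix(rnorm(30), ncol = 3) * 5
  q <- random_unit_quat()
  moved <- sweep(pts %*% t(quat_matrix(q)), 2, c(10, -3, 7), `+`)
  expect_equal(radius_of_gyration(pts), radius_of_gyration(moved),
               tolerance = 1e-9)
})

test_that("SASA reproduces the isolated-sphere closed form and burial bounds", {
  one <- rbd_species("one", atoms_df(c(0, 0, 0), radius = 3))
  expect_equal(compute_sasa(one, 1.4), 4 * pi * (3 + 1.4)^2, tolerance = 1e-6)
  # gap > 2 * probe: spheres still isolated
  far <- rbd_species("far", atoms_df(rbind(c(0, 0, 0), c(10, 0, 0)), radius = 2))
  expect_equal(compute_sasa(far, 1.4), rep(4 * pi * 3.4^2, 2), tolerance = 1e-6)
  # overlapping atoms are buried, and the additivity bound holds
  near <- rbd_species("near", atoms_df(rbind(c(0, 0, 0), c(1, 0, 0)), radius = 2))
  s <- compute_sasa(near, 1.4)
  expect_true(all(s <= 4 * pi * 3.4^2 + 1e-9))
  expect_lt(sum(s), 2 * 4 * pi * 3.4^2)
})

test_that("HOPG slab has graphite geometry", {
  surf <- build_hopg_layer(50, 50, 3)
  zs <- sort(unique(round(surf$lattice[, 3], 6)), decreasing = TRUE)
  expect_equal(zs, c(0, -3.35, -6.70))
  expect_equal(surf$z_top, 0)
  # nearest-neighbour distance within the top layer is the C-C bond
  top <- surf$lattice[surf$lattice[, 3] == 0, 1:2]
  mid <- top[top[, 1] > 10 & top[, 1] < 40 & top[, 2] > 10 & top[, 2] < 40, ]
  i <- which.min(rowSums(sweep(mid, 2, c(25, 25))^2))
  d <- sqrt(rowSums(sweep(top, 2, as.numeric(mid[i, ]))^2))
  expect_equal(min(d[d > 1e-6]), 1.42, tolerance = 1e-3)
  # areal density: one atom per 2.62 A^2 per layer, within 5%
  expected <- surf$extent_x * surf$extent_y * 3 / 2.62
  expect_lt(abs(nrow(surf$lattice) - expected) / expected, 0.05)
  expect_error(build_hopg_layer(50, 50, 0), "n_layers")
})

test_that("surface PDB and species summary exports are well-formed", {
  surf <- build_hopg_layer(10, 10, 1)
  path <- tempfile(fileext = ".pdb")
  write_surface_pdb(surf, path)
  lines <- readLines(path)
  expect_equal(sum(grepl("^ATOM", lines)), nrow(surf$lattice))
  sp <- make_toy_protein("sumtest")
  js <- tempfile(fileext = ".json")
  species_summary(sp, js)
  got <- jsonlite::read_json(js)
  expect_equal(got$label, "sumtest")
  expect_equal(got$n_atoms, 64)
  expect_equal(got$net_charge, 0)
})
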