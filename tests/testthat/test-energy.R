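# pair and surface energies, forces and torques

test_that("pair energy vanishes beyond the grid range and binds at contact", {
  A <- toy_with_grids()
  qflip <- quat_axis_angle(c(1, 0, 0), pi)
  expect_equal(pair_energy(A, c(0, 0, 0), c(1, 0, 0, 0), A, c(0, 0, 120), qflip), 0)
  # face-to-face contact of the amphipathic bodies is attractive
  e <- pair_energy(A, c(0, 0, 0), c(1, 0, 0, 0), A, c(0, 0, 25), qflip)
  expect_lt(e, -3)
  # hydrophilic back-to-back at a comparable surface separation is not
  e_bb <- pair_energy(A, c(0, 0, 0), qflip, A, c(0, 0, 36.5), c(1, 0, 0, 0))
  expect_gt(e_bb, e + 1)
})

test_that("the two half-sums of the pair energy agree within discretization", {
  # for two identical bodies related by a two-fold axis the half-sums are
  # equal in the continuum; small perturbations keep them within the
  # discretization tolerance
  A <- toy_with_grids()
  set.seed(21)
  for (rep in 1:5) {
    phi <- runif(1, 0, 2 * pi)
    q2 <- quat_axis_angle(c(cos(phi), sin(phi), 0), pi)   # C2 arrangement
    tv0 <- pair_energy(A, c(0, 0, 0), c(1, 0, 0, 0), A,
                       c(0, 0, runif(1, 24, 27)), q2, terms = TRUE)
    expect_equal(sum(tv0[1:4]), sum(tv0[5:8]), tolerance = 1e-9)
    # perturbed near-symmetric arrangement in the bound basin
    q2p <- quat_compose(q2, runif(3, -0.03, 0.03))
    c2p <- c(runif(2, -0.3, 0.3), runif(1, 24, 27))
    tv <- pair_energy(A, c(0, 0, 0), c(1, 0, 0, 0), A, c2p, q2p, terms = TRUE)
    h1 <- sum(tv[1:4]); h2 <- sum(tv[5:8])
    expect_lt(abs(h1 - h2), 0.05 * max(abs(h1), abs(h2), 0.5))
  }
})

test_that("two neutral hydrophobic beads in weak contact attract (beta < 0)", {
  N <- prepare_toy_species(make_toy_protein("neutA", charge_pattern = "neutral"))
  qflip <- quat_axis_angle(c(1, 0, 0), pi)
  e <- pair_energy(N, c(0, 0, 0), c(1, 0, 0, 0), N, c(0, 0, 26), qflip)
  expect_lt(e, 0)
})

test_that("minimum image is applied to pair energies", {
  A <- toy_with_grids()
  box <- c(100, 100, 100)
  qf <- quat_axis_angle(c(1, 0, 0), pi)
  e_direct <- pair_energy(A, c(0, 0, 0), c(1, 0, 0, 0), A, c(0, 0, 25), qf)
  e_wrapped <- pair_energy(A, c(0, 0, 90), c(1, 0, 0, 0), A, c(0, 0, 15), qf,
                           box = box)
  expect_equal(e_wrapped, e_direct, tolerance = 1e-12)
})

test_that("forces obey Newton's third law and match a 1-D energy scan", {
  A <- toy_with_grids()
  box <- c(300, 300, 300)
  # probe on the repulsive wall where the gradient is well-conditioned
  ctr <- rbind(c(150, 150, 150), c(150, 150, 172.4))
  qs <- rbind(c(1, 0, 0, 0), quat_axis_angle(c(1, 0, 0), pi))
  ft <- force_torque(list(A), c(1, 1), ctr, qs, box)
  expect_lt(max(abs(ft$force[1, ] + ft$force[2, ])),
            0.05 * max(sqrt(sum(ft$force[1, ]^2)), sqrt(sum(ft$force[2, ]^2))))
  # dense 1-D scan around the separation: dE/dz vs force z-component
  # (small matching step sizes so both estimates converge to the derivative)
  ft2 <- force_torque(list(A), c(1, 1), ctr, qs, box, h_t = 0.2, h_r = 0.01)
  zs <- seq(22.15, 22.65, by = 0.025)
  es <- sapply(zs, function(z)
    pair_energy(A, ctr[1, ], qs[1, ], A, ctr[1, ] + c(0, 0, z), qs[2, ], box = box))
  slope <- stats::coef(stats::lm(es ~ zs))[2]
  expect_lt(abs(-slope - ft2$force[2, 3]) / abs(slope), 0.05)
  # isolated body: no forces
  ft1 <- force_torque(list(A), 1, rbind(c(150, 150, 150)),
                      rbind(c(1, 0, 0, 0)), box)
  expect_equal(unname(ft1$force), matrix(0, 1, 3))
  expect_equal(unname(ft1$torque), matrix(0, 1, 3))
})

test_that("two like point charges repel along the separation vector", {
  spq <- rbd_species("pq", atoms_df(c(0, 0, 0), radius = 1.5, charge = 1))
  spq <- build_species_grids(spq, energy_model("solution"), size_el = 40,
                             size_np = 20, size_sc = 20, spacing = 0.5,
                             spacing_el = 0.5)
  ctr <- rbind(c(100, 100, 100), c(100, 100, 110))
  qs <- rbind(c(1, 0, 0, 0), c(1, 0, 0, 0))
  ft <- force_torque(list(spq), c(1, 1), ctr, qs, c(200, 200, 200))
  expect_lt(ft$force[1, 3], 0)        # pushed apart (down)
  expect_gt(ft$force[2, 3], 0)
  expect_lt(max(abs(ft$force[, 1:2])), 1e-6 + 0.02 * abs(ft$force[1, 3]))
})

test_that("gradient forces equal infinitesimal finite differences of the energy", {
  A <- toy_with_grids()
  set.seed(31)
  box <- c(300, 300, 300)
  ctr <- rbind(c(150, 150, 150), c(151, 149, 176))
  qs <- rbind(random_unit_quat(), random_unit_quat())
  gr <- force_torque(list(A), c(1, 1), ctr, qs, box, method = "grad")
  h <- 1e-6
  for (ax in 1:3) {
    dc <- c(0, 0, 0); dc[ax] <- h
    ep <- pair_energy(A, ctr[1, ] + dc, qs[1, ], A, ctr[2, ], qs[2, ], box = box)
    em <- pair_energy(A, ctr[1, ] - dc, qs[1, ], A, ctr[2, ], qs[2, ], box = box)
    expect_equal(-(ep - em) / (2 * h), gr$force[1, ax], tolerance = 1e-4)
    dth <- c(0, 0, 0); dth[ax] <- h
    eq1 <- pair_energy(A, ctr[1, ], quat_compose(qs[1, ], dth), A, ctr[2, ],
                       qs[2, ], box = box)
    eq2 <- pair_energy(A, ctr[1, ], quat_compose(qs[1, ], -dth), A, ctr[2, ],
                       qs[2, ], box = box)
    expect_equal(-(eq1 - eq2) / (2 * h), gr$torque[1, ax], tolerance = 1e-4)
  }
})

surface_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      model <- toy_energy_model("surface")
      surf <- build_hopg_layer(30, 30, 3)
      cache <<- surface_grid_set(surf, model, z_max = 60, spacing = 0.5)
    }
    cache
  }
})

test_that("surface energy is zero far away and orientation-selective", {
  surf <- surface_fixture()
  tf <- prepare_toy_species(make_two_faced_bead(), toy_energy_model("surface"))
  # far above the grid top
  expect_equal(surface_energy(surf, tf, c(10, 10, 120)), 0)
  # hydrophobic face (which points -z) towards the surface beats face-up,
  # comparing each orientation at its own best height
  zs <- seq(6, 30, by = 0.5)
  e_down <- min(sapply(zs, function(z) surface_energy(surf, tf, c(10, 10, z))))
  e_up <- min(sapply(zs, function(z)
    surface_energy(surf, tf, c(10, 10, z), quat_axis_angle(c(1, 0, 0), pi))))
  expect_lt(e_down, -1)
  expect_lt(e_down, e_up - 0.5)
  # axial symmetry: rotation about z leaves the energy almost unchanged
  zb <- zs[which.min(sapply(zs, function(z) surface_energy(surf, tf, c(10, 10, z))))]
  e0 <- surface_energy(surf, tf, c(10, 10, zb))
  e_rot <- surface_energy(surf, tf, c(10, 10, zb), quat_axis_angle(c(0, 0, 1), 1.1))
  expect_equal(e_rot, e0, tolerance = 0.05)
})

test_that("surface energy is invariant under lattice-period translations", {
  surf <- surface_fixture()
  tf <- prepare_toy_species(make_two_faced_bead(), toy_energy_model("surface"))
  zs <- seq(6, 25, by = 0.5)
  zb <- zs[which.min(sapply(zs, function(z) surface_energy(surf, tf, c(10, 10, z))))]
  e0 <- surface_energy(surf, tf, c(10, 10, zb))
  e1 <- surface_energy(surf, tf, c(10 + surf$cell[1], 10, zb))
  e2 <- surface_energy(surf, tf, c(10, 10 + surf$cell[2], zb))
  expect_equal(e1, e0, tolerance = 1e-9)
  expect_equal(e2, e0, tolerance = 1e-9)
  # arbitrary in-plane positions vary by less than 0.1 kcal/mol
  set.seed(5)
  es <- replicate(10, surface_energy(surf, tf, c(runif(1, 0, 30),
                                                 runif(1, 0, 30), zb)))
  expect_lt(max(es) - min(es), 0.1)
})
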