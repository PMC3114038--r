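# Ermak-McCammon propagation, boundaries, initialization, bookkeeping

test_that("box side follows from concentration", {
  b <- box_from_concentration(7.5, 1, 20)
  expect_equal(b[1], 85.4, tolerance = 0.005)
  expect_equal(prod(box_from_concentration(7.5, 2, 20)) /
                 prod(box_from_concentration(7.5, 1, 20)), 2, tolerance = 1e-9)
  expect_equal(box_from_concentration(7.5, 512, 2)[1] /
                 box_from_concentration(7.5, 512, 20)[1], 10^(1 / 3),
               tolerance = 1e-9)
  expect_error(box_from_concentration(7.5, 0, 20), "positive")
})

test_that("a zero-force, zero-noise step leaves the state unchanged", {
  sp <- make_toy_protein("still")
  st <- list(centers = rbind(c(10, 10, 10)), quats = rbind(c(1, 0, 0, 0)),
             time = 0)
  z3 <- matrix(0, 1, 3)
  st2 <- bd_step(st, list(sp), 1, z3, z3, noise = matrix(0, 1, 6))
  expect_equal(st2$centers, st$centers)
  expect_equal(st2$quats, st$quats)
  expect_equal(st2$time, 5e-4)
  expect_error(bd_step(st, list(sp), 1, matrix(NaN, 1, 3), z3), "body 1")
})

test_that("boundary conditions wrap and reflect as specified", {
  st <- list(centers = rbind(c(103, -2, 55), c(50, 50, -3), c(50, 50, 104)),
             box = c(100, 100, 100))
  w <- apply_boundaries(st)
  expect_equal(w$centers[1, ], c(3, 98, 55))
  expect_equal(w$centers[2, 3], 97)          # periodic z
  r <- apply_boundaries(st, surface = TRUE)
  expect_equal(r$centers[2, 3], 3)           # reflected at the bottom
  expect_equal(r$centers[3, 3], 2 * 100 - 104)
  expect_equal(minimum_image(c(98, 0, 0) - c(1, 0, 0), c(100, 100, 100)),
               c(-3, 0, 0))
})

test_that("random initialization avoids overlaps and is seed-deterministic", {
  sp <- make_toy_protein("init")
  p <- sim_params(t_total = 1, box = rep(300, 3),
                  species_counts = c(init = 16), t_equil = 0, seed = 3)
  set.seed(3); s1 <- initialize_random(list(sp), p)
  set.seed(3); s2 <- initialize_random(list(sp), p)
  expect_identical(s1, s2)
  dmin <- Inf
  for (i in 1:15) for (j in (i + 1):16) {
    d <- s1$centers[j, ] - s1$centers[i, ]
    d <- d - p$box * round(d / p$box)
    dmin <- min(dmin, sqrt(sum(d^2)))
  }
  expect_gt(dmin, 2 * 15)  # shells of radius 15 cannot interpenetrate
  # over-dense packing fails with a clear message
  pd <- sim_params(t_total = 1, box = rep(80, 3),
                   species_counts = c(init = 60), t_equil = 0, seed = 3)
  expect_error(initialize_random(list(sp), pd, max_attempts = 20), "overlap|box")
})

test_that("parameter validation rejects inconsistent settings", {
  expect_error(sim_params(t_total = 10, box = rep(100, 3),
                          species_counts = c(a = 1), t_equil = 10), "t_equil")
  expect_error(sim_params(t_total = 10, box = rep(100, 3),
                          species_counts = c(a = 1), timestep = 0), "timestep")
})

test_that("runs are reproducible and snapshots have exact cadence", {
  sp <- make_toy_protein("rep")
  p <- sim_params(t_total = 2, box = rep(400, 3), species_counts = c(rep = 4),
                  t_equil = 0.5, snapshot_interval = 0.1, seed = 17)
  t1 <- run_simulation(list(sp), p, forces_on = FALSE, record_energy = FALSE)
  t2 <- run_simulation(list(sp), p, forces_on = FALSE, record_energy = FALSE)
  expect_identical(t1$centers, t2$centers)
  expect_identical(t1$quats, t2$quats)
  expect_equal(t1$times, seq(0, 2, by = 0.1))
  expect_true(all(abs(diff(t1$times) - 0.1) < 1e-12))
  # quaternions stay normalized
  n2 <- apply(t1$quats, c(1, 2), function(q) sum(q^2))
  expect_lt(max(abs(n2 - 1)), 1e-9)
})

test_that("free diffusion: MSD linear in t and no net drift", {
  sp <- make_toy_protein("free", n_beads = 8)
  p <- sim_params(t_total = 50, box = rep(1000, 3), species_counts = c(free = 8),
                  t_equil = 0, snapshot_interval = 0.01, seed = 9)
  traj <- run_simulation(list(sp), p, forces_on = FALSE, wrap = FALSE,
                         record_energy = FALSE)
  msd <- trajectory_msd(traj, max_lag = 100)
  fit <- summary(stats::lm(msd ~ lag_ns, data = msd))
  expect_gt(fit$r.squared, 0.99)
  # center-of-mass displacement within 3 sigma of zero
  disp <- traj$centers[length(traj$times), , ] - traj$centers[1, , ]
  com <- colMeans(disp)
  sigma <- sqrt(2 * sp$d_trans * 50 / 8)
  expect_true(all(abs(com) < 3 * sigma))
})

test_that("one step of the compiled engine matches the reference step", {
  sp <- toy_with_grids()
  p <- sim_params(t_total = 0.0005, box = rep(300, 3),
                  species_counts = c(toyA = 2), t_equil = 0,
                  snapshot_interval = 0.0005, seed = 23)
  init <- list(centers = rbind(c(150, 150, 140), c(150, 150, 165)),
               quats = rbind(c(1, 0, 0, 0), quat_axis_angle(c(1, 0, 0), pi)),
               body_species = c(1, 1), labels = c("toyA", "toyA"),
               box = p$box, time = 0)
  traj <- run_simulation(list(sp), p, init = init, record_energy = FALSE)
  # reference: same forces, same noise stream
  ft <- force_torque(list(sp), c(1, 1), init$centers, init$quats, p$box,
                     method = "grad")
  set.seed(p$seed)
  noise <- matrix(rnorm(12), 2, 6, byrow = TRUE)
  st <- bd_step(list(centers = init$centers, quats = init$quats, time = 0),
                list(sp), c(1, 1), ft$force, ft$torque, noise = noise)
  expect_equal(traj$centers[2, , ], unname(st$centers), tolerance = 1e-12)
  expect_equal(traj$quats[2, , ], unname(st$quats), tolerance = 1e-12)
})

test_that("recorded energies equal the offline pair + surface recomputation", {
  sp <- toy_with_grids()
  p <- sim_params(t_total = 5, box = rep(150, 3), species_counts = c(toyA = 4),
                  t_equil = 0, snapshot_interval = 1, seed = 31)
  traj <- run_simulation(list(sp), p)
  for (k in seq_along(traj$times)) {
    st <- trajectory_state(traj, k)
    e <- system_energy(list(sp), traj$body_species, st$centers, st$quats,
                       traj$box)
    expect_equal(traj$energies[k], e, tolerance = 1e-6)
  }
})

test_that("two purely repulsive bodies keep a non-negative mean energy", {
  hard <- make_toy_protein("hard", charge_pattern = "neutral")
  hard$atoms$sasa <- 0                      # excluded volume only
  hard <- prepare_toy_species(hard)
  p <- sim_params(t_total = 20, box = rep(90, 3), species_counts = c(hard = 2),
                  t_equil = 2, snapshot_interval = 0.5, seed = 41)
  traj <- run_simulation(list(hard), p)
  expect_gte(mean(traj$energies[production_frames(traj)]), 0)
})
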