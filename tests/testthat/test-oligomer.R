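# encounter criterion, oligomer partitioning, fractions, tetramer typing,
# contact probabilities

test_that("independent contact counting follows the criterion", {
  crit <- contact_criterion(2, 4.5, 6.0)
  # two 1-atom bodies 4.0 A apart: one contact, not an encounter at n_ind = 2
  A <- rbind(c(0, 0, 0)); B <- rbind(c(4, 0, 0))
  expect_equal(count_independent_contacts(A, B, crit), 1)
  expect_false(rigidbd:::cpp_has_encounter(A, B, crit$d_c, crit$d_min,
                                           crit$n_ind))
  # 2-atom bodies, intra spacing 7 (> d_min): both cross pairs independent
  A2 <- rbind(c(0, 0, 0), c(7, 0, 0)); B2 <- rbind(c(0, 4, 0), c(7, 4, 0))
  expect_equal(count_independent_contacts(A2, B2, crit), 2)
  # intra spacing 5 (< d_min): the two contacts are not independent
  A3 <- rbind(c(0, 0, 0), c(5, 0, 0)); B3 <- rbind(c(0, 4, 0), c(5, 4, 0))
  expect_equal(count_independent_contacts(A3, B3, crit), 1)
})

test_that("contact count equals the exhaustive enumeration oracle", {
  crit <- contact_criterion(2, 4.5, 6.0)
  set.seed(77)
  checked <- 0
  while (checked < 60) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    A <- matrix(runif(3 * na, 0, 9), ncol = 3)
    B <- sweep(matrix(runif(3 * nb, 0, 9), ncol = 3), 2, c(6, 0, 0), `+`)
    got <- count_independent_contacts(A, B, crit)
    oracle <- tryCatch(max_indep_contacts_oracle(A, B, crit$d_c, crit$d_min),
                       error = function(e) NA)
    if (is.na(oracle)) next
    expect_equal(got, oracle)
    checked <- checked + 1
  }
})

test_that("oligomers are the connected components of the encounter graph", {
  pc <- make_planted_configuration("linear-trimer")
  part <- partition_oligomers(pc$state, pc$species, pc$body_species,
                              pc$criterion)
  expect_equal(lengths(part$groups), 3)
  # partition property: disjoint and exhaustive
  all_idx <- sort(unlist(part$groups))
  expect_equal(all_idx, seq_len(3))
  # no contacts -> all singletons
  pm <- make_planted_configuration("monomers")
  pp <- partition_oligomers(pm$state, pm$species, pm$body_species, pm$criterion)
  expect_equal(sort(lengths(pp$groups)), rep(1L, 5))
})

test_that("random frames partition identically to a union-find oracle", {
  sp <- .plant_species_for_tests()
  set.seed(13)
  for (rep in 1:5) {
    n <- 6
    st <- list(centers = matrix(runif(3 * n, 0, 28), ncol = 3),
               quats = t(replicate(n, random_unit_quat())),
               box = rep(200, 3), time = 0)
    crit <- contact_criterion(2, 4.5, 6.0)
    part <- partition_oligomers(st, list(sp), rep(1, n), crit)
    got <- lapply(part$groups, sort)
    want <- lapply(partition_oracle(st, list(sp), rep(1, n), crit), sort)
    got <- got[order(vapply(got, min, 0))]
    want <- want[order(vapply(want, min, 0))]
    expect_equal(got, want)
  }
})

test_that("oligomer fractions average correctly and sum to one", {
  # synthetic trajectory: 4 bodies; half the frames a dimer + 2 monomers,
  # half all monomers
  sp <- .plant_species_for_tests()
  nf <- 10
  centers <- array(0, c(nf, 4, 3))
  quats <- array(0, c(nf, 4, 4)); quats[, , 1] <- 1
  for (k in seq_len(nf)) {
    centers[k, , ] <- cbind(c(0, 40, 80, 120), 0, 0)
    if (k > nf / 2) centers[k, 2, ] <- c(0, 0, 3.8)   # stack on body 1
  }
  traj <- structure(list(
    times = seq(0, by = 0.5, length.out = nf), centers = centers,
    quats = quats, energies = numeric(nf), box = rep(500, 3),
    body_species = rep(1, 4), labels = rep("plant", 4),
    params = sim_params(t_total = 5, box = rep(500, 3),
                        species_counts = c(plant = 4), t_equil = 0),
    has_surface = FALSE, species_labels = "plant"), class = "rbd_trajectory")
  of <- oligomer_fractions(traj, list(sp), contact_criterion(),
                           frames = seq_len(nf))
  expect_equal(sum(of$chi), 1, tolerance = 1e-9)
  expect_equal(of$chi[of$n == 2], 0.25)
  expect_equal(of$chi[of$n == 1], 0.75)
})

test_that("tetramer composition classes ignore permutation", {
  expect_equal(classify_tetramer(rep("chainA", 4)), "AAAA")
  expect_equal(classify_tetramer(rep("chainB", 4)), "BBBB")
  expect_equal(classify_tetramer(c("chainB", "chainA", "chainB", "chainA")),
               "ABAB")
  expect_equal(classify_tetramer(c("chainA", "chainA", "chainA", "chainB")),
               "other")
})

test_that("planted configurations reproduce their declared ground truth", {
  for (kind in c("monomers", "dimer", "linear-trimer", "tetramer-2x2")) {
    pc <- make_planted_configuration(kind)
    part <- partition_oligomers(pc$state, pc$species, pc$body_species,
                                pc$criterion)
    got <- lapply(part$groups, sort)
    want <- lapply(pc$truth, sort)
    expect_equal(got[order(vapply(got, min, 0))],
                 want[order(vapply(want, min, 0))], ignore_attr = TRUE)
  }
  pc4 <- make_planted_configuration("tetramer-2x2")
  expect_equal(classify_tetramer(pc4$labels, "plantA", "plantB"), "ABAB")
})

test_that("contact probabilities normalize and flag patch residues", {
  # planted two-body trajectory: a 48-residue species whose first 11
  # residues (the patch, < a quarter of the chain) are repeatedly contacted
  # by a partner plate; the third-quartile threshold must flag exactly them
  probe <- rbd_species("probe", atoms_df(
    cbind(seq(0, by = 7, length.out = 48), 0, 0), radius = 1.5,
    residue_number = 1:48))
  plate <- rbd_species("plate", atoms_df(
    cbind(seq(0, by = 7, length.out = 11), 0, 0), radius = 1.5,
    residue_number = 1:11))
  nf <- 4
  centers <- array(0, c(nf, 2, 3))
  quats <- array(0, c(nf, 2, 4)); quats[, , 1] <- 1
  for (k in seq_len(nf)) {
    centers[k, 1, ] <- c(164.5, 0, 0)     # probe atoms back at x = 0..329
    centers[k, 2, ] <- c(35, 4, 0)        # plate under residues 1..11
  }
  traj <- structure(list(
    times = seq(0, by = 0.5, length.out = nf), centers = centers,
    quats = quats, energies = numeric(nf), box = rep(1000, 3),
    body_species = c(1, 2), labels = c("probe", "plate"),
    params = sim_params(t_total = 2, box = rep(1000, 3),
                        species_counts = c(probe = 1, plate = 1), t_equil = 0),
    has_surface = FALSE, species_labels = c("probe", "plate")),
    class = "rbd_trajectory")
  cp <- contact_probability(traj, list(probe, plate), contact_criterion(),
                            species_label = "probe", frames = seq_len(nf))
  expect_equal(max(cp$p), 1)
  expect_true(all(cp$p >= 0 & cp$p <= 1))
  expect_equal(sort(unique(cp$residue_number[cp$relevant])), 1:11)
  expect_false(any(cp$relevant[cp$residue_number > 11]))
  # an atom never in contact has p = 0
  expect_true(all(cp$p[cp$residue_number > 11] == 0))
})
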