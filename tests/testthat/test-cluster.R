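# least-squares superposition and GROMOS-style clustering

test_that("superposition recovers rigid transforms exactly", {
  set.seed(19)
  X <- matrix(rnorm(30), ncol = 3) * 4
  q <- random_unit_quat()
  moved <- sweep(X %*% t(quat_matrix(q)), 2, c(5, -2, 9), `+`)
  fit <- superpose(moved, X)
  expect_lt(fit$rmsd, 1e-9)
  # rmsd is invariant to the initial orientation of the mobile structure
  q2 <- random_unit_quat()
  moved2 <- moved %*% t(quat_matrix(q2))
  expect_equal(superpose(moved2, X)$rmsd, fit$rmsd, tolerance = 1e-9)
  expect_error(superpose(X[1:5, ], X), "mismatch")
})

test_that("superposition matches a brute-force rotation search on 3 points", {
  # non-degenerate triangle pair; grid-search over rotations is the oracle
  X <- rbind(c(0, 0, 0), c(4, 0, 0), c(1, 3, 0))
  Y <- rbind(c(0.3, -0.2, 0.1), c(4.1, 0.4, -0.3), c(0.8, 3.2, 0.4))
  fit <- superpose(X, Y)
  # brute force: scan Euler-like axis-angle rotations
  best <- Inf
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  for (a in seq(0, pi, length.out = 25)) {
    for (ux in seq(-1, 1, length.out = 13)) for (uy in seq(-1, 1, length.out = 13)) {
      uz2 <- 1 - ux^2 - uy^2
      if (uz2 < 0) next
      for (s in c(-1, 1)) {
        R <- quat_matrix(quat_axis_angle(c(ux, uy, s * sqrt(uz2)), a))
        r <- sqrt(mean(rowSums((Xc %*% t(R) - Yc)^2)))
        if (r < best) best <- r
      }
    }
  }
  expect_lt(fit$rmsd, best + 1e-3)   # optimal fit is at least as good
  expect_lt(abs(fit$rmsd - best), 0.05)
})

test_that("gromos clustering reproduces hand-derived clusters", {
  # two tight bundles (5 and 3 members) separated far beyond the cutoff
  d_in <- 2; d_out <- 100
  n <- 8
  M <- matrix(d_out, n, n)
  M[1:5, 1:5] <- d_in
  M[6:8, 6:8] <- d_in
  diag(M) <- 0
  cl <- cluster_gromos(M, cutoff = 15)
  expect_equal(length(cl$centroids), 2)
  expect_equal(cl$sizes, c(5L, 3L))            # larger cluster first
  expect_equal(cl$centroids[1], 1)             # tie broken by lowest index
  expect_equal(cl$labels, c(rep(1L, 5), rep(2L, 3)))
  # all mutually close -> a single cluster
  cl1 <- cluster_gromos(matrix(1, 4, 4) - diag(4), cutoff = 15)
  expect_equal(length(cl1$centroids), 1)
  expect_equal(cl1$sizes, 4L)
  # a singleton beyond the cutoff from everything forms its own cluster
  M2 <- matrix(1, 4, 4) - diag(4)
  M2 <- rbind(cbind(M2, 99), 99); diag(M2) <- 0
  cl2 <- cluster_gromos(M2, cutoff = 15)
  expect_equal(cl2$sizes, c(4L, 1L))
  expect_error(cluster_gromos(matrix(0, 0, 0)), "empty")
})

test_that("hand-built asymmetric distance structure clusters correctly", {
  # chain: 1-2 close, 2-3 close, 1-3 far; structure 2 has most neighbours
  M <- rbind(c(0, 10, 25), c(10, 0, 10), c(25, 10, 0))
  cl <- cluster_gromos(M, cutoff = 15)
  expect_equal(cl$centroids[1], 2)
  expect_equal(cl$labels, c(1L, 1L, 1L))
})

test_that("tetramer harvesting and clustering runs end to end", {
  pc <- make_planted_configuration("tetramer-2x2")
  nf <- 3
  centers <- array(0, c(nf, 4, 3))
  quats <- array(0, c(nf, 4, 4)); quats[, , 1] <- 1
  for (k in seq_len(nf)) centers[k, , ] <- pc$state$centers
  traj <- structure(list(
    times = seq(0, by = 1, length.out = nf), centers = centers, quats = quats,
    energies = numeric(nf), box = pc$state$box,
    body_species = pc$body_species, labels = pc$labels,
    params = sim_params(t_total = 3, box = pc$state$box,
                        species_counts = c(plantA = 2, plantB = 2),
                        t_equil = 0, snapshot_interval = 1),
    has_surface = FALSE, species_labels = c("plantA", "plantB")),
    class = "rbd_trajectory")
  res <- cluster_tetramers(traj, pc$species, pc$criterion,
                           ref_label = "plantA")
  expect_equal(length(res$oligomers), 3)
  # identical frames: one cluster holding every harvested tetramer
  expect_equal(length(res$clusters$centroids), 1)
  expect_equal(res$clusters$sizes, 3L)
  expect_lt(max(res$rmsd), 1e-6)
})
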