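# shared fixtures: built in code, deterministic

# minimal atom table
atoms_df <- function(xyz, radius = 1.5, charge = 0, sasa = 0,
                     residue_number = NULL) {
  xyz <- rbind(xyz)
  n <- nrow(xyz)
  data.frame(id = seq_len(n), residue_name = "UNK",
             residue_number = residue_number %||% seq_len(n),
             atom_name = "X",
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             radius = radius, charge = charge, sasa = sasa)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# write a small PQR file; returns the path
write_tmp_pqr <- function(lines) {
  path <- tempfile(fileext = ".pqr")
  writeLines(lines, path)
  path
}

pqr_line <- function(id, name, res, resno, x, y, z, q, r) {
  sprintf("ATOM %d %s %s %d %.3f %.3f %.3f %.4f %.4f",
          id, name, res, resno, x, y, z, q, r)
}

# toy species with grids, cached across tests in one session
toy_with_grids <- local({
  cache <- new.env()
  function(pattern = "dipolar", label = NULL) {
    label <- label %||% if (pattern == "dipolar") "toyA" else "toyB"
    key <- paste0(label, "_", pattern)
    if (is.null(cache[[key]]))
      cache[[key]] <- prepare_toy_species(
        make_toy_protein(label, charge_pattern = pattern))
    cache[[key]]
  }
})

# 4-atom square plate (side 7 A, bead radius 1.5 A): atoms mutually
# independent under the atomic criterion, convenient for planted contacts
.plant_species_for_tests <- function(label = "plant") {
  rbd_species(label, atoms_df(rbind(c(-3.5, -3.5, 0), c(3.5, -3.5, 0),
                                    c(3.5, 3.5, 0), c(-3.5, 3.5, 0)),
                              radius = 1.5, sasa = 25),
              d_trans = 20, d_rot = 0.05)
}

random_unit_quat <- function() {
  q <- stats::rnorm(4)
  q / sqrt(sum(q^2))
}

# independent exhaustive oracle for the maximum number of mutually
# independent contacts: enumerate all subsets of candidate cross pairs
max_indep_contacts_oracle <- function(A, B, d_c, d_min) {
  A <- rbind(A); B <- rbind(B)
  cand <- which(outer(seq_len(nrow(A)), seq_len(nrow(B)), Vectorize(function(i, j)
    sqrt(sum((A[i, ] - B[j, ])^2)) < d_c)), arr.ind = TRUE)
  k <- nrow(cand)
  if (k == 0) return(0L)
  if (k > 18) stop("oracle instance too large (", k, " candidate pairs)")
  compat <- matrix(TRUE, k, k)
  for (p in seq_len(k)) for (q in seq_len(k)) {
    if (p == q) next
    da <- sqrt(sum((A[cand[p, 1], ] - A[cand[q, 1], ])^2))
    db <- sqrt(sum((B[cand[p, 2], ] - B[cand[q, 2], ])^2))
    compat[p, q] <- da > d_min && db > d_min
  }
  best <- 1L
  for (mask in seq_len(2^k - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
    if (length(sel) <= best) next
    ok <- TRUE
    for (p in seq_along(sel)) {
      for (q in seq_len(p - 1)) {
        if (!compat[sel[p], sel[q]]) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) best <- length(sel)
  }
  best
}

# brute-force union-find partition oracle over encounter pairs
partition_oracle <- function(state, species, body_species, criterion) {
  n <- nrow(rbind(state$centers))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  apos <- lapply(species, function(s) as.matrix(s$atoms[, c("x", "y", "z")]))
  centers <- rbind(state$centers); quats <- rbind(state$quats)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- centers[j, ] - centers[i, ]
    d <- d - state$box * round(d / state$box)
    Ai <- apos[[body_species[i]]] %*% t(quat_matrix(quats[i, ]))
    Bj <- sweep(apos[[body_species[j]]] %*% t(quat_matrix(quats[j, ])), 2, d, `+`)
    cnt <- count_independent_contacts(Ai, Bj, criterion)
    if (cnt >= criterion$n_ind) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  unname(split(seq_len(n), vapply(seq_len(n), find, 1L)))
}
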