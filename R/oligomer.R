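#' Atomic-contact encounter criterion
#'
#' An encounter complex between two proteins is declared when at least
#' `n_ind` independent atomic contacts exist: atom pairs (one atom from each
#' protein) closer than `d_c`, such that within each protein the selected
#' atoms are pairwise farther apart than `d_min`.
#'
#' @param n_ind minimum number of independent contacts (default 2).
#' @param d_c contact distance cutoff, Angstrom (4.5 protein-protein, 4.0
#'   protein-surface).
#' @param d_min independence distance, Angstrom.
#' @return list of class `contact_criterion`.
#' @export
contact_criterion <- function(n_ind = 2, d_c = 4.5, d_min = 6.0) {
  if (!(d_min > d_c && d_c > 0)) stop("need d_min > d_c > 0")
  if (n_ind < 1) stop("n_ind must be >= 1")
  cr <- list(n_ind = as.integer(n_ind), d_c = d_c, d_min = d_min)
  class(cr) <- "contact_criterion"
  cr
}

# lab-frame atom coordinates of body i
.body_atoms_lab <- function(apos_list, body_species, centers, quats, i) {
  R <- quat_matrix(quats[i, ])
  sweep(apos_list[[body_species[i]]] %*% t(R), 2, centers[i, ], `+`)
}

#' Number of independent atomic contacts between two bodies
#'
#' Computes the maximum number of mutually independent cross-protein
#' contacts (atom pairs closer than `d_c` whose same-protein atoms are
#' pairwise farther than `d_min`) by exact branch-and-bound over the
#' candidate pairs; beyond `node_cap` search nodes the greedy
#' ascending-distance selection is returned instead (a lower bound).
#'
#' @param xyz_a,xyz_b atom coordinate matrices (lab frame, minimum image
#'   already applied).
#' @param criterion a [contact_criterion()].
#' @param node_cap branch-and-bound node budget.
#' @return integer contact count.
#' @export
count_independent_contacts <- function(xyz_a, xyz_b, criterion = contact_criterion(),
                                       node_cap = 2e6) {
  cpp_max_indep_contacts(as.matrix(xyz_a), as.matrix(xyz_b),
                         criterion$d_c, criterion$d_min, node_cap)
}

#' Partition a frame into oligomers (connected encounter components)
#'
#' Edges of the contact graph are body pairs satisfying the encounter
#' criterion; oligomers are the connected components (a group of two or more
#' proteins mutually in contact, directly or through intermediates).
#'
#' @param state frame state: list with `centers`, `quats`, `box`.
#' @param species list of [rbd_species()].
#' @param body_species 1-based species index per body.
#' @param criterion a [contact_criterion()].
#' @return list of class `oligomer_partition`: `groups` (list of integer
#'   vectors partitioning all body indices), `frame_time`.
#' @export
partition_oligomers <- function(state, species, body_species,
                                criterion = contact_criterion()) {
  centers <- rbind(state$centers)
  quats <- rbind(state$quats)
  n <- nrow(centers)
  apos <- lapply(species, function(s) as.matrix(s$atoms[, c("x", "y", "z")]))
  brad <- vapply(species, `[[`, 0, "bound_radius")
  edges <- integer(0)
  if (n > 1) {
    lab_atoms <- vector("list", n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d <- centers[j, ] - centers[i, ]
        d <- d - state$box * round(d / state$box)
        if (sqrt(sum(d^2)) >
            brad[body_species[i]] + brad[body_species[j]] + criterion$d_c)
          next
        if (is.null(lab_atoms[[i]]))
          lab_atoms[[i]] <- apos[[body_species[i]]] %*% t(quat_matrix(quats[i, ]))
        if (is.null(lab_atoms[[j]]))
          lab_atoms[[j]] <- apos[[body_species[j]]] %*% t(quat_matrix(quats[j, ]))
        Bj <- sweep(lab_atoms[[j]], 2, d, `+`)
        if (cpp_has_encounter(lab_atoms[[i]], Bj, criterion$d_c,
                              criterion$d_min, criterion$n_ind))
          edges <- c(edges, i, j)
      }
    }
  }
  g <- igraph::make_graph(edges, n = n, directed = FALSE)
  comp <- igraph::components(g)
  groups <- split(seq_len(n), comp$membership)
  names(groups) <- NULL
  out <- list(groups = groups, frame_time = state$time)
  class(out) <- "oligomer_partition"
  out
}

#' Time-averaged oligomer fractions
#'
#' chi_n: average fraction of molecules belonging to n-mers over the
#' production segment of a trajectory.
#'
#' @param traj an `rbd_trajectory`.
#' @param species list of [rbd_species()].
#' @param criterion a [contact_criterion()].
#' @param frames frame indices to analyse (default: production segment).
#' @param max_n largest oligomer size reported individually (all sizes are
#'   still included in the fractions).
#' @return data.frame with columns `n` and `chi` (sums to 1), plus attribute
#'   `"sizes_per_frame"` (list of group-size vectors).
#' @export
oligomer_fractions <- function(traj, species, criterion = contact_criterion(),
                               frames = NULL, max_n = NULL) {
  if (is.null(frames)) frames <- production_frames(traj)
  if (!length(frames)) stop("no frames to analyse (empty production segment)")
  nb <- dim(traj$centers)[2]
  sizes_pf <- vector("list", length(frames))
  acc <- numeric(nb)
  for (k in seq_along(frames)) {
    st <- trajectory_state(traj, frames[k])
    part <- partition_oligomers(st, species, traj$body_species, criterion)
    sizes <- lengths(part$groups)
    sizes_pf[[k]] <- sizes
    for (s in sizes) acc[s] <- acc[s] + s
  }
  chi <- acc / (nb * length(frames))
  keep <- if (is.null(max_n)) which(chi > 0 | seq_len(nb) <= 5) else seq_len(max_n)
  out <- data.frame(n = keep, chi = chi[keep])
  attr(out, "sizes_per_frame") <- sizes_pf
  out
}

#' Classify the composition of a tetramer
#'
#' @param labels character vector of 4 species labels (any order; all
#'   permutations are identical).
#' @param label_a,label_b the two conformer labels.
#' @return `"AAAA"`, `"BBBB"`, `"ABAB"` (two of each) or `"other"`.
#' @export
classify_tetramer <- function(labels, label_a = "chainA", label_b = "chainB") {
  stopifnot(length(labels) == 4)
  na <- sum(labels == label_a)
  nb <- sum(labels == label_b)
  if (na == 4) return("AAAA")
  if (nb == 4) return("BBBB")
  if (na == 2 && nb == 2) return("ABAB")
  "other"
}

#' Average tetramer counts per frame, by composition class
#'
#' @inheritParams oligomer_fractions
#' @param label_a,label_b the two conformer labels for
#'   [classify_tetramer()].
#' @return data.frame with `class` and `mean_count` (tetramers per frame).
#' @export
tetramer_counts <- function(traj, species, criterion = contact_criterion(),
                            frames = NULL, label_a = "chainA",
                            label_b = "chainB") {
  if (is.null(frames)) frames <- production_frames(traj)
  if (!length(frames)) stop("no frames to analyse")
  classes <- c("AAAA", "ABAB", "BBBB", "other")
  acc <- stats::setNames(numeric(4), classes)
  for (k in frames) {
    st <- trajectory_state(traj, k)
    part <- partition_oligomers(st, species, traj$body_species, criterion)
    for (grp in part$groups) {
      if (length(grp) != 4) next
      cl <- classify_tetramer(traj$labels[grp], label_a, label_b)
      acc[cl] <- acc[cl] + 1
    }
  }
  data.frame(class = classes, mean_count = as.numeric(acc) / length(frames))
}

#' Collect oligomers of a given size from a trajectory
#'
#' Harvests groups of `size` bodies (by default at 1 ns intervals) and
#' returns, for each, the lab-frame pose unwrapped around the group's first
#' body so the oligomer is whole under minimum image.
#'
#' @inheritParams oligomer_fractions
#' @param size oligomer size to collect (4 for tetramers).
#' @param interval_ns harvest cadence, ns.
#' @return list of oligomer records: `bodies`, `labels`, `centers`, `quats`,
#'   `frame_time`.
#' @export
collect_oligomers <- function(traj, species, size = 4,
                              criterion = contact_criterion(),
                              interval_ns = 1.0) {
  frames <- production_frames(traj)
  dt <- diff(traj$times[1:2])
  every <- max(1L, as.integer(round(interval_ns / dt)))
  frames <- frames[seq(1, length(frames), by = every)]
  out <- list()
  for (k in frames) {
    st <- trajectory_state(traj, k)
    part <- partition_oligomers(st, species, traj$body_species, criterion)
    for (grp in part$groups) {
      if (length(grp) != size) next
      ctr <- rbind(st$centers)[grp, , drop = FALSE]
      ref <- ctr[1, ]
      for (m in seq_len(nrow(ctr))) {
        d <- ctr[m, ] - ref
        ctr[m, ] <- ref + (d - st$box * round(d / st$box))
      }
      out[[length(out) + 1]] <- list(bodies = grp,
                                     labels = traj$labels[grp],
                                     centers = ctr,
                                     quats = rbind(st$quats)[grp, , drop = FALSE],
                                     frame_time = st$time)
    }
  }
  out
}

#' Atomic contact probabilities and relevant residues
#'
#' Counts, per atom of a species, how often the atom is within `d_c` of an
#' atom of another protein (or of the surface), over the production frames.
#' The relative probability is p_i = n_i / max_j n_j; a residue is flagged
#' relevant when any of its atoms has p above the third quartile of the
#' per-atom probability distribution (zeros included).
#'
#' @param traj an `rbd_trajectory`.
#' @param species list of [rbd_species()].
#' @param criterion a [contact_criterion()] (use `d_c = 4.0` for
#'   protein-surface contacts).
#' @param target `"protein"` or `"surface"`.
#' @param surface the `rbd_surface` (required for `target = "surface"`).
#' @param species_label which species to profile (default: first).
#' @param frames frame indices (default: production segment).
#' @return data.frame per atom: `id`, `residue_name`, `residue_number`,
#'   `atom_name`, `n`, `p`, `relevant`; threshold in attribute
#'   `"threshold"`.
#' @export
contact_probability <- function(traj, species, criterion = contact_criterion(),
                                target = c("protein", "surface"),
                                surface = NULL, species_label = NULL,
                                frames = NULL) {
  target <- match.arg(target)
  if (target == "surface" && is.null(surface))
    stop("surface target needs the surface model")
  if (is.null(frames)) frames <- production_frames(traj)
  labels <- vapply(species, `[[`, "", "label")
  if (is.null(species_label)) species_label <- labels[1]
  si <- match(species_label, labels)
  sp <- species[[si]]
  apos <- lapply(species, function(s) as.matrix(s$atoms[, c("x", "y", "z")]))
  brad <- vapply(species, `[[`, 0, "bound_radius")
  counts <- numeric(nrow(sp$atoms))
  bodies <- which(traj$body_species == si)
  # surface atoms for distance checks: top-cell atoms replicated 3x3
  if (target == "surface") {
    cell <- surface$cell
    lat <- surface$lattice
    base <- lat[lat[, 1] < cell[1] - 1e-6 & lat[, 2] < cell[2] - 1e-6 &
                  lat[, 3] > -criterion$d_c - 1e-6, , drop = FALSE]
    reps <- expand.grid(ix = -1:1, iy = -1:1)
    surf_at <- do.call(rbind, lapply(seq_len(nrow(reps)), function(r)
      cbind(base[, 1] + reps$ix[r] * cell[1],
            base[, 2] + reps$iy[r] * cell[2], base[, 3])))
  }
  for (k in frames) {
    st <- trajectory_state(traj, k)
    centers <- rbind(st$centers); quats <- rbind(st$quats)
    for (i in bodies) {
      Ai <- sweep(apos[[si]] %*% t(quat_matrix(quats[i, ])), 2, centers[i, ], `+`)
      if (target == "protein") {
        hit <- rep(FALSE, nrow(Ai))
        for (j in seq_len(nrow(centers))) {
          if (j == i) next
          d <- centers[j, ] - centers[i, ]
          d <- d - st$box * round(d / st$box)
          if (sqrt(sum(d^2)) >
              brad[si] + brad[traj$body_species[j]] + criterion$d_c) next
          Bj <- sweep(apos[[traj$body_species[j]]] %*%
                        t(quat_matrix(quats[j, ])), 2, centers[i, ] + d, `+`)
          hit <- hit | cpp_atoms_in_contact(Ai, Bj, criterion$d_c)
        }
      } else {
        if (min(Ai[, 3]) > criterion$d_c) next
        Aw <- Ai
        Aw[, 1] <- Aw[, 1] %% cell[1]
        Aw[, 2] <- Aw[, 2] %% cell[2]
        hit <- cpp_atoms_in_contact(Aw, surf_at, criterion$d_c)
      }
      counts <- counts + hit
    }
  }
  p <- if (max(counts) > 0) counts / max(counts) else counts
  thr <- stats::quantile(p, 0.75, names = FALSE)
  a <- sp$atoms
  res_rel <- tapply(p > thr, a$residue_number, any)
  out <- data.frame(id = a$id, residue_name = a$residue_name,
                    residue_number = a$residue_number,
                    atom_name = a$atom_name, n = counts, p = p,
                    relevant = as.logical(res_rel[as.character(a$residue_number)]))
  attr(out, "threshold") <- thr
  out
}
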