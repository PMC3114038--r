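#' Least-squares superposition (Kabsch)
#'
#' Finds the rigid transform (rotation + translation, no reflection)
#' minimizing the RMSD of `structure[fit_selection, ]` onto
#' `reference[fit_selection, ]`, applies it to the whole structure, and
#' reports the RMSD over all atoms.
#'
#' @param structure n x 3 coordinate matrix to move.
#' @param reference n x 3 coordinate matrix (same atom order).
#' @param fit_selection indices of the atoms used for the fit (default: all).
#' @return list with `coords` (transformed structure), `rmsd` (all atoms,
#'   Angstrom) and `rmsd_fit` (fit selection only).
#' @export
superpose <- function(structure, reference, fit_selection = NULL) {
  structure <- as.matrix(structure); reference <- as.matrix(reference)
  if (!all(dim(structure) == dim(reference)))
    stop("atom count mismatch between structure and reference")
  if (is.null(fit_selection)) fit_selection <- seq_len(nrow(structure))
  X <- structure[fit_selection, , drop = FALSE]
  Y <- reference[fit_selection, , drop = FALSE]
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  s <- svd(crossprod(Xc, Yc))            # 3x3
  d <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)              # X %*% R aligns onto Y
  moved <- sweep(sweep(structure, 2, cx) %*% R, 2, cy, `+`)
  rmsd_all <- sqrt(mean(rowSums((moved - reference)^2)))
  rmsd_fit <- sqrt(mean(rowSums((moved[fit_selection, , drop = FALSE] - Y)^2)))
  list(coords = moved, rmsd = rmsd_all, rmsd_fit = rmsd_fit)
}

# full atom coordinates of an oligomer record, reference chain first
.oligomer_coords <- function(olig, species, species_labels, ref_label = NULL) {
  ord <- seq_along(olig$labels)
  if (!is.null(ref_label) && any(olig$labels == ref_label))
    ord <- c(which(olig$labels == ref_label)[1],
             setdiff(ord, which(olig$labels == ref_label)[1]))
  coords <- do.call(rbind, lapply(ord, function(m) {
    si <- match(olig$labels[m], species_labels)
    apos <- as.matrix(species[[si]]$atoms[, c("x", "y", "z")])
    sweep(apos %*% t(quat_matrix(olig$quats[m, ])), 2, olig$centers[m, ], `+`)
  }))
  nref <- {
    si <- match(olig$labels[ord[1]], species_labels)
    nrow(species[[si]]$atoms)
  }
  list(coords = coords, fit = seq_len(nref))
}

#' Pairwise RMSD matrix of oligomer structures
#'
#' Every structure is superposed onto every other by least-squares fitting
#' on the reference chain (the first chain, or the first body with
#' `ref_label`); the distance is the RMSD over all atoms of the complete
#' oligomer.
#'
#' @param oligomers list of oligomer records from [collect_oligomers()].
#' @param species list of [rbd_species()].
#' @param ref_label label of the reference chain used for fitting.
#' @return symmetric matrix of RMSDs, Angstrom.
#' @export
oligomer_rmsd_matrix <- function(oligomers, species, ref_label = NULL) {
  labels <- vapply(species, `[[`, "", "label")
  prep <- lapply(oligomers, .oligomer_coords, species = species,
                 species_labels = labels, ref_label = ref_label)
  K <- length(prep)
  M <- matrix(0, K, K)
  if (K < 2) return(M)
  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) {
      f <- superpose(prep[[j]]$coords, prep[[i]]$coords, prep[[i]]$fit)
      M[i, j] <- M[j, i] <- f$rmsd
    }
  }
  M
}

#' GROMOS-style conformational clustering
#'
#' Iteratively, the structure with the most neighbours within `cutoff`
#' becomes a cluster centroid; it and its neighbours are removed and the
#' procedure repeats. Ties are broken by the lowest structure index.
#'
#' @param dist_matrix symmetric distance (RMSD) matrix.
#' @param cutoff neighbour cutoff, Angstrom (default 15.0).
#' @return list of class `cluster_result`: `labels` (cluster id per
#'   structure, in order of extraction), `centroids` (structure index of each
#'   cluster representative), `sizes`, `cutoff`.
#' @export
cluster_gromos <- function(dist_matrix, cutoff = 15.0) {
  M <- as.matrix(dist_matrix)
  K <- nrow(M)
  if (K == 0) stop("empty input")
  if (K != ncol(M)) stop("distance matrix must be square")
  labels <- integer(K)
  centroids <- integer(0)
  remaining <- rep(TRUE, K)
  cl <- 0L
  while (any(remaining)) {
    cl <- cl + 1L
    idx <- which(remaining)
    nn <- vapply(idx, function(i) sum(M[i, idx] < cutoff) - 1L, 0L)
    center <- idx[which.max(nn)]   # which.max takes the first (lowest index)
    members <- idx[M[center, idx] < cutoff]
    members <- union(center, members)
    labels[members] <- cl
    centroids <- c(centroids, as.integer(center))
    remaining[members] <- FALSE
  }
  out <- list(labels = labels, centroids = centroids,
              sizes = as.integer(table(factor(labels, levels = seq_len(cl)))),
              cutoff = cutoff)
  class(out) <- "cluster_result"
  out
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("gromos clustering (cutoff %.1f A): %d clusters, sizes %s\n",
              x$cutoff, length(x$centroids),
              paste(utils::head(x$sizes, 10), collapse = ", ")))
  invisible(x)
}

#' Cluster the tetramers of a trajectory
#'
#' Convenience wrapper: harvest tetramers, superpose on the reference chain,
#' build the all-atom RMSD matrix and run [cluster_gromos()].
#'
#' @inheritParams oligomer_rmsd_matrix
#' @param traj an `rbd_trajectory`.
#' @param criterion a [contact_criterion()].
#' @param cutoff clustering cutoff, Angstrom.
#' @param interval_ns harvest cadence.
#' @return list with `clusters` (a `cluster_result`), `oligomers`, `rmsd`.
#' @export
cluster_tetramers <- function(traj, species, criterion = contact_criterion(),
                              cutoff = 15.0, ref_label = NULL,
                              interval_ns = 1.0) {
  oligs <- collect_oligomers(traj, species, size = 4, criterion = criterion,
                             interval_ns = interval_ns)
  if (!length(oligs))
    return(list(clusters = NULL, oligomers = list(), rmsd = matrix(0, 0, 0)))
  M <- oligomer_rmsd_matrix(oligs, species, ref_label)
  list(clusters = cluster_gromos(M, cutoff), oligomers = oligs, rmsd = M)
}
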