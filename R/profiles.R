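#' Surface-normal density profile
#'
#' Histogram of body-center heights above the surface plane (z = 0 at the
#' topmost graphite atoms), averaged over the x-y dimensions and the
#' production frames, normalized by the bulk number density so that a
#' uniform region reads 1. The bulk density is measured over the upper
#' `bulk_fraction` of the box by default.
#'
#' @param traj an `rbd_trajectory` from a surface run.
#' @param bin_width bin width, Angstrom.
#' @param bulk_fraction fraction of the box height (from the top) used as
#'   the bulk region.
#' @param frames frame indices (default: production segment).
#' @return object of class `rbd_profile` with `bin_edges`, `values`
#'   (dimensionless), `kind = "z-profile"` and the raw counts.
#' @export
z_distribution <- function(traj, bin_width = 2.0, bulk_fraction = 0.5,
                           frames = NULL) {
  if (is.null(frames)) frames <- production_frames(traj)
  if (!length(frames)) stop("no frames to analyse")
  zmax <- traj$box[3]
  edges <- seq(0, zmax, by = bin_width)
  if (edges[length(edges)] < zmax) edges <- c(edges, zmax)
  z <- as.vector(traj$centers[frames, , 3])
  counts <- graphics::hist(z, breaks = edges, plot = FALSE)$counts
  widths <- diff(edges)
  vol <- traj$box[1] * traj$box[2] * widths
  dens <- counts / (vol * length(frames))          # bodies / A^3 per frame
  bulk_lo <- (1 - bulk_fraction) * zmax
  bulk_bins <- which(edges[-length(edges)] >= bulk_lo)
  bulk_density <- sum(counts[bulk_bins]) /
    (sum(vol[bulk_bins]) * length(frames))
  if (bulk_density <= 0)
    stop("no bodies in the designated bulk region; cannot normalize")
  out <- list(bin_edges = edges, values = dens / bulk_density,
              counts = counts, kind = "z-profile",
              bulk_density = bulk_density)
  class(out) <- "rbd_profile"
  out
}

#' Radial distribution function g(r) of body centers
#'
#' Standard center-center g(r) with minimum-image distances, normalized by
#' the ideal-gas shell count so that an uncorrelated system reads 1.
#'
#' @param traj an `rbd_trajectory`.
#' @param bin_width bin width, Angstrom.
#' @param r_max maximum distance (default: half the smallest box edge).
#' @param frames frame indices (default: production segment).
#' @return `rbd_profile` with `kind = "rdf"`.
#' @export
radial_distribution <- function(traj, bin_width = 2.0, r_max = NULL,
                                frames = NULL) {
  if (is.null(frames)) frames <- production_frames(traj)
  if (!length(frames)) stop("no frames to analyse")
  box <- traj$box
  if (is.null(r_max)) r_max <- min(box) / 2
  edges <- seq(0, r_max, by = bin_width)
  r_top <- edges[length(edges)]
  nb <- dim(traj$centers)[2]
  if (nb < 2) stop("g(r) needs at least two bodies")
  counts <- numeric(length(edges) - 1)
  for (k in frames) {
    cc <- traj$centers[k, , , drop = TRUE]
    for (i in seq_len(nb - 1)) {
      d <- sweep(cc[(i + 1):nb, , drop = FALSE], 2, cc[i, ])
      d <- minimum_image(d, box)
      r <- sqrt(rowSums(d^2))
      r <- r[r < r_top]
      if (length(r))
        counts <- counts + graphics::hist(r, breaks = edges, plot = FALSE)$counts
    }
  }
  vol <- prod(box)
  shell <- 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  ideal <- nb * (nb - 1) / 2 * shell / vol * length(frames)
  out <- list(bin_edges = edges, values = counts / ideal, counts = counts,
              kind = "rdf")
  class(out) <- "rbd_profile"
  out
}

#' @export
print.rbd_profile <- function(x, ...) {
  pk <- which.max(x$values)
  mid <- (x$bin_edges[pk] + x$bin_edges[pk + 1]) / 2
  cat(sprintf("%s: %d bins, peak %.2f at %.1f A\n", x$kind,
              length(x$values), x$values[pk], mid))
  invisible(x)
}

#' Bin centers of a profile
#' @param profile an `rbd_profile`.
#' @export
profile_midpoints <- function(profile) {
  e <- profile$bin_edges
  (e[-1] + e[-length(e)]) / 2
}

#' Radial distribution convergence between trajectory segments
#'
#' Splits the chosen frames into consecutive thirds, computes g(r) for each
#' and reports the largest absolute difference between consecutive thirds --
#' the equilibration check used alongside energy stabilization.
#'
#' @param traj an `rbd_trajectory`.
#' @param bin_width,r_max as in [radial_distribution()].
#' @param frames frame indices (default: production segment).
#' @return list with `max_diff_12`, `max_diff_23` and the three profiles.
#' @export
rdf_convergence <- function(traj, bin_width = 5.0, r_max = NULL,
                            frames = NULL) {
  if (is.null(frames)) frames <- production_frames(traj)
  thirds <- split(frames, cut(seq_along(frames), 3, labels = FALSE))
  gs <- lapply(thirds, function(fr)
    radial_distribution(traj, bin_width, r_max, frames = fr))
  d12 <- max(abs(gs[[1]]$values - gs[[2]]$values))
  d23 <- max(abs(gs[[2]]$values - gs[[3]]$values))
  list(max_diff_12 = d12, max_diff_23 = d23, profiles = gs)
}
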