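# Grid-based volume of the groove between two loops (the pY peptide-binding
# cleft between the EF and BG loops of N-SH2).

# Distance from points (n x 3) to the segment a..b (possibly extended).
dist_to_segment <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 < 1e-12) stopf("degenerate groove axis: coincident loop centroids")
  t <- ((p[, 1] - a[1]) * ab[1] + (p[, 2] - a[2]) * ab[2] +
          (p[, 3] - a[3]) * ab[3]) / len2
  t <- pmin(pmax(t, 0), 1)
  dx <- p[, 1] - (a[1] + t * ab[1])
  dy <- p[, 2] - (a[2] + t * ab[2])
  dz <- p[, 3] - (a[3] + t * ab[3])
  sqrt(dx * dx + dy * dy + dz * dz)
}

#' Grid-based groove volume between two loops
#'
#' The groove envelope is a capsule (spherocylinder) of radius
#' `capsule_radius` around the axis joining the CA centroids of the two
#' mouth selections, optionally extended by `margin` at both ends. The
#' returned volume counts grid voxels that lie inside the envelope, outside
#' every atom sphere (`vdw + probe_radius`), and are solvent-connected to
#' the envelope boundary by 6-neighbour flood fill (sealed interior voids
#' are excluded, matching the semantics of an open groove). Deterministic
#' for a fixed grid.
#'
#' @param frame an `md_structure`.
#' @param mouth_a,mouth_b logical selections whose CA-atom centroids define
#'   the groove axis (e.g. the EF and BG loops).
#' @param grid_spacing voxel edge, Angstrom (default 0.5).
#' @param probe_radius added to atom radii, Angstrom (default 1.4: a water-
#'   sized probe defines what counts as open groove space).
#' @param capsule_radius envelope radius, Angstrom (default 5).
#' @param margin axial extension beyond each centroid, Angstrom.
#' @return volume in Angstrom^3.
#' @export
groove_volume <- function(frame, mouth_a, mouth_b, grid_spacing = 0.5,
                          probe_radius = 1.4, capsule_radius = 5.0,
                          margin = 0) {
  at <- frame$atoms
  ca <- function(sel) {
    m <- sel & at$name == "CA"
    if (!any(m)) stopf("mouth selection contains no CA atoms")
    colMeans(coords(frame)[m, , drop = FALSE])
  }
  a <- ca(mouth_a); b <- ca(mouth_b)
  if (sqrt(sum((b - a)^2)) < 1e-6)
    stopf("degenerate groove axis: coincident loop centroids")
  u <- (b - a) / sqrt(sum((b - a)^2))
  a <- a - margin * u; b <- b + margin * u

  h <- grid_spacing
  lo <- pmin(a, b) - capsule_radius - h
  hi <- pmax(a, b) + capsule_radius + h
  gx <- seq(lo[1], hi[1], by = h)
  gy <- seq(lo[2], hi[2], by = h)
  gz <- seq(lo[3], hi[3], by = h)
  nx <- length(gx); ny <- length(gy); nz <- length(gz)
  pts <- cbind(rep(gx, times = ny * nz),
               rep(rep(gy, each = nx), times = nz),
               rep(gz, each = nx * ny))

  inside_env <- dist_to_segment(pts, a, b) <= capsule_radius

  # occlusion by atoms (only those that can reach the envelope)
  heavy <- which(at$is_heavy)
  occluded <- rep(FALSE, nrow(pts))
  if (length(heavy)) {
    ax <- coords(frame)[heavy, , drop = FALSE]
    rr <- at$vdw[heavy] + probe_radius
    reach <- dist_to_segment(ax, a, b) <= capsule_radius + rr
    ax <- ax[reach, , drop = FALSE]; rr <- rr[reach]
    cand <- which(inside_env)
    for (j in seq_len(nrow(ax))) {
      d2 <- (pts[cand, 1] - ax[j, 1])^2 + (pts[cand, 2] - ax[j, 2])^2 +
        (pts[cand, 3] - ax[j, 3])^2
      occluded[cand[d2 <= rr[j]^2]] <- TRUE
    }
  }
  open_mask <- inside_env & !occluded

  # flood fill from voxels adjacent to non-envelope space (or the box edge)
  mask <- array(open_mask, c(nx, ny, nz))
  env <- array(inside_env, c(nx, ny, nz))
  visited <- array(FALSE, c(nx, ny, nz))
  idx <- which(mask)
  ai <- arrayInd(idx, c(nx, ny, nz))
  seed <- logical(length(idx))
  for (s in seq_len(nrow(ai))) {
    i <- ai[s, 1]; j <- ai[s, 2]; k <- ai[s, 3]
    if (i == 1 || i == nx || j == 1 || j == ny || k == 1 || k == nz ||
        !env[i - 1, j, k] || !env[i + 1, j, k] ||
        !env[i, j - 1, k] || !env[i, j + 1, k] ||
        !env[i, j, k - 1] || !env[i, j, k + 1]) seed[s] <- TRUE
  }
  queue <- idx[seed]
  visited[queue] <- TRUE
  off <- c(-1, 1, -nx, nx, -nx * ny, nx * ny)
  nxyz <- nx * ny * nz
  # face voxel layers lie outside the envelope by construction (the grid box
  # extends one spacing beyond the capsule), so linear-index neighbour steps
  # can never wrap across array faces through the mask.
  while (length(queue)) {
    nbrs <- unique(as.vector(outer(queue, off, "+")))
    nbrs <- nbrs[nbrs >= 1 & nbrs <= nxyz]
    nbrs <- nbrs[mask[nbrs] & !visited[nbrs]]
    visited[nbrs] <- TRUE
    queue <- nbrs
  }
  sum(visited) * h^3
}

#' Mean groove volume over sampled snapshots
#'
#' Samples the trajectory at `stride_ns` intervals across `window`
#' (defaults: every 1 ns over 3-30 ns, i.e. 28 snapshots), computes the
#' groove volume for each, and returns mean and standard deviation.
#'
#' @inheritParams groove_volume
#' @param traj an `md_trajectory`.
#' @param window sampling window `c(from, to)` in ns.
#' @param stride_ns spacing between snapshots, ns.
#' @return list `mean`, `sd`, `n`, `volumes` (per-snapshot Angstrom^3),
#'   `times`.
#' @export
volume_series_average <- function(traj, mouth_a, mouth_b, window = c(3, 30),
                                  stride_ns = 1, grid_spacing = 0.5,
                                  probe_radius = 1.4, capsule_radius = 5.0,
                                  margin = 0) {
  if (window[1] < min(traj$times) - 1e-9 ||
      window[2] > max(traj$times) + 1e-9)
    stopf("sampling window [%g, %g] ns exceeds trajectory extent [%g, %g] ns",
          window[1], window[2], min(traj$times), max(traj$times))
  want <- seq(window[1], window[2], by = stride_ns)
  pick <- vapply(want, function(t) which.min(abs(traj$times - t)), integer(1))
  pick <- unique(pick)
  vols <- vapply(pick, function(k)
    groove_volume(get_frame(traj, k), mouth_a, mouth_b, grid_spacing,
                  probe_radius, capsule_radius, margin), numeric(1))
  list(mean = mean(vols), sd = stats::sd(vols), n = length(vols),
       volumes = vols, times = traj$times[pick])
}

#' Analytic capsule-minus-balls volume for clamp fixtures
#'
#' Closed-form volume of the groove envelope used by [groove_volume()] for
#' the synthetic clamp of [make_clamp_structure()]: a spherocylinder of
#' radius `capsule_radius` and axis length `separation`, minus one full
#' ball of radius `vdw + probe` at each axis endpoint (the designated
#' mouth CA atoms), valid while `vdw + probe <= capsule_radius` and
#' `separation > 2 * (vdw + probe)`.
#'
#' @param separation axis length (mouth separation), Angstrom.
#' @param capsule_radius envelope radius, Angstrom.
#' @param vdw mouth-atom van der Waals radius, Angstrom.
#' @param probe_radius probe radius, Angstrom.
#' @return volume in Angstrom^3.
#' @export
clamp_analytic_volume <- function(separation, capsule_radius, vdw = 1.70,
                                  probe_radius = 1.4) {
  rho <- vdw + probe_radius
  stopifnot(rho <= capsule_radius, separation > 2 * rho)
  pi * capsule_radius^2 * separation + 4 / 3 * pi * capsule_radius^3 -
    2 * (4 / 3 * pi * rho^3)
}
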