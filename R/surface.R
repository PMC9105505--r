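# Shrake-Rupley surface areas and the buried-interface-area quantity.

# Quasi-uniform unit sphere points on a Fibonacci (golden-angle) lattice:
# deterministic, so every area below is reproducible bit-for-bit.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  r <- sqrt(pmax(1 - z^2, 0))
  phi <- pi * (3 - sqrt(5)) * i
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Shrake-Rupley surface area
#'
#' Per-atom exposed surface area by sphere quadrature: each atom's sphere of
#' radius `vdw + probe_radius` is sampled at `n_points` quasi-uniform points
#' and the exposed fraction (points inside no neighbouring inflated sphere)
#' is multiplied by the sphere area `4*pi*(vdw + probe)^2`. With
#' `probe_radius = 0` this is the van der Waals surface; 1.4 gives the
#' conventional solvent-accessible surface.
#'
#' @param frame an `md_structure`.
#' @param sel logical selection of atoms to include (default: heavy atoms).
#' @param probe_radius probe radius, Angstrom.
#' @param n_points quadrature points per atom (>= 32; default 960).
#' @return numeric vector of per-atom areas (Angstrom^2) for the selected
#'   atoms, in selection order.
#' @export
sphere_surface_area <- function(frame, sel = frame$atoms$is_heavy,
                                probe_radius = 0, n_points = 960) {
  stopifnot(n_points >= 32, probe_radius >= 0)
  sel <- rep_len(sel, nrow(frame$atoms))
  idx <- which(sel)
  if (!length(idx)) stopf("empty selection")
  xyz <- coords(frame)[idx, , drop = FALSE]
  R <- frame$atoms$vdw[idx] + probe_radius
  n <- length(idx)
  d2 <- cross_dist2(xyz, xyz)
  coincident <- which(d2 < 1e-12 & upper.tri(d2), arr.ind = TRUE)
  if (nrow(coincident))
    stopf("coincident atom centers: atoms %d and %d",
          idx[coincident[1, 1]], idx[coincident[1, 2]])
  pts <- fibonacci_sphere(n_points)
  areas <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (R[i] + R)^2 & seq_len(n) != i)
    sp <- pts * R[i]
    sp <- sweep(sp, 2, xyz[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
        (sp[, 3] - xyz[j, 3])^2
      exposed <- exposed & dj2 > R[j]^2
      if (!any(exposed)) break
    }
    areas[i] <- 4 * pi * R[i]^2 * mean(exposed)
  }
  areas
}

#' Buried interface area between two regions
#'
#' The buried area is half of what the two regions lose on complexation:
#' `(A_a + A_b - A_complex) / 2`, where the three terms are the surface
#' areas of region A alone, region B alone, and the two-region complex.
#' By default the van der Waals surface (probe 0) is used, matching the
#' definition of the domain contact area this package quantifies; pass
#' `probe_radius = 1.4` for the solvent-accessible variant.
#'
#' @param frame an `md_structure`.
#' @param region_map a `region_map`.
#' @param region_a,region_b region names (must not overlap).
#' @param probe_radius probe radius, Angstrom.
#' @param n_points quadrature points per atom.
#' @param heavy_only restrict to heavy atoms (default TRUE).
#' @return list of class `area_result`: `a_region_a`, `a_region_b`,
#'   `a_complex`, `buried` (all Angstrom^2), plus the parameters used.
#' @export
buried_area <- function(frame, region_map, region_a, region_b,
                        probe_radius = 0, n_points = 960, heavy_only = TRUE) {
  sel_a <- region_mask(frame$atoms, region_map, region_a)
  sel_b <- region_mask(frame$atoms, region_map, region_b)
  if (any(sel_a & sel_b)) stopf("regions %s and %s overlap", region_a, region_b)
  if (heavy_only) {
    sel_a <- sel_a & frame$atoms$is_heavy
    sel_b <- sel_b & frame$atoms$is_heavy
  }
  sub <- function(m) new_structure(frame$atoms[m, , drop = FALSE], frame$label)
  a_a <- sum(sphere_surface_area(sub(sel_a), TRUE, probe_radius, n_points))
  a_b <- sum(sphere_surface_area(sub(sel_b), TRUE, probe_radius, n_points))
  a_ab <- sum(sphere_surface_area(sub(sel_a | sel_b), TRUE, probe_radius,
                                  n_points))
  structure(list(a_region_a = a_a, a_region_b = a_b, a_complex = a_ab,
                 buried = (a_a + a_b - a_ab) / 2,
                 probe_radius = probe_radius, n_points = n_points),
            class = "area_result")
}

#' Buried-area time series
#'
#' @inheritParams buried_area
#' @param traj an `md_trajectory`.
#' @param window optional analysis window in ns.
#' @return data.frame `time_ns`, `buried` (Angstrom^2).
#' @export
buried_area_series <- function(traj, region_map, region_a, region_b,
                               probe_radius = 0, n_points = 960,
                               window = NULL) {
  frames <- seq_len(n_frames(traj))
  if (!is.null(window))
    frames <- frames[traj$times >= window[1] & traj$times <= window[2]]
  if (!length(frames)) stopf("window selects no frames")
  vals <- vapply(frames, function(k)
    buried_area(get_frame(traj, k), region_map, region_a, region_b,
                probe_radius, n_points)$buried, numeric(1))
  data.frame(time_ns = traj$times[frames], buried = vals)
}
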