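# Synthetic structures and trajectories with planted ground truth.
#
# The generator emulates the analysis-facing features of an MD conformer
# stream - a loop-separation coordinate following a prescribed Gaussian
# mixture, a lysine/tyrosine pair with controllable cation-pi geometry,
# pseudo-domains with controllable contact - without any physics. Planted
# values are exact by construction so every pipeline stage can be validated
# against known truth.

std_atom <- function(serial, name, resname, resno, chain, element, x, y, z) {
  data.frame(serial = serial, name = name, resname = resname, resno = resno,
             chain = chain, element = element, x = x, y = y, z = z,
             occ = 1, bfac = 0, vdw = vdw_radius(element), is_heavy =
               element != "H", stringsAsFactors = FALSE)
}

finish_structure <- function(rows, label) {
  at <- do.call(rbind, rows)
  at$serial <- seq_len(nrow(at))
  validate_structure(new_structure(at, label))
}

#' Synthetic clamp: two walls flanking a groove of known volume
#'
#' A rigid toy analogue of the EF/BG loop clamp around the pY peptide
#' cleft: residue 67 ("EF" side) and residue 92 ("BG" side) each contribute
#' a single CA atom on the groove axis, exactly `mouth_separation` apart,
#' while flanking wall residues (66/68 and 89-91) carry atoms placed at
#' `wall_distance` from the axis - outside the reach of the groove envelope
#' so that [clamp_analytic_volume()] gives the exact grid-method target.
#'
#' @param mouth_separation CA-CA distance of the designated mouth atoms,
#'   Angstrom.
#' @param capsule_radius envelope radius the clamp is designed for,
#'   Angstrom.
#' @param wall_distance lateral wall offset from the axis; default keeps
#'   walls clear of the envelope for any probe up to 1.4 Angstrom.
#' @return an `md_structure`; attributes `mouth_separation`,
#'   `capsule_radius`.
#' @export
make_clamp_structure <- function(mouth_separation, capsule_radius = 5.0,
                                 wall_distance = capsule_radius + 4.6) {
  if (mouth_separation <= 2 * 1.70)
    stopf("walls overlap: mouth separation %.2f A below atom diameter",
          mouth_separation)
  s <- mouth_separation
  rows <- list()
  rows[[1]] <- std_atom(1, "CA", "GLY", 67, "A", "C", 0, 0, 0)
  rows[[2]] <- std_atom(2, "CA", "ASN", 92, "A", "C", 0, s, 0)
  wall <- function(resno, resname, y) {
    pos <- rbind(c(wall_distance, y, 0), c(-wall_distance, y, 0),
                 c(0, y, wall_distance), c(0, y, -wall_distance))
    nm <- c("N", "C", "O", "CB")
    do.call(rbind, lapply(1:4, function(i)
      std_atom(0, nm[i], resname, resno, "A", substr(nm[i], 1, 1),
               pos[i, 1], pos[i, 2], pos[i, 3])))
  }
  rows[[3]] <- wall(66, "TYR", 0)
  rows[[4]] <- wall(68, "SER", 0)
  rows[[5]] <- wall(89, "GLY", s)
  rows[[6]] <- wall(91, "ILE", s)
  x <- finish_structure(rows, sprintf("clamp[s=%.2f]", s))
  attr(x, "mouth_separation") <- s
  attr(x, "capsule_radius") <- capsule_radius
  x
}

#' Synthetic two-domain complex with optional bridging strap
#'
#' Two compact pseudo-domains of CA-only residues on a 3.8-Angstrom
#' lattice, facing each other along x with an exact closest heavy-atom
#' `gap`. The optional "strap" is a short third segment whose end residues
#' contact both domains within 5 Angstrom, emulating the bridging role of
#' the E6 region between N-SH2 and PTP.
#'
#' @param gap closest heavy-atom distance between the domains, Angstrom.
#' @param n_res_a,n_res_b residues per domain (kept at 8 on a 2x2x2
#'   lattice unless smaller).
#' @param with_e6_strap include the bridging segment (residues 201-203).
#' @return an `md_structure` with a `region_map` attribute defining
#'   regions `domA` (residues 1-...), `domB` (101-...), `strap` (201-203).
#' @export
make_two_domain_complex <- function(gap, n_res_a = 8, n_res_b = 8,
                                    with_e6_strap = FALSE) {
  stopifnot(gap >= 0, n_res_a >= 1, n_res_b >= 1)
  lattice <- function(n) {
    g <- expand.grid(x = c(-3.8, 0), y = c(0, 3.8), z = c(0, 3.8))
    g[order(-g$x, g$y, g$z)[seq_len(min(n, 8))], , drop = FALSE]
  }
  rows <- list()
  la <- lattice(n_res_a)
  for (i in seq_len(nrow(la)))
    rows[[length(rows) + 1]] <- std_atom(0, "CA", "ALA", i, "A", "C",
                                         la$x[i], la$y[i], la$z[i])
  lb <- lattice(n_res_b)
  for (i in seq_len(nrow(lb)))
    rows[[length(rows) + 1]] <- std_atom(0, "CA", "ALA", 100 + i, "A", "C",
                                         gap - lb$x[i], lb$y[i], lb$z[i])
  nmax_a <- max(seq_len(nrow(la)))
  nmax_b <- 100 + max(seq_len(nrow(lb)))
  if (with_e6_strap) {
    sp <- rbind(c(0, -3.5, 0), c(gap / 2, -4.5, 0), c(gap, -3.5, 0))
    for (i in 1:3)
      rows[[length(rows) + 1]] <- std_atom(0, "CA", "GLY", 200 + i, "A", "C",
                                           sp[i, 1], sp[i, 2], sp[i, 3])
  }
  x <- finish_structure(rows, sprintf("two_domain[gap=%.2f]", gap))
  rmap <- structure(list(
    domA = data.frame(chain = "A", start = 1, end = nmax_a),
    domB = data.frame(chain = "A", start = 101, end = nmax_b),
    strap = data.frame(chain = "A", start = 201, end = 203)
  ), class = "region_map")
  attr(x, "region_map") <- rmap
  attr(x, "gap") <- gap
  x
}

#' Trajectory of a two-domain complex with prescribed per-frame gaps
#'
#' @param gaps numeric vector of closest-approach gaps, one per frame.
#' @param dt frame spacing, ns.
#' @param ... passed to [make_two_domain_complex()].
#' @return an `md_trajectory` with the complex's `region_map` attached.
#' @export
two_domain_trajectory <- function(gaps, dt = 0.005, ...) {
  frames <- lapply(gaps, make_two_domain_complex, ...)
  traj <- traj_from_frames(frames, times = (seq_along(gaps) - 1) * dt,
                           label = "two_domain_traj")
  attr(traj, "region_map") <- attr(frames[[1]], "region_map")
  attr(traj, "gaps") <- gaps
  traj
}

#' Specification for a synthetic conformer ensemble
#'
#' @param n_frames number of frames (>= 2).
#' @param dt frame spacing, ns (default 0.005, i.e. 5 ps).
#' @param mixture list of `c(weight, center, width)` triples (Angstrom)
#'   describing the loop-separation Gaussian mixture.
#' @param switch_rate optional per-frame probability of re-drawing the
#'   mixture component (a multi-state chain); `NULL` = i.i.d. components.
#' @param cation_pi list: `fraction` of frames in contact, contact
#'   geometry `L_in`/`theta_in`, non-contact geometry `L_out`/`theta_out`.
#' @param fluct per-residue jitter amplitude (per-coordinate standard
#'   deviation, Angstrom) for the scaffold residues; recycled.
#' @param seed RNG seed.
#' @return list of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_frames = 6000, dt = 0.005,
                          mixture = list(c(1, 8.8, 0.6)),
                          switch_rate = NULL,
                          cation_pi = list(fraction = 0.4, L_in = 6,
                                           theta_in = 30, L_out = 10.5,
                                           theta_out = 80),
                          fluct = 0.2, seed = 1) {
  w <- vapply(mixture, `[`, numeric(1), 1)
  stopifnot(n_frames >= 2, all(w >= 0), abs(sum(w) - 1) < 1e-8,
            all(vapply(mixture, `[`, numeric(1), 3) > 0))
  structure(list(n_frames = n_frames, dt = dt, mixture = mixture,
                 switch_rate = switch_rate, cation_pi = cation_pi,
                 fluct = fluct, seed = seed),
            class = "ensemble_spec")
}

# Scaffold atom table for the synthetic N-SH2-like construct. Residue
# numbering mirrors the real domain so the standard selectors work: Ser36,
# Pro38, Lys55 (with NZ), Thr59, Tyr62, Tyr66 (with ring), Gly67 (EF mouth),
# Asn92 (BG mouth), plus filler CA residues 1-20.
scaffold_atoms <- function() {
  rows <- list()
  add <- function(name, resname, resno, element, x, y, z)
    rows[[length(rows) + 1]] <<- std_atom(0, name, resname, resno, "A",
                                          element, x, y, z)
  for (i in 1:20) add("CA", "ALA", i, "C", -20 + 2 * i, -8, 6)
  add("CA", "SER", 36, "C", -6, 6, 0)
  add("CA", "PRO", 38, "C", -8, 4, 2)
  add("CA", "LYS", 55, "C", 0, 8, 0)
  add("O",  "LYS", 55, "O", 1.2, 8.5, 0.5)
  add("NZ", "LYS", 55, "N", 0, 0, 0)       # positioned per frame
  add("CA", "THR", 59, "C", -4, 9, 1)
  add("N",  "THR", 59, "N", -4.8, 9.8, 1.2)
  add("CA", "TYR", 62, "C", -2, 11, 2)
  add("O",  "TYR", 62, "O", -1.1, 11.6, 2.4)
  add("N",  "TYR", 66, "N", 0.8, 11.2, 3.1)
  add("CA", "TYR", 66, "C", 0, 10.5, 2.5)
  ring_center <- c(0, 12, 4)
  for (k in seq_along(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"))) {
    ang <- (k - 1) * pi / 3
    nm <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")[k]
    add(nm, "TYR", 66, "C", ring_center[1] + 1.39 * cos(ang),
        ring_center[2] + 1.39 * sin(ang), ring_center[3])
  }
  add("CA", "GLY", 67, "C", -4.1, 0, 0)    # EF mouth, placed per frame
  add("CA", "ASN", 92, "C", 4.1, 0, 0)     # BG mouth, placed per frame
  at <- do.call(rbind, rows)
  at$serial <- seq_len(nrow(at))
  at
}

#' Sample a synthetic conformer trajectory with planted ground truth
#'
#' Frames carry a synthetic N-SH2-like scaffold in which the Gly67 CA -
#' Asn92 CA separation is drawn from the spec's Gaussian mixture and
#' planted exactly (the two CAs are placed symmetrically about the origin
#' at the sampled distance), the Lys55 NZ / Tyr66 ring pair satisfies the
#' cation-pi thresholds in exactly `round(fraction * n_frames)` frames
#' (contact frames chosen by seeded sampling, geometry deterministic), and
#' all other scaffold residues jitter isotropically with the stated
#' per-residue amplitudes. The planted values travel with the trajectory as
#' a `ground_truth` attribute.
#'
#' @param spec an [ensemble_spec()].
#' @return an `md_trajectory`; `attr(, "ground_truth")` lists the planted
#'   mixture, per-frame separations and components, cation-pi contact
#'   frames and realised fraction, fluctuation amplitudes and seed.
#' @export
sample_trajectory <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  at <- scaffold_atoms()
  n <- spec$n_frames
  K <- length(spec$mixture)
  w <- vapply(spec$mixture, `[`, numeric(1), 1)
  ce <- vapply(spec$mixture, `[`, numeric(1), 2)
  wd <- vapply(spec$mixture, `[`, numeric(1), 3)

  i67 <- atom_index(at, "A", 67, "CA")
  i92 <- atom_index(at, "A", 92, "CA")
  inz <- atom_index(at, "A", 55, "NZ")
  ring_names <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
  iring <- vapply(ring_names, function(nm) atom_index(at, "A", 66, nm),
                  integer(1))
  ring_ctr <- colMeans(cbind(at$x[iring], at$y[iring], at$z[iring]))
  fixed <- c(i67, i92, inz, iring)

  res_key <- paste(at$chain, at$resno)
  res_ids <- unique(res_key)
  amp <- rep_len(spec$fluct, length(res_ids))
  amp_atom <- amp[match(res_key, res_ids)]
  amp_atom[fixed] <- 0

  cp <- spec$cation_pi
  gt <- NULL
  xyz <- array(NA_real_, c(n, nrow(at), 3))
  base <- cbind(at$x, at$y, at$z)
  with_local_seed(spec$seed, {
    comp <- integer(n)
    if (is.null(spec$switch_rate)) {
      comp <- sample.int(K, n, replace = TRUE, prob = w)
    } else {
      comp[1] <- sample.int(K, 1, prob = w)
      flip <- stats::runif(n) < spec$switch_rate
      for (k in 2:n)
        comp[k] <- if (flip[k]) sample.int(K, 1, prob = w) else comp[k - 1]
    }
    sep <- stats::rnorm(n, ce[comp], wd[comp])
    sep <- pmax(sep, 3.5)                  # physical floor, never triggered
                                           # in the study's regimes
    n_contact <- round(cp$fraction * n)
    contact <- sort(sample.int(n, n_contact))
    in_contact <- logical(n); in_contact[contact] <- TRUE

    dir_in <- c(sin(cp$theta_in * pi / 180), 0, cos(cp$theta_in * pi / 180))
    dir_out <- c(sin(cp$theta_out * pi / 180), 0, cos(cp$theta_out * pi / 180))
    for (k in seq_len(n)) {
      fr <- base + matrix(stats::rnorm(3 * nrow(at), 0, amp_atom), ncol = 3)
      fr[fixed, ] <- base[fixed, ]
      fr[i67, ] <- c(-sep[k] / 2, 0, 0)
      fr[i92, ] <- c(sep[k] / 2, 0, 0)
      nz <- if (in_contact[k]) ring_ctr + cp$L_in * dir_in
            else ring_ctr + cp$L_out * dir_out
      fr[inz, ] <- nz
      xyz[k, , ] <- fr
    }
    gt <- list(mixture = spec$mixture, separations = sep, components = comp,
                cation_pi_contact = contact,
                cation_pi_fraction = n_contact / n,
                fluct = amp, seed = spec$seed)
  })
  traj <- new_trajectory(at, xyz, times = (seq_len(n) - 1) * spec$dt,
                         label = sprintf("synthetic[seed=%d]", spec$seed))
  attr(traj, "ground_truth") <- gt
  traj
}

#' Write a trajectory's planted ground truth as key-value text
#' @param traj a trajectory from [sample_trajectory()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_ground_truth <- function(traj, path) {
  gt <- attr(traj, "ground_truth")
  if (is.null(gt)) stopf("trajectory carries no ground truth")
  con <- file(path, "w"); on.exit(close(con))
  for (k in seq_along(gt$mixture))
    writeLines(sprintf("mixture_%d: weight=%g center=%g width=%g", k,
                       gt$mixture[[k]][1], gt$mixture[[k]][2],
                       gt$mixture[[k]][3]), con)
  writeLines(sprintf("cation_pi_fraction: %g", gt$cation_pi_fraction), con)
  writeLines(sprintf("seed: %d", gt$seed), con)
  writeLines(sprintf("n_frames: %d", length(gt$separations)), con)
  invisible(path)
}

#' The six-construct synthetic study suite
#'
#' Ensemble specifications emulating the study design this package
#' re-analyses: three wild-type-like runs whose loop-separation ensembles
#' stay in the closed range (centres 8.3-10.4 Angstrom), and three
#' mutant-like runs (single-missense, double-missense, and region-deletion
#' analogues) that acquire additional open-ward ensembles at 11.7, 12.6 and
#' 13.6 Angstrom. Cation-pi contact fractions are high and similar for the
#' closed-retaining constructs and reduced for the deletion analogue.
#'
#' @param n_frames frames per construct.
#' @param seed base seed; construct `i` uses `seed + i`.
#' @return named list of [ensemble_spec()]s with a `group` attribute
#'   (`"wt"` or `"mutant"`) per construct.
#' @export
synthetic_construct_suite <- function(n_frames = 6000, seed = 20220427) {
  specs <- list(
    wt_run1 = list(list(c(1, 8.8, 0.60)), 0.40),
    wt_run2 = list(list(c(1, 8.6, 0.65)), 0.38),
    wt_run3 = list(list(c(1, 9.0, 0.60)), 0.42),
    single_missense = list(list(c(0.45, 8.8, 0.6), c(0.55, 11.7, 0.8)), 0.40),
    double_missense = list(list(c(0.35, 8.8, 0.6), c(0.65, 12.6, 0.8)), 0.38),
    region_deletion = list(list(c(0.30, 8.8, 0.6), c(0.70, 13.6, 0.8)), 0.25)
  )
  groups <- c("wt", "wt", "wt", "mutant", "mutant", "mutant")
  out <- vector("list", length(specs))
  names(out) <- names(specs)
  for (i in seq_along(specs)) {
    cp <- list(fraction = specs[[i]][[2]], L_in = 6, theta_in = 30,
               L_out = 10.5, theta_out = 80)
    out[[i]] <- ensemble_spec(n_frames = n_frames, mixture = specs[[i]][[1]],
                              cation_pi = cp, seed = seed + i)
    attr(out[[i]], "group") <- groups[i]
  }
  out
}
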