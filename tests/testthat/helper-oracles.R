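# Shared fixtures and independent oracles, all built in code.

# Compact md_structure builder: one row per atom.
toy_structure <- function(name, resno, x, y, z, chain = "A",
                          element = substr(name, 1, 1), resname = "ALA",
                          label = "toy") {
  n <- length(name)
  at <- data.frame(serial = seq_len(n), name = name, resname = resname,
                   resno = resno, chain = chain, element = element,
                   x = x, y = y, z = z, occ = 1, bfac = 0,
                   vdw = shp2md::vdw_radius(element),
                   is_heavy = element != "H", stringsAsFactors = FALSE)
  shp2md:::new_structure(at, label)
}

# CA-only chain covering the full SHP2 residue range, for region selection.
full_length_ca <- function(chain = "A", resno = 1:529) {
  toy_structure(rep("CA", length(resno)), resno,
                x = resno * 1.5, y = 0, z = 0, chain = chain,
                element = "C", label = "ca_chain")
}

rigid_move <- function(s, angle_deg = 0, axis = c(0, 0, 1), shift = c(0, 0, 0)) {
  th <- angle_deg * pi / 180
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  xyz <- shp2md::coords(s) %*% t(R)
  s$atoms$x <- xyz[, 1] + shift[1]
  s$atoms$y <- xyz[, 2] + shift[2]
  s$atoms$z <- xyz[, 3] + shift[3]
  s
}

# Random two-region toy for interface oracle comparisons.
random_two_region_toy <- function(seed, n = 50, spread = 8) {
  set.seed(seed)
  n_a <- n %/% 2; n_b <- n - n_a
  xyz <- matrix(runif(3 * n, 0, spread), ncol = 3)
  el <- sample(c("C", "N", "O", "H"), n, replace = TRUE,
               prob = c(0.5, 0.2, 0.2, 0.1))
  nm <- gsub("[.]", "", make.unique(el))
  resno <- c(sample(1:10, n_a, replace = TRUE),
             sample(101:110, n_b, replace = TRUE))
  s <- toy_structure(nm, resno, xyz[, 1], xyz[, 2], xyz[, 3], element = el)
  rmap <- structure(list(a = data.frame(chain = "A", start = 1, end = 10),
                         b = data.frame(chain = "A", start = 101, end = 110)),
                    class = "region_map")
  list(s = s, rmap = rmap)
}

# --- independent oracles ---------------------------------------------------

# Exposed area of each of two spheres of radius r at centre distance d
# (vdW surface): 4*pi*r^2 - 2*pi*r*h with cap height h = r - d/2.
two_sphere_exposed_area <- function(r, d) {
  h <- r - d / 2
  4 * pi * r^2 - 2 * pi * r * h
}

# Brute-force per-residue min heavy-atom distance between two selections.
brute_min_dist <- function(frame, sel_a, sel_b) {
  at <- frame$atoms
  ia <- which(sel_a & at$is_heavy)
  ib <- which(sel_b & at$is_heavy)
  xyz <- shp2md::coords(frame)
  key <- paste(at$chain[ia], at$resno[ia], sep = ":")
  out <- c()
  for (r in unique(key)) {
    best <- Inf
    for (i in ia[key == r]) for (j in ib) {
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (d < best) best <- d
    }
    out[r] <- best
  }
  out
}

# Exhaustive-subset oracle for the hypergeometric point probability.
enum_outcome_p <- function(n_total, n_group, n_matches) {
  subsets <- utils::combn(n_total, n_group)
  carriers <- seq_len(n_group)  # WLOG items 1..n_group carry the outcome
  hits <- apply(subsets, 2, function(s) sum(s %in% carriers) == n_matches)
  mean(hits)
}

# Numeric rigid-motion oracle: minimise RMSD over rotations (Euler angles)
# and translations by general-purpose optimisation from several starts.
numeric_min_rmsd <- function(P, Q) {
  rot <- function(a) {
    cz <- cos(a[1]); sz <- sin(a[1]); cy <- cos(a[2]); sy <- sin(a[2])
    cx <- cos(a[3]); sx <- sin(a[3])
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(par) {
    R <- rot(par[1:3])
    moved <- P %*% t(R) + matrix(par[4:6], nrow(P), 3, byrow = TRUE)
    sqrt(mean(rowSums((moved - Q)^2)))
  }
  best <- Inf
  for (s in 1:12) {
    a0 <- c(s, s * 2, s * 3) %% (2 * pi)
    f <- stats::optim(c(a0, colMeans(Q) - colMeans(P)), obj,
                      method = "BFGS", control = list(maxit = 2000,
                                                      reltol = 1e-14))
    best <- min(best, f$value)
  }
  best
}

# Analytic Gaussian curve wrapped as a fraction_curve object.
synthetic_curve <- function(x, centers, widths, amps, noise_sd = 0,
                            window_width = 1.5, seed = NULL) {
  y <- numeric(length(x))
  for (k in seq_along(centers))
    y <- y + amps[k] * exp(-(x - centers[k])^2 / (2 * widths[k]^2))
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- pmax(y + stats::rnorm(length(x), 0, noise_sd), 0)
  }
  structure(data.frame(center = x, fraction = y),
            class = c("fraction_curve", "data.frame"),
            window_width = window_width, step = x[2] - x[1],
            n_frames = NA_integer_, observable = "synthetic")
}

# Minimal ring+cation trajectory with an exact planted (L, theta) geometry.
planted_cation_pi_traj <- function(L, theta_deg, n = 2) {
  spec <- shp2md::ensemble_spec(
    n_frames = n, mixture = list(c(1, 8.8, 0.6)),
    cation_pi = list(fraction = 1, L_in = L, theta_in = theta_deg,
                     L_out = 12, theta_out = 85),
    fluct = 0, seed = 11)
  shp2md::sample_trajectory(spec)
}
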