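# Fraction curves, synchronised Gaussian deconvolution, cation-pi
# detection, averaged conformers, hypergeometric outcome test.

const_series <- function(values, dt = 0.005) {
  structure(data.frame(time_ns = (seq_along(values) - 1) * dt,
                       value = values),
            class = c("distance_series", "data.frame"), observable = "toy")
}

test_that("fraction curves localise point masses and tile to total mass 1", {
  fc <- fraction_curve(const_series(rep(8.2, 100)), window_width = 1.5,
                       step = 1.5)
  expect_true(all(fc$fraction %in% c(0, 1)))
  expect_equal(sum(fc$fraction), 1)
  in_win <- abs(fc$center - 8.2) <= 0.75
  expect_equal(fc$fraction[fc$fraction == 1],
               fc$fraction[in_win][fc$fraction[in_win] == 1])

  bim <- fraction_curve(const_series(c(rep(8, 50), rep(14, 50))),
                        window_width = 1.5, step = 1.5)
  expect_equal(sum(bim$fraction), 1)
  expect_setequal(bim$fraction[bim$fraction > 0], c(0.5, 0.5))
})

test_that("fraction curves match the analytic Gaussian mass within binomial error", {
  n <- 5400
  set.seed(123)
  v <- rnorm(n, 10, 0.5)
  fc <- fraction_curve(const_series(v), window_width = 1.5, step = 0.3)
  for (i in seq_len(nrow(fc))) {
    p <- pnorm(fc$center[i] + 0.75, 10, 0.5) - pnorm(fc$center[i] - 0.75, 10, 0.5)
    tol <- 3 * sqrt(p * (1 - p) / n) + 2 / n
    expect_lt(abs(fc$fraction[i] - p), tol + 1e-12)
  }
})

test_that("a single exact Gaussian is recovered to high precision", {
  x <- seq(5, 12, by = 0.3)
  cv <- synthetic_curve(x, centers = 8.5, widths = 0.6, amps = 0.3)
  fit <- fit_column(list(cv), K = 1, seed = 4)
  expect_equal(fit$centers, 8.5, tolerance = 1e-4)
  expect_equal(fit$widths, 0.6, tolerance = 1e-4)
  expect_equal(as.numeric(fit$amplitudes), 0.3, tolerance = 1e-4)
  expect_lt(fit$residual, 1e-8)
})

test_that("column-synchronised fits share centres and widths across curves", {
  x <- seq(6, 17, by = 0.3)
  amps <- list(c(0.30, 0.05), c(0.18, 0.15), c(0.04, 0.28))
  curves <- lapply(1:3, function(i)
    synthetic_curve(x, centers = c(8.8, 13.6), widths = c(0.7, 0.9),
                    amps = amps[[i]], noise_sd = 0.003, seed = 100 + i))
  fit <- fit_column(curves, K = 2, seed = 4)
  expect_equal(fit$centers, c(8.8, 13.6), tolerance = 0.02)
  expect_equal(fit$widths, c(0.7, 0.9), tolerance = 0.05)
  for (i in 1:3)
    expect_equal(unname(fit$amplitudes[i, ]), amps[[i]], tolerance = 0.05)
})

test_that("fit residual is non-increasing in K and invariant to curve order", {
  x <- seq(6, 17, by = 0.3)
  curves <- lapply(1:2, function(i)
    synthetic_curve(x, centers = c(9, 13), widths = c(0.8, 1.0),
                    amps = c(0.2, 0.1 * i), noise_sd = 0.004, seed = 200 + i))
  f1 <- fit_column(curves, K = 1, seed = 9)
  f2 <- fit_column(curves, K = 2, seed = 9)
  expect_lte(f2$residual, f1$residual + 1e-12)

  fp <- fit_column(rev(curves), K = 2, seed = 9)
  expect_equal(fp$centers, f2$centers, tolerance = 1e-6)
  expect_equal(fp$widths, f2$widths, tolerance = 1e-6)
  expect_equal(fp$amplitudes[2:1, ], f2$amplitudes, tolerance = 1e-6)
})

test_that("amplitudes are never negative and K cannot exceed the windows", {
  x <- seq(6, 10, by = 0.5)
  cv <- synthetic_curve(x, centers = 8, widths = 0.5, amps = 0.2,
                        noise_sd = 0.01, seed = 5)
  fit <- fit_column(list(cv), K = 2, seed = 5)
  expect_true(all(fit$amplitudes >= 0))
  expect_error(fit_column(list(cv), K = 100, seed = 1), "exceeds")
})

test_that("cation-pi geometry follows the planted L and theta exactly", {
  tr <- planted_cation_pi_traj(L = 6, theta_deg = 0)
  g <- cation_pi_geometry(tr, c("A", 55), c("A", 66))
  expect_equal(g$L, rep(6, 2), tolerance = 1e-9)
  expect_equal(g$theta, rep(0, 2), tolerance = 1e-6)

  tr90 <- planted_cation_pi_traj(L = 6, theta_deg = 90)
  g90 <- cation_pi_geometry(tr90, c("A", 55), c("A", 66))
  expect_equal(g90$theta, rep(90, 2), tolerance = 1e-6)
  expect_equal(suppressMessages(
    cation_pi_fraction(tr90, c("A", 55), c("A", 66), window = NULL)), 0)
})

test_that("the 60-degree angle boundary is inclusive", {
  just_in <- planted_cation_pi_traj(L = 6, theta_deg = 59.9)
  expect_equal(suppressMessages(
    cation_pi_fraction(just_in, c("A", 55), c("A", 66), window = NULL)), 1)
  just_out <- planted_cation_pi_traj(L = 6, theta_deg = 60.1)
  expect_equal(suppressMessages(
    cation_pi_fraction(just_out, c("A", 55), c("A", 66), window = NULL)), 0)
})

test_that("planted contact fractions are recovered exactly", {
  spec <- ensemble_spec(n_frames = 500,
                        cation_pi = list(fraction = 0.4, L_in = 6,
                                         theta_in = 30, L_out = 10.5,
                                         theta_out = 80), seed = 21)
  tr <- sample_trajectory(spec)
  expect_equal(suppressMessages(
    cation_pi_fraction(tr, c("A", 55), c("A", 66), window = NULL)), 0.4)
})

test_that("theta is invariant under in-plane ring rotation and rigid motion", {
  tr <- planted_cation_pi_traj(L = 6, theta_deg = 35, n = 2)
  g0 <- cation_pi_geometry(tr, c("A", 55), c("A", 66))
  # rotate the whole frame rigidly
  frames <- lapply(1:2, function(k)
    rigid_move(get_frame(tr, k), angle_deg = 71, axis = c(2, -1, 1),
               shift = c(4, 4, -9)))
  g1 <- cation_pi_geometry(traj_from_frames(frames), c("A", 55), c("A", 66))
  expect_equal(g1$L, g0$L, tolerance = 1e-9)
  expect_equal(g1$theta, g0$theta, tolerance = 1e-6)
  # rotate the ring atoms about their own normal (in-plane): theta unchanged
  fr <- get_frame(tr, 1)
  iring <- which(fr$atoms$resno == 66 &
                   fr$atoms$name %in% c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"))
  ctr <- colMeans(coords(fr)[iring, ])
  xyz <- coords(fr)[iring, ]
  th <- 40 * pi / 180
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
               byrow = TRUE)
  rot <- sweep(sweep(xyz, 2, ctr) %*% t(Rz), 2, ctr, "+")
  fr$atoms[iring, c("x", "y", "z")] <- rot
  g2 <- cation_pi_geometry(as_trajectory(fr), c("A", 55), c("A", 66))
  expect_equal(g2$theta[1], g0$theta[1], tolerance = 1e-6)
})

test_that("missing ring atoms are reported", {
  tr <- planted_cation_pi_traj(L = 6, theta_deg = 30)
  tr$atoms <- tr$atoms[tr$atoms$name != "CZ", ]
  expect_error(cation_pi_geometry(tr, c("A", 55), c("A", 66)), "not found")
})

test_that("averaged conformers reproduce trivial ensembles", {
  s <- toy_structure(rep("CA", 4), 1:4, x = c(0, 3.8, 7.6, 11.4),
                     y = c(0, 1.9, 0, 1.9), z = 0)
  tr <- traj_from_frames(list(s, s, s))
  avg <- average_conformer(tr, rep(TRUE, 4))
  expect_equal(coords(avg), coords(s), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(avg$atoms$bfac, rep(0, 4), tolerance = 1e-12)

  up <- s; up$atoms$z[3] <- 0.5
  dn <- s; dn$atoms$z[3] <- -0.5
  tr2 <- traj_from_frames(list(up, dn))
  avg2 <- average_conformer(tr2, atom_sel(tr2, resno = c(1, 2, 4)))
  expect_equal(avg2$atoms$z[3], 0, tolerance = 1e-10)
  expect_equal(avg2$atoms$bfac[3], 0.5, tolerance = 1e-10)
  expect_lt(max(avg2$atoms$bfac[-3]), 1e-10)
})

test_that("per-residue mobility annotation recovers planted jitter amplitudes", {
  spec <- ensemble_spec(n_frames = 1500, mixture = list(c(1, 8.8, 1e-6)),
                        fluct = 0.25, seed = 13)
  tr <- sample_trajectory(spec)
  # align on the rigid ring atoms so jitter is measured, not absorbed
  ring_sel <- atom_sel(tr, resno = 66,
                       name = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"))
  avg <- average_conformer(tr, ring_sel)
  filler <- avg$atoms$resno <= 20 & avg$atoms$name == "CA"
  got <- avg$atoms$bfac[filler]
  expected <- sqrt(3) * 0.25
  expect_equal(mean(got), expected, tolerance = 0.05)
})

test_that("the hypergeometric point probability matches exhaustive enumeration", {
  expect_equal(hypergeometric_outcome_p(6, 3, 3), 1 / choose(6, 3),
               tolerance = 1e-14)
  expect_equal(hypergeometric_outcome_p(6, 3, 3), 0.05, tolerance = 1e-14)
  expect_equal(hypergeometric_outcome_p(2, 1, 1), 0.5)
  for (n in 4:10) {
    for (k in 1:min(n - 1, 4)) {
      for (j in 0:k) {
        expect_equal(hypergeometric_outcome_p(n, k, j),
                     enum_outcome_p(n, k, j), tolerance = 1e-12)
      }
    }
  }
  expect_error(hypergeometric_outcome_p(6, 3, 4), "invalid counts")
  # upper-tail option
  expect_equal(hypergeometric_outcome_p(6, 3, 3, tail = TRUE), 0.05)
  expect_gte(hypergeometric_outcome_p(6, 3, 2, tail = TRUE),
             hypergeometric_outcome_p(6, 3, 2))
})
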