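# Shrake-Rupley areas, buried interface area, groove volumes.

test_that("isolated spheres reproduce the closed-form area", {
  s <- toy_structure("CA", 1, 0, 0, 0)
  a0 <- sphere_surface_area(s, probe_radius = 0, n_points = 960)
  expect_equal(a0, 4 * pi * 1.7^2, tolerance = 5e-3)
  a14 <- sphere_surface_area(s, probe_radius = 1.4, n_points = 960)
  expect_equal(a14, 4 * pi * 3.1^2, tolerance = 5e-3)
})

test_that("two overlapping spheres match the analytic cap formula within 2%", {
  s <- toy_structure(c("C1", "C2"), c(1, 2), x = c(0, 2), y = 0, z = 0,
                     element = "C")
  areas <- sphere_surface_area(s, probe_radius = 0, n_points = 960)
  exact <- two_sphere_exposed_area(1.7, 2)
  expect_equal(areas[1], exact, tolerance = 0.02)
  expect_equal(areas[2], exact, tolerance = 0.02)
})

test_that("quadrature converges: doubling the points moves areas < 1%", {
  set.seed(31)
  xyz <- matrix(rnorm(150, sd = 4), ncol = 3)
  s <- toy_structure(sprintf("C%d", 1:50), 1:50, xyz[, 1], xyz[, 2],
                     xyz[, 3], element = "C")
  a1 <- sum(sphere_surface_area(s, probe_radius = 1.4, n_points = 960))
  a2 <- sum(sphere_surface_area(s, probe_radius = 1.4, n_points = 1920))
  expect_lt(abs(a1 - a2) / a2, 0.01)
})

test_that("coincident atom centres are rejected naming the pair", {
  s <- toy_structure(c("C1", "C2"), c(1, 2), x = c(0, 0), y = 0, z = 0,
                     element = "C")
  expect_error(sphere_surface_area(s), "coincident.*1 and 2")
})

test_that("buried area obeys its defining identity and vanishes for separated regions", {
  toy <- make_two_domain_complex(20)
  rmap <- attr(toy, "region_map")
  res <- buried_area(toy, rmap, "domA", "domB", n_points = 960)
  expect_equal(res$buried,
               (res$a_region_a + res$a_region_b - res$a_complex) / 2,
               tolerance = 1e-12)
  expect_equal(res$buried, 0, tolerance = 1e-9)  # beyond contact range

  close_toy <- make_two_domain_complex(2.5)
  res2 <- buried_area(close_toy, rmap, "domA", "domB", n_points = 960)
  expect_gt(res2$buried, 0)
  expect_lte(res2$a_complex, res2$a_region_a + res2$a_region_b + 1e-9)
})

test_that("two touching single-atom regions bury the spherical cap area", {
  s <- toy_structure(c("CA", "CA"), c(1, 101), x = c(0, 2), y = 0, z = 0)
  rmap <- structure(list(a = data.frame(chain = "A", start = 1, end = 1),
                         b = data.frame(chain = "A", start = 101, end = 101)),
                    class = "region_map")
  res <- buried_area(s, rmap, "a", "b", n_points = 960)
  r <- 1.7; h <- r - 2 / 2
  expect_equal(res$buried, 2 * pi * r * h, tolerance = 0.02)
})

test_that("areas are invariant under global rigid motion", {
  toy <- make_two_domain_complex(2.5)
  rmap <- attr(toy, "region_map")
  a <- buried_area(toy, rmap, "domA", "domB", n_points = 960)$buried
  moved <- rigid_move(toy, angle_deg = 63, axis = c(1, 1, 0),
                      shift = c(10, -4, 2))
  b <- buried_area(moved, rmap, "domA", "domB", n_points = 960)$buried
  # quadrature points are fixed in the lab frame, so rotation leaves only
  # discretisation noise
  expect_equal(a, b, tolerance = 0.01)
})

test_that("buried-area series is flat for a constant docking geometry", {
  tr <- two_domain_trajectory(rep(2.5, 4))
  rmap <- attr(tr, "region_map")
  ba <- buried_area_series(tr, rmap, "domA", "domB", n_points = 480)
  expect_equal(nrow(ba), 4)
  expect_lt(diff(range(ba$buried)), 1e-9)
  expect_gt(ba$buried[1], 0)
})

test_that("clamp groove volume matches the analytic envelope within 5%", {
  cl <- make_clamp_structure(10, capsule_radius = 5)
  v <- groove_volume(cl, atom_sel(cl, resno = 67, name = "CA"),
                     atom_sel(cl, resno = 92, name = "CA"),
                     grid_spacing = 0.4, probe_radius = 1.4,
                     capsule_radius = 5)
  expect_equal(v, clamp_analytic_volume(10, 5), tolerance = 0.05)
})

test_that("groove volume increases strictly with mouth separation", {
  seps <- c(8.2, 9.5, 10.8, 12.1, 13.4, 14.8)
  vols <- vapply(seps, function(s) {
    cl <- make_clamp_structure(s, capsule_radius = 5)
    groove_volume(cl, atom_sel(cl, resno = 67, name = "CA"),
                  atom_sel(cl, resno = 92, name = "CA"),
                  grid_spacing = 0.5, capsule_radius = 5)
  }, numeric(1))
  expect_true(all(diff(vols) > 0))
})

test_that("groove volume is invariant under rigid motion and rejects degenerate axes", {
  cl <- make_clamp_structure(9)
  sel_a <- atom_sel(cl, resno = 67, name = "CA")
  sel_b <- atom_sel(cl, resno = 92, name = "CA")
  v1 <- groove_volume(cl, sel_a, sel_b, grid_spacing = 0.5)
  cl2 <- rigid_move(cl, angle_deg = 45, axis = c(1, 0, 1), shift = c(3, 9, -5))
  v2 <- groove_volume(cl2, sel_a, sel_b, grid_spacing = 0.5)
  expect_equal(v1, v2, tolerance = 0.02)

  degen <- cl
  degen$atoms[sel_b, c("x", "y", "z")] <- degen$atoms[sel_a, c("x", "y", "z")]
  expect_error(groove_volume(degen, sel_a, sel_b), "degenerate")
})

test_that("volume averaging over snapshots has the expected statistics", {
  cl1 <- make_clamp_structure(9)
  tr_const <- traj_from_frames(rep(list(cl1), 5), times = 0:4)
  sel_a <- atom_sel(cl1, resno = 67, name = "CA")
  sel_b <- atom_sel(cl1, resno = 92, name = "CA")
  va <- volume_series_average(tr_const, sel_a, sel_b, window = c(0, 4),
                              stride_ns = 1)
  expect_equal(va$n, 5)
  expect_equal(va$sd, 0)

  cl2 <- make_clamp_structure(12)
  tr_alt <- traj_from_frames(list(cl1, cl2, cl1, cl2), times = 0:3)
  vb <- volume_series_average(tr_alt, sel_a, sel_b, window = c(0, 3),
                              stride_ns = 1)
  v1 <- groove_volume(cl1, sel_a, sel_b)
  v2 <- groove_volume(cl2, sel_a, sel_b)
  expect_equal(vb$mean, (v1 + v2) / 2, tolerance = 1e-9)

  expect_error(volume_series_average(tr_const, sel_a, sel_b,
                                     window = c(0, 10)), "exceeds")
})

test_that("closed-like and open-like ensembles order their mean groove volumes", {
  mk <- function(center, seed) {
    spec <- ensemble_spec(n_frames = 1001, mixture = list(c(1, center, 0.3)),
                          seed = seed)
    sample_trajectory(spec)
  }
  closed <- mk(8.8, 1); open <- mk(14.8, 2)
  va <- function(tr) volume_series_average(
    tr, atom_sel(tr, resno = 67, name = "CA"),
    atom_sel(tr, resno = 92, name = "CA"),
    window = c(1, 5), stride_ns = 1)$mean
  expect_lt(va(closed), va(open))
})
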