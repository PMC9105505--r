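# Interface residue identification and distance heat maps.

two_res_regions <- function(d) {
  s <- toy_structure(c("CA", "CA"), c(1, 101), x = c(0, d), y = 0, z = 0)
  rmap <- structure(list(a = data.frame(chain = "A", start = 1, end = 1),
                         b = data.frame(chain = "A", start = 101, end = 101)),
                    class = "region_map")
  list(s = s, rmap = rmap)
}

test_that("the 5-A threshold is an inclusive boundary", {
  inside <- two_res_regions(4.9)
  got <- interfacial_residues(inside$s, inside$rmap, "a", "b", threshold = 5)
  expect_equal(unname(got["A:1"]), 4.9, tolerance = 1e-10)
  sym <- interfacial_residues(inside$s, inside$rmap, "b", "a", threshold = 5)
  expect_equal(unname(sym["A:101"]), 4.9, tolerance = 1e-10)

  outside <- two_res_regions(5.1)
  expect_length(interfacial_residues(outside$s, outside$rmap, "a", "b",
                                     threshold = 5), 0)
})

test_that("interface scan agrees exactly with the all-pairs brute force", {
  for (seed in 1:6) {
    toy <- random_two_region_toy(seed)
    oracle <- brute_min_dist(toy$s,
                             shp2md:::region_mask(toy$s$atoms, toy$rmap, "a"),
                             shp2md:::region_mask(toy$s$atoms, toy$rmap, "b"))
    for (thr in c(4, 5, 6)) {
      got <- interfacial_residues(toy$s, toy$rmap, "a", "b", threshold = thr)
      want <- oracle[oracle <= thr]
      expect_equal(got[order(names(got))], want[order(names(want))],
                   tolerance = 1e-12)
    }
  }
})

test_that("hydrogens are ignored in interface distances", {
  s <- toy_structure(c("CA", "H", "CA"), c(1, 1, 101),
                     x = c(0, 4, 6), y = 0, z = 0,
                     element = c("C", "H", "C"))
  rmap <- structure(list(a = data.frame(chain = "A", start = 1, end = 1),
                         b = data.frame(chain = "A", start = 101, end = 101)),
                    class = "region_map")
  got <- interfacial_residues(s, rmap, "a", "b", threshold = 7)
  expect_equal(unname(got["A:1"]), 6)  # not the 2-A H..CA contact
})

test_that("linker exclusions drop residues from the interface scan", {
  s <- toy_structure(c("CA", "CA", "CA"), c(1, 2, 101),
                     x = c(0, 1, 4.5), y = 0, z = 0)
  rmap <- structure(list(a = data.frame(chain = "A", start = 1, end = 2),
                         b = data.frame(chain = "A", start = 101, end = 101)),
                    class = "region_map")
  all_in <- interfacial_residues(s, rmap, "a", "b", threshold = 5)
  expect_setequal(names(all_in), c("A:1", "A:2"))
  ex <- interfacial_residues(s, rmap, "a", "b", threshold = 5,
                             exclude = data.frame(chain = "A", resno = 2))
  expect_setequal(names(ex), "A:1")
  expect_error(interfacial_residues(s, rmap, "a", "b",
                                    exclude = data.frame(chain = "A",
                                                         resno = 1:2)),
               "empty region")
})

test_that("heat map columns track a separating two-domain trajectory", {
  gaps <- seq(4, 12, by = 1)
  tr <- two_domain_trajectory(gaps)
  rmap <- attr(tr, "region_map")
  im <- interface_heatmap(tr, rmap, "domA", "domB", threshold = 5, cap = 10)
  expect_s3_class(im, "interface_map")
  # the facing residues' min distance equals the planted gap, increasing
  face <- im[which.min(im[, 1]), ]
  expect_equal(unname(face[1:7]), gaps[1:7], tolerance = 1e-9)
  expect_true(all(diff(stats::na.omit(unname(face))) > 0))
  # beyond the cap the cell is absent
  expect_true(anyNA(face))
  expect_true(all(is.na(face[gaps > 10])))
})

test_that("identical frames give identical heat map columns; reference occupies column 0", {
  tr <- two_domain_trajectory(rep(4.5, 3))
  rmap <- attr(tr, "region_map")
  ref <- make_two_domain_complex(3.9)
  im <- interface_heatmap(tr, rmap, "domA", "domB", reference = ref)
  expect_equal(attr(im, "times")[1], 0)
  expect_equal(ncol(im), 4)
  expect_equal(im[, 2], im[, 3])
  expect_equal(im[, 3], im[, 4])
  expect_equal(min(im[, 1], na.rm = TRUE), 3.9, tolerance = 1e-9)
})

test_that("row sets are nested in the threshold", {
  for (seed in 1:10) {
    toy <- random_two_region_toy(seed, n = 40)
    r5 <- interfacial_residues(toy$s, toy$rmap, "a", "b", threshold = 5)
    r6 <- interfacial_residues(toy$s, toy$rmap, "a", "b", threshold = 6)
    expect_true(all(names(r5) %in% names(r6)))
  }
})

test_that("global minimum distance is symmetric between the two regions", {
  for (seed in 11:16) {
    toy <- random_two_region_toy(seed, n = 30)
    ra <- interfacial_residues(toy$s, toy$rmap, "a", "b", threshold = Inf)
    rb <- interfacial_residues(toy$s, toy$rmap, "b", "a", threshold = Inf)
    expect_equal(min(ra), min(rb), tolerance = 1e-12)
  }
})

test_that("stable and transient interface residues split at the residence cutoff", {
  # facing residue inside threshold in all frames; another dips in once
  gaps <- c(4.5, 4.5, 4.5, 8.2)
  tr <- two_domain_trajectory(gaps)
  rmap <- attr(tr, "region_map")
  im <- interface_heatmap(tr, rmap, "domA", "domB", threshold = 5)
  res <- interface_residence(im)
  expect_true(all(res$class %in% c("stable", "transient")))
  face <- res[which.max(res$occupancy), ]
  expect_equal(face$occupancy, 0.75)
  expect_equal(face$class, "stable")
})

test_that("surface distance colouring stores capped distances in B-factors", {
  s <- toy_structure(c("CA", "CA", "CA"), c(1, 101, 102),
                     x = c(0, 0, 30), y = 0, z = 0)
  rmap <- structure(list(a = data.frame(chain = "A", start = 1, end = 1),
                         b = data.frame(chain = "A", start = 101, end = 102)),
                    class = "region_map")
  ann <- surface_distance_coloring(s, rmap, "b", "a", cap = 10)
  expect_equal(ann$atoms$bfac, c(0, 10))
  # agreement with brute force on a random toy
  toy <- random_two_region_toy(99, n = 30)
  ann2 <- surface_distance_coloring(toy$s, toy$rmap, "a", "b", cap = 50)
  sel_a <- shp2md:::region_mask(toy$s$atoms, toy$rmap, "a")
  sel_b <- shp2md:::region_mask(toy$s$atoms, toy$rmap, "b") &
    toy$s$atoms$is_heavy
  xyz <- coords(toy$s)
  for (i in seq_len(nrow(ann2$atoms))) {
    ai <- which(sel_a)[i]
    want <- min(sqrt(colSums((t(xyz[sel_b, , drop = FALSE]) - xyz[ai, ])^2)))
    expect_equal(ann2$atoms$bfac[i], want, tolerance = 1e-12)
  }
})

test_that("heat maps export as tab-separated matrices", {
  tr <- two_domain_trajectory(c(4.5, 5.5))
  rmap <- attr(tr, "region_map")
  im <- interface_heatmap(tr, rmap, "domA", "domB")
  f <- tempfile(fileext = ".tsv")
  write_interface_map(im, f)
  back <- utils::read.delim(f, check.names = FALSE)
  expect_equal(nrow(back), nrow(im))
  expect_equal(back$residue, rownames(im))
})
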