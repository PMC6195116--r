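test_that("geometry validation rejects impossible parameters", {
  expect_error(backbone_geometry(b_n_ca = 0), "positive")
  expect_error(backbone_geometry(a_n_ca_c = 180), "between 0 and 180")
  expect_error(build_backbone(matrix(1, 2, 3)), "phi, psi")
  expect_error(build_backbone(matrix(c(NA, 10, 10, 10, NA, NA), 3, 2)),
               "interior")
})

test_that("built chains have ideal internal coordinates and recover torsions", {
  g <- backbone_geometry()
  ch <- build_backbone(matrix(c(-57, -47), 10, 2, byrow = TRUE), g)
  expect_identical(nrow(ch), 30L)
  xyz <- as.matrix(ch[, c("x", "y", "z")])
  # bond lengths alternate N-CA, CA-C, C-N
  bonds <- unname(sqrt(rowSums(diff(xyz)^2)))
  expect_equal(bonds, rep(c(g$b_n_ca, g$b_ca_c, g$b_c_n), 10)[-30L],
               tolerance = 1e-9)
  # torsions recovered exactly (before any PDB rounding)
  phi <- sapply(2:10, function(i) {
    k <- 3 * (i - 1)
    dihedral_angle(xyz[k, ], xyz[k + 1, ], xyz[k + 2, ], xyz[k + 3, ])
  })
  expect_equal(phi, rep(-57, 9), tolerance = 1e-9)
  # two residues: a valid 6-atom chain
  expect_identical(nrow(build_backbone(matrix(c(NA, -40, 130, NA), 2, 2))), 6L)
})

test_that("global size metrics behave on analytic cases", {
  one <- build_backbone(matrix(c(NA, NA), 1, 2))
  expect_equal(radius_of_gyration(one[1:1, , drop = FALSE]), 0)
  # two atoms 2 A apart -> rg = 1 (half the separation)
  toy <- one[1:2, ]
  toy$x <- c(0, 2); toy$y <- toy$z <- c(0, 0)
  class(toy) <- class(one); attr(toy, "chain_id") <- "A"
  expect_equal(radius_of_gyration(toy), 1)
  # straight colinear 3-atom toy at 1 A spacing: end-to-end 2
  tri <- one[c(1, 1, 1), ]
  tri$x <- 0:2; tri$y <- tri$z <- 0
  class(tri) <- class(one); attr(tri, "chain_id") <- "A"
  expect_equal(end_to_end_distance(tri), 2)

  helix <- build_backbone(matrix(c(-57, -47), 10, 2, byrow = TRUE))
  ext <- build_backbone(matrix(c(180, 180), 10, 2, byrow = TRUE))
  expect_lt(radius_of_gyration(helix), radius_of_gyration(ext))
  expect_lt(end_to_end_distance(helix), end_to_end_distance(ext))
})

test_that("the handedness proxy is zero for planar chains and mirror-odd", {
  ext <- build_backbone(matrix(c(180, 180), 10, 2, byrow = TRUE))
  expect_equal(chirality_proxy(ext), 0, tolerance = 1e-12)
  helix <- build_backbone(matrix(c(-57, -47), 10, 2, byrow = TRUE))
  mirror <- build_backbone(matrix(c(57, 47), 10, 2, byrow = TRUE))
  expect_equal(chirality_proxy(helix), -chirality_proxy(mirror))
  expect_gt(abs(chirality_proxy(helix)), 0.5)
  expect_true(abs(chirality_proxy(helix)) <= 1)
  # fixed sign convention: the right-handed alpha helix is positive
  expect_gt(chirality_proxy(helix), 0)
  short <- build_backbone(matrix(c(NA, -40, -60, -40, -60, NA), 3, 2))
  expect_true(is.na(chirality_proxy(short)))
})

test_that("binned trends at coarse resolution conserve counts and orderings", {
  tr <- rnumber_binned_trends(step = 30, bin_width = 0.05)
  expect_identical(sum(tr$n), 13L * 13L)   # every grid point in one bin
  expect_true(all(tr$rg_mean > 0 & tr$re_mean >= 0))
  expect_true(all(abs(tr$chi_mean) <= 1))
  expect_true(all(diff(tr$bin_lo) > 0))
  # mirror antisymmetry across R = 0.5: every grid point (phi, psi) has its
  # mirror (-phi, -psi) in the grid, so the count-weighted total vanishes
  expect_equal(sum(tr$chi_mean * tr$n), 0, tolerance = 1e-9)
})

test_that("PDB writing round-trips and frames map to MODEL records", {
  set.seed(33)
  frames <- lapply(1:2, function(i)
    build_backbone(cbind(runif(5, -180, 180), runif(5, -180, 180))))
  txt <- write_pdb(frames)
  expect_identical(lengths(regmatches(txt, gregexpr("MODEL", txt))), 2L)
  mods <- read_pdb_models(txt)
  expect_length(mods, 2L)
  expect_identical(mods[[1L]][["A"]]$resid, 1:5)
  expect_error(write_pdb(list()), "at least one")
})

test_that("trajectory generators are seed-deterministic", {
  a <- make_test_trajectory("disorder", n_res = 8, n_frames = 3, seed = 42)
  b <- make_test_trajectory("disorder", n_res = 8, n_frames = 3, seed = 42)
  c <- make_test_trajectory("disorder", n_res = 8, n_frames = 3, seed = 43)
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("the stable-helix archetype concentrates every frame in one band", {
  tab <- read_ensemble(make_test_trajectory("stable-helix", n_res = 20,
                                            n_frames = 6, seed = 2))
  h <- build_histogram_series(tab, "A")
  helix_band <- which(attr(h, "bin_edges")[-1L] > 0.30 &
                      attr(h, "bin_edges")[-101L] < 0.42)
  expect_true(all(colSums(h[helix_band, ]) > 0.9))
})

test_that("the helix-to-sheet archetype migrates between the two bands", {
  tab <- read_ensemble(make_test_trajectory("helix-to-sheet", n_res = 15,
                                            n_frames = 8, seed = 3))
  h <- build_histogram_series(tab, "A")
  mids <- as.numeric(rownames(h))
  mean_r <- apply(h, 2L, function(p) sum(p * mids))
  expect_lt(mean_r[1L], 0.40)                # starts helical (~0.356)
  expect_gt(mean_r[8L], 0.48)                # ends near the beta locus
  expect_true(all(diff(mean_r) > 0))         # monotone transition
})

test_that("all generated fixtures parse without warnings", {
  for (kind in c("stable-helix", "disorder", "helix-to-sheet",
                 "restrained-release")) {
    expect_no_warning(
      tab <- read_ensemble(make_test_trajectory(kind, n_res = 10,
                                                n_frames = 3, seed = 7)))
    expect_identical(nrow(tab), 30L)
  }
})
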