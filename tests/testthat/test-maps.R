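test_that("residue maps lay the table out as residues x models", {
  tab <- make_table(model = rep(1:3, each = 4), chain = "A",
                    resid = rep(1:4, 3), R = (1:12) / 12)
  m <- build_residue_map(tab, "A")
  expect_identical(dim(m), c(4L, 3L))
  expect_identical(rownames(m), as.character(1:4))
  expect_identical(colnames(m), as.character(1:3))
  # any cell reads back the source record
  expect_equal(m["2", "3"], tab$R[tab$model == "3" & tab$resid == 2])
  expect_equal(unname(m[, 1L]), (1:4) / 12)
  # single-model input gives a single column
  expect_identical(dim(build_residue_map(make_table(1, "A", 1:4, R = 0.3),
                                         "A")), c(4L, 1L))
  expect_error(build_residue_map(tab, "Z"), "available chains: A")
})

test_that("signed maps carry negative cells exactly where psi < phi", {
  phi <- c(-75, 75, -57, 120)
  psi <- c(145, -145, -47, -30)
  tab <- table_from_angles(1, "A", 1:4, phi, psi)
  m <- build_residue_map(tab, "A", signed = TRUE)
  expect_identical(unname(m[, 1L] < 0), psi < phi)
  expect_true(all(m >= -1 & m <= 1))
  expect_equal(abs(unname(m[, 1L])), ramachandran_number(phi, psi))
})

test_that("histogram series are normalized per model on the printed bin grid", {
  # all mass in one bin
  tab <- make_table(1, "A", 1:5, R = 0.345)
  h <- build_histogram_series(tab, "A")
  expect_identical(dim(h), c(100L, 1L))
  expect_equal(unname(h[35L, 1L]), 1)  # bin [0.34, 0.35)
  expect_equal(sum(h), 1)

  # 100 records at bin midpoints -> perfectly flat distribution
  tab2 <- make_table(1, "A", 1:100, R = seq(0.005, 0.995, by = 0.01))
  h2 <- build_histogram_series(tab2, "A")
  expect_equal(unname(h2[, 1L]), rep(0.01, 100))

  # r = 1.0 is counted in the final (closed) bin
  h3 <- build_histogram_series(make_table(1, "A", 1:2, R = c(1, 0)), "A")
  expect_equal(unname(h3[100L, 1L]), 0.5)
  expect_equal(unname(h3[1L, 1L]), 0.5)

  # every model column sums to 1 on an arbitrary fixture
  set.seed(8)
  tab4 <- make_table(rep(1:4, each = 25), "A", rep(1:25, 4), R = runif(100))
  h4 <- build_histogram_series(tab4, "A")
  expect_equal(unname(colSums(h4)), rep(1, 4), tolerance = 1e-9)
  expect_error(build_histogram_series(tab4, "A", bin_width = 0.03), "evenly")
})

test_that("models with no defined R give flagged all-zero histogram columns", {
  tab <- make_table(rep(1:2, each = 3), "A", rep(1:3, 2),
                    R = c(0.2, 0.4, 0.6, NA, NA, NA))
  h <- build_histogram_series(tab, "A")
  expect_equal(sum(h[, 2L]), 0)
  expect_identical(attr(h, "empty_models"), "2")
})

test_that("deviation maps expose jumps in the right frames", {
  # one residue jumps 0.3 -> 0.7 at frame 5 of 8
  r <- c(rep(0.3, 4), rep(0.7, 4))
  tab <- make_table(model = 1:8, chain = "A", resid = 1, R = r)
  prev <- build_deviation_map(tab, "A", "previous")
  expect_equal(unname(prev[1L, ]), c(0, 0, 0, 0, 0.4, 0, 0, 0))
  first <- build_deviation_map(tab, "A", "first")
  expect_equal(unname(first[1L, ]), c(0, 0, 0, 0, 0.4, 0.4, 0.4, 0.4))

  # constant trajectory -> all-zero maps
  const <- make_table(rep(1:3, each = 2), "A", rep(1:2, 3), R = 0.5)
  expect_true(all(build_deviation_map(const, "A", "first") == 0))
  expect_true(all(build_deviation_map(const, "A", "previous") == 0))

  # with exactly two frames the two modes coincide
  two <- make_table(rep(1:2, each = 3), "A", rep(1:3, 2),
                    R = c(0.1, 0.5, 0.9, 0.3, 0.2, 0.4))
  expect_equal(unclass(build_deviation_map(two, "A", "first")),
               unclass(build_deviation_map(two, "A", "previous")),
               ignore_attr = TRUE)

  expect_warning(build_deviation_map(make_table(1, "A", 1:3, R = 0.5), "A"),
                 "single-model")
})

test_that("frame-to-frame deviations are invariant under time reversal", {
  set.seed(21)
  r <- runif(10)
  fwd <- make_table(model = 1:10, chain = "A", resid = 1, R = r)
  rev <- make_table(model = 1:10, chain = "A", resid = 1, R = rev(r))
  d_f <- build_deviation_map(fwd, "A", "previous")
  d_r <- build_deviation_map(rev, "A", "previous")
  expect_equal(sort(unname(d_f[1L, -1L])), sort(unname(d_r[1L, -1L])))
})

test_that("conditioned stacks group by residue type and neighbor context", {
  # three residue types at distinct fixed r -> three point masses
  tab <- make_table(1, "A", 1:9, resname = rep(c("ALA", "GLY", "PRO"), 3),
                    R = rep(c(0.105, 0.505, 0.905), 3))
  st <- build_conditioned_stack(tab, "residue")
  expect_identical(rownames(st), c("ALA", "GLY", "PRO"))
  expect_equal(unname(st["ALA", 11L]), 1)
  expect_equal(unname(st["GLY", 51L]), 1)
  expect_equal(unname(st["PRO", 91L]), 1)
  expect_equal(unname(rowSums(st)), rep(1, 3))

  # single-type table: the one row equals the global histogram
  tab1 <- make_table(1, "A", 1:50, resname = "ALA",
                     R = seq(0.015, 0.985, length.out = 50))
  st1 <- build_conditioned_stack(tab1, "residue")
  h1 <- build_histogram_series(tab1, "A")
  expect_equal(unname(st1["ALA", ]), unname(h1[, 1L]))
})

test_that("the pre-proline context isolates a shift into its own row", {
  # residues sitting before a PRO carry r > 0.5; everything else r < 0.5
  resnames <- rep(c("ALA", "PRO", "LEU", "GLY"), 5)
  r <- ifelse(c(resnames[-1L], "XXX") == "PRO", 0.605, 0.305)
  tab <- make_table(1, "A", 1:20, resname = resnames, R = r)
  st <- build_conditioned_stack(tab, "preceding")
  high_bins <- which(attr(st, "bin_edges")[-1L] > 0.5)
  expect_equal(sum(st["PRO", high_bins]), 1)       # shift shows in row PRO
  for (other in setdiff(rownames(st), "PRO")) {
    if (!other %in% attr(st, "empty_conditions"))
      expect_equal(sum(st[other, high_bins]), 0)
  }

  # "following" is the mirrored context: rows collect residues after a type
  stf <- build_conditioned_stack(tab, "following")
  # residues after a PRO are LEU rows with r < 0.5 unless they precede PRO
  expect_equal(unname(rowSums(stf)[rownames(stf) != "XXX"]),
               rep(1, nrow(stf)))
})

test_that("sequence gaps break neighbor contexts and empty rows are kept", {
  # PRO at resid 10 is not adjacent to resid 8
  tab <- make_table(1, "A", c(8L, 10L), resname = c("ALA", "PRO"),
                    R = c(0.3, 0.6))
  st <- build_conditioned_stack(tab, "preceding")
  expect_true("PRO" %in% attr(st, "empty_conditions"))
  expect_equal(sum(st["PRO", ]), 0)
  expect_true(all(rownames(st) == c("ALA", "PRO")))  # empty row kept
})

test_that("map CSV export is labeled and byte-deterministic", {
  tab <- make_table(rep(1:3, each = 4), "A", rep(1:4, 3), R = (1:12) / 13)
  m <- build_residue_map(tab, "A")
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_map_csv(m, f1); write_map_csv(m, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  got <- utils::read.csv(f1, check.names = FALSE)
  expect_identical(names(got), c("residue", "1", "2", "3"))
  expect_equal(as.numeric(got[2L, -1L]), unname(m[2L, ]))
})
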