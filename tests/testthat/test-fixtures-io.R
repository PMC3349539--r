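test_that("packaged fixtures validate and match their checksums", {
  expect_true(verify_fixtures())
  tab <- ffl_reference_table2()
  expect_equal(dim(tab), c(8, 6))
  expect_equal(tab["C1", "G+"], 0.4862)
  expect_equal(tab["I1", "P+T-"], 0)
  expect_equal(unname(sum(tab["C3", ])), 1, tolerance = 1e-3)
  expect_true(all(abs(rowSums(tab) - 1) <= 1e-3))
})

test_that("probability tables round-trip bit-identically", {
  tab <- ffl_reference_table2()
  tmp <- tempfile(fileext = ".csv")
  write_probability_table(tab, tmp)
  again <- read_probability_table(tmp)
  expect_identical(tab, again)
  write_probability_table(again, tmp)
  expect_identical(again, read_probability_table(tmp))
})

test_that("malformed probability tables are rejected", {
  tmp <- tempfile(fileext = ".csv")
  writeLines(c("motif,a,b", "C1,0.5,0.5"), tmp)
  expect_error(read_probability_table(tmp), "malformed")
  writeLines(c("motif,G+,G-,P+T+,P+T-,P-T-,P-T+",
               "C1,0.9,0.3,0,0,0,0"), tmp)
  expect_error(read_probability_table(tmp), "summing")
})

test_that("reference transition matrices load with printed values intact", {
  single <- suppressWarnings(ffl_reference_transitions("single"))
  acc <- ffl_reference_transitions("accumulated")
  expect_length(single, 8)
  expect_length(acc, 8)
  expect_equal(single$C1["G+", "P+T+"], 0.008)
  expect_equal(unname(single$C1["P-T+", ]), rep(0, 6))
  expect_equal(acc$I1["P+T+", "P+T+"], 0.229)
  totals <- vapply(c(single, acc), sum, numeric(1))
  # all blocks total ~1 as printed, except the C3 single block whose
  # printed entries genuinely total 1.106 in the source table
  expect_true(all(abs(totals[-3] - 1) <= 0.02))
  expect_equal(unname(totals[3]), 1.106, tolerance = 1e-9)
  expect_warning(ffl_reference_transitions("single"), "C3")
})

test_that("transition bundles round-trip through CSV", {
  acc <- ffl_reference_transitions("accumulated")
  tmp <- tempfile(fileext = ".csv")
  write_transition_matrices(acc, tmp)
  expect_identical(acc, read_transition_matrices(tmp))
})

test_that("the synthetic abundance fixture is normalized with C1 and I1 on top", {
  ab <- ffl_reference_abundance()
  for (src in unique(ab$source)) {
    blk <- ab[ab$source == src, ]
    expect_equal(sum(blk$abundance), 1, tolerance = 1e-3)
    top2 <- blk$motif[order(blk$abundance, decreasing = TRUE)][1:2]
    expect_setequal(top2, c("C1", "I1"))
  }
})

test_that("trajectories export as t/Y/Z tables", {
  p <- ffl_params(alpha_x = 5, beta_x = 8, beta_y = 3, beta_xy = 20)
  traj <- ffl_integrate(p, n_grid = 101)
  tmp <- tempfile(fileext = ".csv")
  write_trajectory(traj, tmp)
  df <- read.csv(tmp)
  expect_equal(names(df), c("t", "Y", "Z"))
  expect_equal(nrow(df), 101)
  expect_equal(df$Z[1], traj$z0, tolerance = 1e-6)
})
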