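test_that("kurtosis extremes hit the analytic values", {
  expect_equal(sample_kurtosis(c(1, 0, 0, 0, 0, 0)), 6, tolerance = 1e-12)
  expect_equal(sample_kurtosis(rep(1 / 6, 6)), -10 / 3,
               tolerance = 1e-12)
  cfg <- plasticity_config()
  expect_equal(cfg$k_specialized, 6, tolerance = 1e-12)
  expect_equal(cfg$k_flexible, -10 / 3, tolerance = 1e-12)
  expect_equal(cfg$k0, 4 / 3, tolerance = 1e-12)
  # the flexible value is the limit of a vanishing symmetric perturbation
  eps <- 1e-7
  p <- rep(1 / 6, 6) + eps * c(1, 1, 1, -1, -1, -1)
  expect_equal(sample_kurtosis(p), -10 / 3, tolerance = 1e-6)
})

test_that("kurtosis of reference probability rows matches the reference", {
  tab <- ffl_reference_table2()
  expect_equal(sample_kurtosis(tab["C1", ]), 1.631, tolerance = 0.005)
  expect_equal(sample_kurtosis(tab["C2", ]), 4.142, tolerance = 0.005)
  expect_error(sample_kurtosis(c(0.5, 0.5)), "length 6")
  expect_error(sample_kurtosis(c(0.9, 0.3, -0.2, 0, 0, 0)), "nonnegative")
})

test_that("entropy extremes and direct evaluation agree", {
  expect_identical(shannon_entropy(c(1, 0, 0, 0, 0, 0)), 0)
  expect_equal(shannon_entropy(rep(1 / 6, 6)), log2(6), tolerance = 1e-12)
  p <- ffl_reference_table2()["I1", ]
  manual <- -sum(vapply(p[p > 0], function(q) q * log(q) / log(2),
                        numeric(1)))
  expect_equal(shannon_entropy(p), manual, tolerance = 1e-12)
})

test_that("plasticity and predicted abundance follow their definitions", {
  cfg <- plasticity_config()
  expect_equal(psi_score(cfg$k0, cfg), 0)
  tab <- ffl_reference_table2()
  expect_equal(psi_score(sample_kurtosis(tab["C4", ]), cfg), 3.501,
               tolerance = 0.005)
  expect_equal(psi_score(sample_kurtosis(tab["C3", ]), cfg), 1.707,
               tolerance = 0.005)
  expect_equal(unname(rho_score(rep(2, 8))), rep(1 / 8, 8))
  expect_error(rho_score(c(1, -1, 2)), "positive")
  # scale freedom: rho depends only on relative plasticity
  psis <- c(0.3, 1.2, 2.5, 0.7)
  expect_equal(rho_score(psis), rho_score(10 * psis), tolerance = 1e-12)
})

test_that("the full score table reproduces the reference values", {
  scores <- score_table(ffl_reference_table2())
  ref <- ffl_reference_table1()
  expect_equal(scores$motif, ref$motif)
  expect_equal(scores$kurtosis, ref$kurtosis, tolerance = 0.005)
  expect_equal(scores$psi, ref$psi, tolerance = 0.005)
  expect_equal(scores$rho, ref$rho, tolerance = 0.005)
  expect_equal(sum(scores$rho), 1, tolerance = 1e-6)
  expect_true(all(scores$entropy_bits >= 0 &
                    scores$entropy_bits <= log2(6)))
})

test_that("kurtosis of any probability vector stays within the extremes", {
  set.seed(5)
  for (i in 1:10000) {
    g <- rgamma(6, shape = exp(runif(1, -2, 2)))
    p <- g / sum(g)
    k <- sample_kurtosis(p)
    expect_gte(k, -10 / 3 - 1e-9)
    expect_lte(k, 6 + 1e-9)
  }
})

test_that("kurtosis and entropy order the extremes oppositely", {
  onehot <- c(1, 0, 0, 0, 0, 0)
  unif <- rep(1 / 6, 6)
  set.seed(8)
  tab <- random_probability_table(seed = 8, concentration = 1)
  ks <- apply(tab, 1, sample_kurtosis)
  hs <- apply(tab, 1, shannon_entropy)
  expect_true(all(ks <= sample_kurtosis(onehot)))
  expect_true(all(ks >= sample_kurtosis(unif)))
  expect_true(all(hs >= shannon_entropy(onehot)))
  expect_true(all(hs <= shannon_entropy(unif)))
})
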