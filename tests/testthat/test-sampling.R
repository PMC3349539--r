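test_that("parameter sampling is reproducible and sign-consistent", {
  a <- sample_parameters("C1", 5, seed = 123)
  b <- sample_parameters("C1", 5, seed = 123)
  expect_identical(a, b)
  for (p in sample_parameters("C1", 50, seed = 1)) {
    expect_true(p$alpha_x > 1 && p$beta_x > 1 && p$beta_y > 1 &&
                  p$beta_xy > 1)
  }
  for (p in sample_parameters("I1", 50, seed = 2)) {
    expect_true(p$alpha_x > 1)   # X -> Y activation
    expect_true(p$beta_x > 1)    # direct X -> Z activation
    expect_true(p$beta_y < 1)    # Y -| Z inhibition
    expect_true(p$beta_xy < 1)   # joint sign = product of edge signs
  }
})

test_that("sampled values respect the prior ranges", {
  prior <- ffl_prior(f_max = 10, rate_range = c(0.1, 10),
                     omega_range = c(0.5, 2), x_active_range = c(1, 3),
                     nm_max = 3)
  sets <- sample_parameters("C2", 500, seed = 9, prior = prior)
  vals <- do.call(rbind, lapply(sets, function(p) as.data.frame(p)))
  expect_true(all(vals$gamma_y >= 0.1 & vals$gamma_y <= 10))
  expect_true(all(vals$delta_z >= 0.1 & vals$delta_z <= 10))
  expect_true(all(vals$omega_zxy >= 0.5 & vals$omega_zxy <= 2))
  expect_true(all(vals$x_active >= 1 & vals$x_active <= 3))
  expect_true(all(vals$n %in% 1:3 & vals$m %in% 1:3))
  expect_true(all(vals$alpha_x < 1 & vals$alpha_x >= 0.1))  # C2: X -| Y
  expect_error(ffl_prior(f_max = 0.5), "f_max")
  expect_error(ffl_prior(rate_range = c(5, 1)), "ranges")
})

test_that("a mutation changes exactly one parameter and keeps signs", {
  set.seed(31)
  p <- sample_parameters("C1", 1)[[1]]
  for (i in 1:200) {
    q <- mutate_params(p)
    diffs <- vapply(names(p), function(f) !identical(p[[f]], q[[f]]),
                    logical(1))
    expect_lte(sum(diffs), 1)
    expect_equal(sum(diffs), 1)
    expect_true(check_signs(q, "C1"))
    expect_true(q$n %in% 1:4 && q$m %in% 1:4)
    expect_identical(q$x_active, p$x_active)  # input is not mutable
  }
})

test_that("parameter choice under mutation is uniform over mutable fields", {
  set.seed(57)
  p <- sample_parameters("C1", 1)[[1]]
  fields <- setdiff(names(p), "x_active")
  picks <- character(10000)
  for (i in seq_along(picks)) {
    q <- mutate_params(p)
    picks[i] <- fields[vapply(fields, function(f)
      !identical(p[[f]], q[[f]]), logical(1))]
  }
  counts <- table(factor(picks, levels = fields))
  expect_equal(length(counts), 14)
  expect_gt(stats::chisq.test(counts)$p.value, 1e-4)
})

test_that("a zero-width kernel leaves the circuit untouched", {
  set.seed(3)
  p <- sample_parameters("I4", 1)[[1]]
  for (i in 1:20) {
    expect_identical(unclass(mutate_params(p, kernel_scale = 0)),
                     unclass(p))
  }
})
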