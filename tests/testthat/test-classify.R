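flat_traj <- function(z0 = 1, n = 100) {
  structure(list(t = seq(0, 10, length.out = n), z = rep(z0, n),
                 z0 = z0, z_inf = z0), class = "ffl_trajectory")
}

test_that("constant and monotone trajectories classify as expected", {
  expect_equal(classify_trajectory(flat_traj()), "no-response")
  up <- toy_trajectory("G+", z0 = 1, z_inf = 2)
  dn <- toy_trajectory("G-", z0 = 2, z_inf = 1)
  expect_equal(classify_trajectory(up), "G+")
  expect_equal(classify_trajectory(dn), "G-")
})

test_that("an overshooting adaptive pulse is P+T-", {
  # rise to 3x the pre-input level, settle below it
  traj <- toy_trajectory("P+T-", z0 = 1, z_inf = 0.5, pulse_height = 2.5)
  expect_equal(max(traj$z) > 3, TRUE)
  expect_equal(classify_trajectory(traj), "P+T-")
  expect_equal(oracle_classify(traj), "P+T-")
})

test_that("initial slope sign follows the first band departure", {
  lin <- flat_traj()
  lin$z <- seq(1, 2, length.out = 100)
  lin$z_inf <- 2
  expect_equal(initial_slope_sign(lin), "+")
  dip <- toy_trajectory("P-T+", z0 = 1, z_inf = 2, pulse_height = 0.6)
  expect_equal(initial_slope_sign(dip), "-")
  expect_equal(classify_trajectory(dip), "P-T+")
  expect_true(is.na(initial_slope_sign(flat_traj())))
})

test_that("classification is invariant to concentration and time rescaling", {
  set.seed(91)
  for (i in 1:50) {
    case <- random_toy_case()
    if (is.null(case)) next
    cls <- classify_trajectory(case$traj)
    scaled <- case$traj
    c1 <- exp(runif(1, -3, 3))
    scaled$z <- scaled$z * c1
    scaled$z0 <- scaled$z0 * c1
    scaled$z_inf <- scaled$z_inf * c1
    scaled$t <- scaled$t * exp(runif(1, -2, 2))
    expect_equal(classify_trajectory(scaled), cls)
  }
})

test_that("every trajectory yields exactly one of the seven outcomes", {
  set.seed(17)
  allowed <- c(ffl_classes(), "no-response", "ambiguous")
  for (i in 1:100) {
    case <- random_toy_case()
    if (is.null(case)) next
    out <- classify_trajectory(case$traj)
    expect_length(out, 1)
    expect_true(out %in% allowed)
  }
})

test_that("classifier, oracle and generator ground truth agree", {
  set.seed(29)
  n_checked <- 0
  while (n_checked < 300) {
    case <- random_toy_case()
    if (is.null(case)) next
    n_checked <- n_checked + 1
    expect_equal(classify_trajectory(case$traj), case$shape)
    expect_equal(oracle_classify(case$traj), case$shape)
  }
})

test_that("perfect adaptation takes the target from the strict side of z0", {
  # large pulse, z_inf just inside the band but strictly below z0
  t <- seq(0, 10, length.out = 1000)
  z0 <- 1
  z_inf <- z0 * (1 - 0.005)  # inside the 1% band
  z <- z_inf + (z0 - z_inf) * exp(-3 * t) + 2 * t * exp(-4 * t)
  traj <- structure(list(t = t, z = z, z0 = z0, z_inf = z_inf),
                    class = "ffl_trajectory")
  expect_equal(classify_trajectory(traj), "P+T-")
})
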