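test_that("derivative reduces to basal production without regulation", {
  p <- ffl_params(gamma_y = 2, gamma_z = 3, omega_yx = 0, omega_zx = 0,
                  omega_zy = 0, omega_zxy = 0)
  expect_equal(ffl_derivative(0, 0, 0, p), c(2, 3))
  # steady state by construction: dY = dZ = 0
  expect_equal(ffl_derivative(2 / p$delta_y, 3 / p$delta_z, 0, p),
               c(0, 0))
  expect_error(ffl_derivative(NaN, 0, 0, p), "non-finite")
})

test_that("derivative matches an independently coded occupancy formula", {
  set.seed(42)
  for (i in 1:25) {
    p <- sample_parameters(sample(ffl_motif_ids(), 1), 1)[[1]]
    y <- runif(1, 0, 10); z <- runif(1, 0, 10); x <- runif(1, 0, 5)
    # independent arrangement: occupancy-weighted average of fold-changes
    wy <- c(1, p$omega_yx * x^p$n)
    fy <- c(1, p$alpha_x)
    wz <- c(1, p$omega_zx * x^p$n, p$omega_zy * y^p$m,
            p$omega_zxy * x^p$n * y^p$m)
    fz <- c(1, p$beta_x, p$beta_y, p$beta_xy)
    expected <- c(p$gamma_y * weighted.mean(fy, wy) - p$delta_y * y,
                  p$gamma_z * weighted.mean(fz, wz) - p$delta_z * z)
    expect_equal(ffl_derivative(y, z, x, p), expected, tolerance = 1e-12)
  }
})

test_that("compiled solver right-hand side agrees with the R formula", {
  set.seed(7)
  p <- sample_parameters("I2", 1)[[1]]
  state <- c(Y = 0.7, Z = 2.3)
  h <- 1e-8
  out <- deSolve::ode(state, c(0, h), func = "ffl_derivs",
                      parms = as.numeric(unlist(p)),
                      dllname = "fflscape", initfunc = "ffl_initmod")
  fd <- (out[2, c("Y", "Z")] - state) / h
  expect_equal(unname(fd),
               ffl_derivative(0.7, 2.3, p$x_active, p),
               tolerance = 1e-5)
})

test_that("input-off steady state matches the closed form", {
  set.seed(1)
  for (id in c("C1", "C4", "I1", "I3")) {
    p <- sample_parameters(id, 1)[[1]]
    s <- ffl_steady_state(p, input_on = FALSE)
    expect_equal(s$y, p$gamma_y / p$delta_y, tolerance = 1e-12)
    expect_equal(max(abs(ffl_derivative(s$y, s$z, 0, p))), 0,
                 tolerance = 1e-12)
  }
  p0 <- ffl_params(gamma_y = 4, gamma_z = 6, delta_y = 2, delta_z = 3,
                   omega_yx = 0, omega_zx = 0, omega_zy = 0,
                   omega_zxy = 0)
  s0 <- ffl_steady_state(p0)
  expect_equal(c(s0$y, s0$z), c(2, 2))
})

test_that("trajectories relax to the input-on fixed point", {
  set.seed(11)
  n_ok <- 0L
  for (i in 1:40) {
    p <- sample_parameters(sample(ffl_motif_ids(), 1), 1)[[1]]
    traj <- ffl_integrate(p)
    rel_err <- abs(traj$z[length(traj$z)] - traj$z_inf) /
      max(traj$z_inf, 1e-12)
    if (rel_err < 1e-5) n_ok <- n_ok + 1L
  }
  expect_gte(n_ok, 40 * 0.99)
})

test_that("trajectories stay nonnegative and bounded", {
  set.seed(23)
  for (i in 1:30) {
    p <- sample_parameters(sample(ffl_motif_ids(), 1), 1)[[1]]
    traj <- ffl_integrate(p)
    expect_gte(min(traj$z), -1e-8)
    expect_gte(min(traj$y), -1e-8)
    z_cap <- max(traj$z0,
                 p$gamma_z * max(1, p$beta_x, p$beta_y, p$beta_xy) /
                   p$delta_z)
    expect_lte(max(traj$z), z_cap * (1 + 1e-6))
  }
})

test_that("degenerate circuits produce flat responses", {
  # no input: trajectory pinned to the input-off steady state
  p_off <- ffl_params(alpha_x = 5, beta_x = 8, beta_y = 3, beta_xy = 20,
                      x_active = 0)
  traj <- ffl_integrate(p_off)
  expect_lt(max(abs(traj$z - traj$z0)), 1e-8)
  expect_equal(classify_trajectory(traj), "no-response")
  # no binding: the input is invisible to Z
  p_nob <- ffl_params(omega_yx = 0, omega_zx = 0, omega_zy = 0,
                      omega_zxy = 0, alpha_x = 50, beta_x = 50,
                      beta_y = 50, beta_xy = 50)
  traj2 <- ffl_integrate(p_nob)
  expect_lt(max(abs(traj2$z - traj2$z0)), 1e-8)
})

test_that("a strong-activation circuit rises monotonically to its target", {
  p <- ffl_params(alpha_x = 20, beta_x = 20, beta_y = 20, beta_xy = 400,
                  omega_yx = 1, omega_zx = 1, omega_zy = 1, omega_zxy = 1)
  traj <- ffl_integrate(p)
  fine <- ffl_integrate(p, n_grid = 20001, rtol = 1e-10, atol = 1e-12)
  expect_gt(traj$z_inf, traj$z0)
  expect_true(all(diff(traj$z) > -1e-9))
  expect_equal(classify_trajectory(traj), "G+")
  # agrees with a fine-grid reference integration on the common grid
  idx <- seq(1, 20001, by = 10)
  expect_equal(fine$z[idx], traj$z, tolerance = 1e-6)
})
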