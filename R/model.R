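#' Right-hand side of the FFL gene-circuit model
#'
#' Two coupled rate equations describe the concentrations of the
#' intermediate Y and the output Z. Production of each protein is a
#' basal rate modulated by the thermodynamic occupancy of its promoter:
#'
#' \deqn{dY/dt = \gamma_Y \frac{1 + \alpha^x \omega_{yx} X^n}
#'   {1 + \omega_{yx} X^n} - \delta_y Y}
#' \deqn{dZ/dt = \gamma_Z \frac{1 + \beta^x \omega_{zx} X^n +
#'   \beta^y \omega_{zy} Y^m + \beta^{xy} \omega_{zxy} X^n Y^m}
#'   {1 + \omega_{zx} X^n + \omega_{zy} Y^m + \omega_{zxy} X^n Y^m}
#'   - \delta_z Z}
#'
#' X is the externally controlled input: 0 before input onset and
#' `x_active` afterwards; it is not itself a dynamical variable.
#'
#' @param y,z Current concentrations of Y and Z (nonnegative).
#' @param x Current concentration of active X.
#' @param params An [ffl_params()] object.
#' @return Numeric vector `c(dY, dZ)`.
#' @examples
#' p <- ffl_params()
#' ffl_derivative(0, 0, 0, p)  # basal production only
#' @export
ffl_derivative <- function(y, z, x, params) {
  if (!all(is.finite(c(y, z, x)))) {
    stop("non-finite state components", call. = FALSE)
  }
  p <- params
  xn <- x^p$n
  ym <- y^p$m
  dy <- p$gamma_y * (1 + p$alpha_x * p$omega_yx * xn) /
    (1 + p$omega_yx * xn) - p$delta_y * y
  dz <- p$gamma_z *
    (1 + p$beta_x * p$omega_zx * xn + p$beta_y * p$omega_zy * ym +
       p$beta_xy * p$omega_zxy * xn * ym) /
    (1 + p$omega_zx * xn + p$omega_zy * ym + p$omega_zxy * xn * ym) -
    p$delta_z * z
  c(dy, dz)
}

#' Steady state of the circuit
#'
#' The circuit is strictly feed-forward: Y relaxes towards a level set
#' only by X, and Z towards a level set by X and Y. The fixed point is
#' therefore unique and available in closed form for any constant input:
#' Y* is the promoter-occupancy production rate over `delta_y`, and Z* the
#' corresponding expression with Y = Y*. With the input off (X = 0) this
#' reduces to Y* = gamma_y / delta_y.
#'
#' @param params An [ffl_params()] object.
#' @param input_on If `TRUE`, X = `x_active`; otherwise X = 0.
#' @param tol Residual tolerance used for the internal consistency check.
#' @return A list of class `"ffl_state"` with fields `x`, `y`, `z`.
#' @examples
#' p <- ffl_params()
#' ffl_steady_state(p, input_on = FALSE)
#' @export
ffl_steady_state <- function(params, input_on = FALSE, tol = 1e-9) {
  p <- params
  x <- if (input_on) p$x_active else 0
  xn <- x^p$n
  y <- p$gamma_y * (1 + p$alpha_x * p$omega_yx * xn) /
    ((1 + p$omega_yx * xn) * p$delta_y)
  ym <- y^p$m
  z <- p$gamma_z *
    (1 + p$beta_x * p$omega_zx * xn + p$beta_y * p$omega_zy * ym +
       p$beta_xy * p$omega_zxy * xn * ym) /
    ((1 + p$omega_zx * xn + p$omega_zy * ym + p$omega_zxy * xn * ym) *
       p$delta_z)
  res <- ffl_derivative(y, z, x, p)
  scale <- max(abs(c(y, z)), 1)
  if (max(abs(res)) / scale > tol) {
    stop("steady-state residual ", format(max(abs(res))),
         " exceeds tolerance ", tol, call. = FALSE)
  }
  structure(list(x = x, y = y, z = z), class = "ffl_state")
}

#' Integrate the response to input onset
#'
#' Starts from the input-off steady state, switches X to `x_active` at
#' t = 0 and integrates Y(t), Z(t) on a dense uniform grid. The default
#' horizon is `t_factor` times the slowest relaxation time
#' `max(1/delta_y, 1/delta_z)`, after which the trajectory has converged
#' to the input-on steady state at default tolerances.
#'
#' @param params An [ffl_params()] object.
#' @param t_max Integration horizon; computed from `t_factor` if `NULL`.
#' @param t_factor Horizon in units of the slowest relaxation time.
#' @param n_grid Number of output grid points (dense output bounds the
#'   error of extremum detection during classification).
#' @param rtol,atol Relative/absolute solver tolerances.
#' @return A list of class `"ffl_trajectory"` with fields `t`, `y`, `z`
#'   (vectors on the grid), `z0` (pre-input steady-state Z) and `z_inf`
#'   (post-input steady-state Z).
#' @examples
#' p <- ffl_params(alpha_x = 5, beta_x = 8, beta_y = 3, beta_xy = 20)
#' traj <- ffl_integrate(p)
#' @export
ffl_integrate <- function(params, t_max = NULL, t_factor = 20,
                          n_grid = 2001, rtol = 1e-8, atol = 1e-10) {
  p <- params
  if (is.null(t_max)) t_max <- t_factor * max(1 / p$delta_y, 1 / p$delta_z)
  s0 <- ffl_steady_state(p, input_on = FALSE)
  s1 <- ffl_steady_state(p, input_on = TRUE)
  times <- seq(0, t_max, length.out = n_grid)
  parms <- as.numeric(unlist(p))  # field order fixed by ffl_params()
  out <- try(deSolve::ode(y = c(Y = s0$y, Z = s0$z), times = times,
                          func = "ffl_derivs", parms = parms,
                          dllname = "fflscape", initfunc = "ffl_initmod",
                          method = "lsoda",
                          rtol = rtol, atol = atol), silent = TRUE)
  if (inherits(out, "try-error") || nrow(out) < n_grid ||
      any(!is.finite(out[, "Z"]))) {
    stop("stiff-integration failure for parameter set: ",
         paste(sprintf("%s=%.4g", names(p), unlist(p)), collapse = ", "),
         call. = FALSE)
  }
  structure(list(t = out[, "time"], y = out[, "Y"], z = out[, "Z"],
                 z0 = s0$z, z_inf = s1$z),
            class = "ffl_trajectory")
}

#' @export
print.ffl_trajectory <- function(x, ...) {
  cat(sprintf(
    "FFL trajectory: %d points on [0, %.3g], Z0 = %.4g, Zinf = %.4g\n",
    length(x$t), max(x$t), x$z0, x$z_inf))
  invisible(x)
}
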