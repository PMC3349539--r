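#' Circuit parameter set
#'
#' Bundles all rate and regulation constants of the two-equation FFL model
#' for one circuit instance. Regulation factors (`alpha_x` for the effect
#' of X on gene Y; `beta_x`, `beta_y`, `beta_xy` for the effects of X, Y
#' and their joint binding on gene Z) are fold-changes relative to basal
#' transcription: values > 1 encode activation, values in (0, 1)
#' inhibition.
#'
#' @param gamma_y,gamma_z Basal production rates of Y and Z
#'   (concentration/time).
#' @param omega_yx,omega_zx,omega_zy,omega_zxy Binding-equilibrium
#'   constants of the regulator-promoter interactions.
#' @param alpha_x Regulation factor of active X on gene Y.
#' @param beta_x,beta_y,beta_xy Regulation factors of X, Y and joint X+Y
#'   binding on gene Z.
#' @param delta_y,delta_z First-order degradation rates (1/time).
#' @param n,m Multimerization degrees of X and Y (positive integers).
#' @param x_active Concentration of active X once the input is present.
#' @return A list of class `"ffl_params"`.
#' @examples
#' p <- ffl_params(alpha_x = 5, beta_x = 8, beta_y = 3, beta_xy = 20)
#' @export
ffl_params <- function(gamma_y = 1, gamma_z = 1,
                       omega_yx = 1, omega_zx = 1, omega_zy = 1,
                       omega_zxy = 1,
                       alpha_x = 2, beta_x = 2, beta_y = 2, beta_xy = 4,
                       delta_y = 1, delta_z = 1,
                       n = 1L, m = 1L, x_active = 1) {
  p <- list(gamma_y = gamma_y, gamma_z = gamma_z,
            omega_yx = omega_yx, omega_zx = omega_zx,
            omega_zy = omega_zy, omega_zxy = omega_zxy,
            alpha_x = alpha_x, beta_x = beta_x, beta_y = beta_y,
            beta_xy = beta_xy,
            delta_y = delta_y, delta_z = delta_z,
            n = as.integer(n), m = as.integer(m), x_active = x_active)
  validate_ffl_params(p)
  structure(p, class = "ffl_params")
}

validate_ffl_params <- function(p) {
  pos <- unlist(p[c("gamma_y", "gamma_z", "alpha_x", "beta_x", "beta_y",
                    "beta_xy", "delta_y", "delta_z")])
  # omegas and x_active may be 0: no binding / no input are legitimate
  # degenerate circuits (the response is then flat)
  nonneg <- unlist(p[c("omega_yx", "omega_zx", "omega_zy", "omega_zxy",
                       "x_active")])
  if (any(!is.finite(c(pos, nonneg))) || any(pos <= 0) || any(nonneg < 0)) {
    stop("rates and regulation factors must be finite and strictly ",
         "positive; binding constants and x_active nonnegative",
         call. = FALSE)
  }
  if (p$n < 1L || p$m < 1L) {
    stop("multimerization degrees n and m must be >= 1", call. = FALSE)
  }
  invisible(p)
}

#' Check sign consistency of a parameter set with a topology
#'
#' A parameter set realizes a given topology when each regulation factor
#' lies on the side of 1 that matches the corresponding edge sign:
#' `alpha_x` for X->Y, `beta_x` for X->Z, `beta_y` for Y->Z. The joint
#' factor `beta_xy` is constrained to the product of the X->Z and Y->Z
#' sides (coherent joint regulation).
#'
#' @param params An [ffl_params()] object.
#' @param motif A motif id or [ffl_motif()] object.
#' @return `TRUE` invisibly; stops with a descriptive error otherwise.
#' @export
check_signs <- function(params, motif) {
  motif <- ffl_motif(motif)
  side <- function(v) if (v > 1) +1 else if (v < 1) -1 else 0
  checks <- c(
    alpha_x = side(params$alpha_x) == motif$sign_xy,
    beta_x  = side(params$beta_x)  == motif$sign_xz,
    beta_y  = side(params$beta_y)  == motif$sign_yz,
    beta_xy = side(params$beta_xy) == motif$sign_xz * motif$sign_yz
  )
  if (!all(checks)) {
    stop("parameter set is not sign-consistent with motif ", motif$motif,
         ": ", paste(names(checks)[!checks], collapse = ", "),
         " on the wrong side of 1", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.ffl_params <- function(x, ...) {
  cat("FFL parameter set:\n")
  v <- unlist(x)
  print(round(v, 4))
  invisible(x)
}

#' @export
as.data.frame.ffl_params <- function(x, ...) {
  as.data.frame(unclass(x), ...)
}
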