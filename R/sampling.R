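#' Prior over circuit parameters
#'
#' Configures the ranges from which Monte-Carlo parameter sets are drawn.
#' Rates, binding constants and the input strength are log-uniform over
#' their ranges; regulation factors are log-uniform over `[1, f_max]`
#' (activation) or `[1/f_max, 1]` (inhibition); multimerization degrees
#' are uniform on `{1, ..., nm_max}`.
#'
#' @param f_max Maximal fold-change of a regulation factor (> 1).
#' @param rate_range Range of basal production and degradation rates.
#' @param omega_range Range of binding-equilibrium constants.
#' @param x_active_range Range of the active-input concentration.
#' @param nm_max Maximal multimerization degree.
#' @return A list of class `"ffl_prior"`.
#' @export
ffl_prior <- function(f_max = 50, rate_range = c(0.01, 100),
                      omega_range = c(0.01, 100),
                      x_active_range = c(0.1, 10), nm_max = 4L) {
  ok_range <- function(r) length(r) == 2 && all(r > 0) && r[1] < r[2]
  if (f_max <= 1) stop("f_max must exceed 1", call. = FALSE)
  if (!ok_range(rate_range) || !ok_range(omega_range) ||
      !ok_range(x_active_range)) {
    stop("ranges must be positive increasing pairs", call. = FALSE)
  }
  if (nm_max < 1) stop("nm_max must be >= 1", call. = FALSE)
  structure(list(f_max = f_max, rate_range = rate_range,
                 omega_range = omega_range,
                 x_active_range = x_active_range,
                 nm_max = as.integer(nm_max)),
            class = "ffl_prior")
}

rlogunif <- function(n, range) exp(stats::runif(n, log(range[1]), log(range[2])))

# one regulation factor on the activation (+1) or inhibition (-1) side of 1
rfactor <- function(sign, f_max) {
  lf <- stats::runif(1, 0, log(f_max))
  # guard the measure-zero neutral value so sign constraints stay strict
  while (lf == 0) lf <- stats::runif(1, 0, log(f_max))
  exp(sign * lf)
}

#' Draw sign-consistent random parameter sets for one motif
#'
#' @param motif Motif id or [ffl_motif()] object.
#' @param n_sets Number of parameter sets to draw.
#' @param seed Optional integer seed for reproducibility.
#' @param prior An [ffl_prior()] configuration.
#' @return A list of `n_sets` [ffl_params()] objects, each sign-consistent
#'   with `motif`.
#' @examples
#' ps <- sample_parameters("C1", 3, seed = 1)
#' @export
sample_parameters <- function(motif, n_sets, seed = NULL,
                              prior = ffl_prior()) {
  stopifnot(n_sets >= 1)
  motif <- ffl_motif(motif)
  if (!is.null(seed)) set.seed(seed)
  joint_sign <- motif$sign_xz * motif$sign_yz
  out <- vector("list", n_sets)
  for (i in seq_len(n_sets)) {
    p <- ffl_params(
      gamma_y   = rlogunif(1, prior$rate_range),
      gamma_z   = rlogunif(1, prior$rate_range),
      omega_yx  = rlogunif(1, prior$omega_range),
      omega_zx  = rlogunif(1, prior$omega_range),
      omega_zy  = rlogunif(1, prior$omega_range),
      omega_zxy = rlogunif(1, prior$omega_range),
      alpha_x   = rfactor(motif$sign_xy, prior$f_max),
      beta_x    = rfactor(motif$sign_xz, prior$f_max),
      beta_y    = rfactor(motif$sign_yz, prior$f_max),
      beta_xy   = rfactor(joint_sign, prior$f_max),
      delta_y   = rlogunif(1, prior$rate_range),
      delta_z   = rlogunif(1, prior$rate_range),
      n         = sample.int(prior$nm_max, 1),
      m         = sample.int(prior$nm_max, 1),
      x_active  = rlogunif(1, prior$x_active_range)
    )
    check_signs(p, motif)
    out[[i]] <- p
  }
  out
}
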