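#' Random motif-function probability table
#'
#' Draws each motif's class distribution from a symmetric Dirichlet with
#' tunable concentration: large concentrations approach the uniform
#' (maximally flexible) distribution, small ones approach one-hot
#' (maximally specialized) rows. Useful for property tests of the
#' plasticity statistics.
#'
#' @param seed Optional integer seed.
#' @param concentration Positive Dirichlet concentration parameter.
#' @param motifs Row labels.
#' @return A row-stochastic matrix, motifs x classes.
#' @examples
#' random_probability_table(seed = 1, concentration = 0.1)
#' @export
random_probability_table <- function(seed = NULL, concentration = 1,
                                     motifs = ffl_motif_ids()) {
  if (concentration <= 0) stop("concentration must be positive",
                               call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  classes <- ffl_classes()
  tab <- t(vapply(motifs, function(m) {
    g <- stats::rgamma(length(classes), shape = concentration)
    while (sum(g) == 0) g <- stats::rgamma(length(classes),
                                           shape = concentration)
    g / sum(g)
  }, numeric(length(classes))))
  dimnames(tab) <- list(motifs, classes)
  tab
}

#' Synthetic abundance vector with a prescribed correlation
#'
#' Builds a nonnegative, normalized abundance vector whose Pearson
#' correlation with a given score vector equals `target_r`. A noise
#' vector is residualized against the scores (so it is exactly
#' uncorrelated in-sample) and mixed as
#' `z = r * std(scores) + sqrt(1 - r^2) * std(noise)`; the subsequent
#' shift to nonnegativity and normalization are affine, so the achieved
#' correlation is exact up to floating point.
#'
#' @param scores Numeric vector (length >= 3, nonconstant).
#' @param target_r Target Pearson correlation in `[-1, 1]`.
#' @param seed Optional integer seed for the noise draw.
#' @return A list with `abundance` (named, nonnegative, sums to 1) and
#'   `achieved_r`.
#' @examples
#' s <- score_table(ffl_reference_table2())
#' ab <- abundance_with_correlation(s$rho, 0.9, seed = 1)
#' ab$achieved_r
#' @export
abundance_with_correlation <- function(scores, target_r, seed = NULL) {
  stopifnot(length(scores) >= 3, abs(target_r) <= 1)
  if (stats::sd(scores) == 0) stop("scores are constant", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  s <- as.numeric(scale(scores))
  noise <- stats::rnorm(length(scores))
  noise <- stats::residuals(stats::lm(noise ~ s))
  if (stats::sd(noise) == 0) noise[] <- 0 else
    noise <- as.numeric(scale(noise))
  z <- target_r * s + sqrt(max(0, 1 - target_r^2)) * noise
  ab <- z - min(z)
  if (sum(ab) == 0) ab <- rep(1, length(z))  # degenerate flat draw
  ab <- ab / sum(ab)
  names(ab) <- names(scores)
  achieved <- if (stats::sd(ab) == 0) NA_real_ else pearson_r(ab, scores)
  list(abundance = ab, achieved_r = achieved)
}

#' Synthetic trajectory of a prescribed response class
#'
#' Constructs a piecewise-smooth Z(t) time-course that the class
#' definitions label as `shape` by construction; used as ground truth for
#' classifier tests. Graders are single exponentials from `z0` to
#' `z_inf`; pulsers rise (or dip) smoothly to a peak `pulse_height`
#' beyond the `[z0, z_inf]` envelope before settling at `z_inf`.
#'
#' @param shape One of `ffl_classes()`.
#' @param z0 Pre-input level (positive).
#' @param z_inf Final level; must sit on the side of `z0` that the class
#'   label requires, beyond the classification band.
#' @param pulse_height Excursion beyond the envelope (pulsers only).
#' @param n Number of grid points.
#' @param t_max Time horizon.
#' @param rel_tol Classification tolerance the trajectory is built
#'   against.
#' @return An `"ffl_trajectory"` object.
#' @examples
#' classify_trajectory(toy_trajectory("P-T+", z0 = 1, z_inf = 2,
#'                                    pulse_height = 0.5))
#' @export
toy_trajectory <- function(shape, z0 = 1, z_inf = 2, pulse_height = NULL,
                           n = 500, t_max = 10, rel_tol = 0.01) {
  stopifnot(shape %in% ffl_classes(), z0 > 0, n >= 50)
  band <- rel_tol * z0
  t <- seq(0, t_max, length.out = n)
  grader <- substr(shape, 1, 1) == "G"
  if (grader) {
    up <- substr(shape, 2, 2) == "+"
    if (up && z_inf <= z0 + band) {
      stop("G+ requires z_inf above z0 beyond the tolerance band",
           call. = FALSE)
    }
    if (!up && z_inf >= z0 - band) {
      stop("G- requires z_inf below z0 beyond the tolerance band",
           call. = FALSE)
    }
    z <- z_inf + (z0 - z_inf) * exp(-t)
  } else {
    slope <- substr(shape, 2, 2)
    target <- substr(shape, 4, 4)
    if (target == "+" && z_inf <= z0 + band) {
      stop(shape, " requires z_inf above z0 beyond the tolerance band",
           call. = FALSE)
    }
    if (target == "-" && z_inf >= z0 - band) {
      stop(shape, " requires z_inf below z0 beyond the tolerance band",
           call. = FALSE)
    }
    if (is.null(pulse_height) || pulse_height <= 0) {
      stop("pulsers need a positive pulse_height", call. = FALSE)
    }
    if (pulse_height <= 2 * rel_tol * max(z0, abs(z_inf - z0))) {
      stop("pulse_height too small to exceed the tolerance band",
           call. = FALSE)
    }
    peak <- if (slope == "+") max(z0, z_inf) + pulse_height else
      min(z0, z_inf) - pulse_height
    if (slope == "-" && peak < 0) {
      stop("downward pulse would take the trajectory negative",
           call. = FALSE)
    }
    t1 <- t_max / 10
    z <- ifelse(
      t <= t1,
      z0 + (peak - z0) * (1 - cos(pi * t / t1)) / 2,
      peak + (z_inf - peak) * (1 - exp(-(t - t1) / (t_max / 12)))
    )
  }
  structure(list(t = t, y = rep(NA_real_, n), z = z, z0 = z0,
                 z_inf = z_inf),
            class = "ffl_trajectory")
}
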