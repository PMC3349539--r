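#' Classify a response trajectory into one of six qualitative classes
#'
#' The output time-course Z(t) following input onset is mapped to one of
#' six classes. Graders (`G+`, `G-`) move monotonically from the pre-input
#' level `z0` to the post-input level `z_inf`. Pulsers overshoot or
#' undershoot first; their label records the sign of the initial slope
#' (`P+`/`P-`) and whether the final level sits above or below the
#' pre-input level (`T+`/`T-`).
#'
#' All comparisons use a relative tolerance band `rel_tol * z0` so that
#' solver ripple is not mistaken for dynamics:
#' * *no-response*: `z_inf` within the band of `z0` and the whole
#'   trajectory stays inside the band.
#' * *monotone*: the excursion beyond the envelope
#'   `[min(z0, z_inf), max(z0, z_inf)]` is at most
#'   `rel_tol * |z_inf - z0|`.
#' * Perfectly adapting pulsers (`z_inf` back inside the band after a
#'   large pulse) take the target sign from the strict side of `z0` on
#'   which `z_inf` lies; an exact tie is reported as `"ambiguous"` and
#'   excluded from probability counts.
#'
#' @param traj An `"ffl_trajectory"` (or a list with fields `t`, `z`,
#'   `z0`, `z_inf`).
#' @param rel_tol Relative tolerance of the dead band around `z0`.
#' @return A single string: one of `ffl_classes()`, `"no-response"` or
#'   `"ambiguous"`.
#' @examples
#' classify_trajectory(toy_trajectory("P+T-", z0 = 1, z_inf = 0.5,
#'                                    pulse_height = 2))
#' @export
classify_trajectory <- function(traj, rel_tol = 0.01) {
  z <- traj$z
  z0 <- traj$z0
  zi <- traj$z_inf
  stopifnot(length(z) >= 3, is.finite(z0), is.finite(zi), z0 > 0)
  band <- rel_tol * z0
  dev <- z - z0

  if (abs(zi - z0) <= band && max(abs(dev)) <= band) return("no-response")

  first <- which(abs(dev) > band)[1]
  if (is.na(first)) return("ambiguous")
  slope <- if (dev[first] > 0) "+" else "-"

  lo <- min(z0, zi)
  hi <- max(z0, zi)
  overshoot <- max(0, max(z) - hi, lo - min(z))
  if (overshoot <= rel_tol * abs(zi - z0)) {
    return(if (zi > z0) "G+" else "G-")
  }

  if (zi > z0 + band) {
    target <- "+"
  } else if (zi < z0 - band) {
    target <- "-"
  } else if (zi > z0) {
    target <- "+"
  } else if (zi < z0) {
    target <- "-"
  } else {
    return("ambiguous")
  }
  paste0("P", slope, "T", target)
}

#' Sign of the initial excursion of a trajectory
#'
#' The initial slope sign is determined by the first departure of Z(t)
#' from the tolerance band around the pre-input level, not by the
#' pointwise derivative at t = 0, which makes the rule robust to solver
#' noise.
#'
#' @inheritParams classify_trajectory
#' @return `"+"`, `"-"`, or `NA_character_` if the trajectory never
#'   leaves the band.
#' @export
initial_slope_sign <- function(traj, rel_tol = 0.01) {
  dev <- traj$z - traj$z0
  band <- rel_tol * traj$z0
  first <- which(abs(dev) > band)[1]
  if (is.na(first)) return(NA_character_)
  if (dev[first] > 0) "+" else "-"
}

#' Simulate one circuit and classify its response
#'
#' Convenience composition of [ffl_integrate()] and
#' [classify_trajectory()]; integration failures are reported as
#' `"failed"` so that Monte-Carlo loops can log and skip them.
#'
#' @param params An [ffl_params()] object.
#' @param rel_tol Classification tolerance.
#' @param ... Passed to [ffl_integrate()].
#' @return A class label, `"no-response"`, `"ambiguous"` or `"failed"`.
#' @export
simulate_class <- function(params, rel_tol = 0.01, ...) {
  traj <- try(ffl_integrate(params, ...), silent = TRUE)
  if (inherits(traj, "try-error")) return("failed")
  classify_trajectory(traj, rel_tol = rel_tol)
}
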