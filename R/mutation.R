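#' Mutate a single circuit parameter
#'
#' A mutation changes exactly one randomly chosen parameter. Continuous
#' parameters are multiplied by `exp(eps)` with `eps` uniform on
#' `[-kernel_scale, kernel_scale]`, so mutations can be numerically small
#' or large. Regulation factors never cross 1: the qualitative type of
#' every regulation (activation vs inhibition) — and hence the motif
#' topology — is preserved by resampling `eps` until the factor stays on
#' its side. Multimerization degrees step by one within
#' `{1, ..., nm_max}`, and only when the kernel has positive width.
#' `x_active` is the external input, not a circuit parameter, and is not
#' mutable.
#'
#' @param params An [ffl_params()] object.
#' @param kernel_scale Half-width of the log-scale mutation kernel
#'   (default `log(10)`: up to a tenfold change either way).
#' @param nm_max Upper bound for multimerization degrees.
#' @return A new [ffl_params()] object differing from `params` in exactly
#'   one field (or identical when `kernel_scale = 0`).
#' @examples
#' set.seed(1)
#' p <- ffl_params(alpha_x = 5, beta_x = 8, beta_y = 3, beta_xy = 20)
#' mutate_params(p)
#' @export
mutate_params <- function(params, kernel_scale = log(10), nm_max = 4L) {
  fields <- mutable_fields()
  f <- fields[sample.int(length(fields), 1)]
  p <- unclass(params)
  if (f %in% c("n", "m")) {
    if (kernel_scale > 0) {
      v <- p[[f]]
      step <- if (v <= 1L) 1L else if (v >= nm_max) -1L else
        sample(c(-1L, 1L), 1)
      p[[f]] <- v + step
    }
  } else {
    old <- p[[f]]
    new <- old * exp(stats::runif(1, -kernel_scale, kernel_scale))
    if (f %in% c("alpha_x", "beta_x", "beta_y", "beta_xy")) {
      # preserve the regulation sign: stay strictly on the current side of 1
      side <- old > 1
      tries <- 0L
      while ((new > 1) != side || new == 1) {
        new <- old * exp(stats::runif(1, -kernel_scale, kernel_scale))
        tries <- tries + 1L
        if (tries > 1000L) { new <- old; break }
      }
    }
    p[[f]] <- new
  }
  validate_ffl_params(p)
  structure(p, class = "ffl_params")
}

mutable_fields <- function() {
  c("gamma_y", "gamma_z", "omega_yx", "omega_zx", "omega_zy", "omega_zxy",
    "alpha_x", "beta_x", "beta_y", "beta_xy", "delta_y", "delta_z",
    "n", "m")
}

#' Mutation-protocol configuration
#'
#' @param n_parameter_sets Number of random circuits per motif.
#' @param max_rounds Maximal number of mutation rounds.
#' @param conv_window,conv_threshold Convergence rule: stop once every
#'   cumulative bin frequency changed by less than `conv_threshold` over
#'   the last `conv_window` rounds.
#' @param kernel_scale Log-scale half-width of the mutation kernel.
#' @param seed Optional master seed.
#' @return A list of class `"mutation_config"`.
#' @export
mutation_config <- function(n_parameter_sets = 1000L, max_rounds = 10000L,
                            conv_window = 500L, conv_threshold = 1e-3,
                            kernel_scale = log(10), seed = NULL) {
  stopifnot(n_parameter_sets >= 1, max_rounds >= 0, conv_window >= 1,
            conv_threshold > 0, kernel_scale >= 0)
  structure(list(n_parameter_sets = as.integer(n_parameter_sets),
                 max_rounds = as.integer(max_rounds),
                 conv_window = as.integer(conv_window),
                 conv_threshold = conv_threshold,
                 kernel_scale = kernel_scale, seed = seed),
            class = "mutation_config")
}

#' Class-transition matrices under single and accumulated mutations
#'
#' Implements the in-silico mutation protocol. A cohort of random
#' circuits for the motif is drawn and classified. Two regimes are then
#' run:
#' * **single** — each round mutates the *original* parameter set of
#'   every circuit once, classifies the mutant, bins the
#'   (baseline class, mutant class) pair and reverts; rounds are
#'   independent trials of single mutations.
#' * **accumulated** — mutations persist; each round bins the
#'   (previous class, new class) pair and the mutant becomes the new
#'   current circuit.
#'
#' Mutants that are unclassifiable (no response, tie-ambiguous or solver
#' failure) are skipped, logged, and — in the accumulated regime — the
#' mutation is rejected. Counts are normalized by the total number of
#' binned events so the 36 entries of each matrix sum to 1: entries are
#' joint frequencies, and the diagonal mass is the functionally invariant
#' (robust) fraction. Iteration stops at `max_rounds` or when the binned
#' frequencies stabilize per the convergence rule.
#'
#' @param motif Motif id or [ffl_motif()] object.
#' @param cfg A [mutation_config()].
#' @param prior An [ffl_prior()] for the initial cohort.
#' @param rel_tol Classification tolerance.
#' @param n_grid Output-grid density for classification.
#' @return A list of class `"ffl_transitions"` with elements `single` and
#'   `accumulated` (6x6 matrices over `ffl_classes()`), `rounds`
#'   (per regime), `skipped` (per regime) and `motif`.
#' @examples
#' \donttest{
#' tm <- transition_matrices("C1", mutation_config(20, 10, seed = 1))
#' robustness(tm$single)
#' }
#' @export
transition_matrices <- function(motif, cfg = mutation_config(),
                                prior = ffl_prior(), rel_tol = 0.01,
                                n_grid = 2001) {
  motif <- ffl_motif(motif)
  classes <- ffl_classes()
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  sets <- sample_parameters(motif, cfg$n_parameter_sets, prior = prior)
  base_cls <- vapply(sets, simulate_class, character(1),
                     rel_tol = rel_tol, n_grid = n_grid)
  keep <- base_cls %in% classes
  sets <- sets[keep]
  base_cls <- base_cls[keep]
  if (length(sets) == 0) {
    stop("no classifiable circuits for motif ", motif$motif, call. = FALSE)
  }

  empty <- matrix(0, 6, 6, dimnames = list(classes, classes))
  run_regime <- function(accumulate) {
    counts <- empty
    skipped <- 0L
    cur_sets <- sets
    cur_cls <- base_cls
    prev_freq <- list()
    rounds <- 0L
    while (rounds < cfg$max_rounds) {
      rounds <- rounds + 1L
      for (i in seq_along(cur_sets)) {
        origin <- if (accumulate) cur_sets[[i]] else sets[[i]]
        from <- if (accumulate) cur_cls[i] else base_cls[i]
        mut <- mutate_params(origin, kernel_scale = cfg$kernel_scale,
                             nm_max = prior$nm_max)
        to <- simulate_class(mut, rel_tol = rel_tol, n_grid = n_grid)
        if (to %in% classes) {
          counts[from, to] <- counts[from, to] + 1
          if (accumulate) {
            cur_sets[[i]] <- mut
            cur_cls[i] <- to
          }
        } else {
          skipped <- skipped + 1L
        }
      }
      freq <- counts / max(sum(counts), 1)
      prev_freq[[rounds]] <- freq
      if (rounds > cfg$conv_window) {
        delta <- max(abs(freq - prev_freq[[rounds - cfg$conv_window]]))
        if (delta < cfg$conv_threshold) break
      }
    }
    total <- sum(counts)
    list(matrix = if (total > 0) counts / total else counts,
         rounds = rounds, skipped = skipped)
  }

  single <- run_regime(accumulate = FALSE)
  accumulated <- run_regime(accumulate = TRUE)
  structure(list(single = single$matrix,
                 accumulated = accumulated$matrix,
                 rounds = c(single = single$rounds,
                            accumulated = accumulated$rounds),
                 skipped = c(single = single$skipped,
                             accumulated = accumulated$skipped),
                 n_circuits = length(sets),
                 motif = motif$motif),
            class = "ffl_transitions")
}

#' @export
print.ffl_transitions <- function(x, ...) {
  cat(sprintf("Mutation transition matrices for %s (%d circuits)\n",
              x$motif, x$n_circuits))
  cat(sprintf("single:      robustness %.3f (%d rounds)\n",
              robustness(x$single), x$rounds[["single"]]))
  cat(sprintf("accumulated: robustness %.3f (%d rounds)\n",
              robustness(x$accumulated), x$rounds[["accumulated"]]))
  invisible(x)
}

#' Mutational robustness of a transition matrix
#'
#' The diagonal entries of a transition matrix are the joint frequencies
#' of mutations that leave the dynamical class unchanged; their sum is
#' the functionally invariant fraction.
#'
#' @param tm A 6x6 transition matrix (or an `"ffl_transitions"` object,
#'   in which case the single-mutation matrix is used).
#' @return The diagonal sum.
#' @export
robustness <- function(tm) {
  if (inherits(tm, "ffl_transitions")) tm <- tm$single
  stopifnot(is.matrix(tm), nrow(tm) == ncol(tm))
  if (any(tm < 0)) stop("transition matrix has negative entries",
                        call. = FALSE)
  sum(diag(tm))
}

#' Evolvability from single- vs accumulated-mutation robustness
#'
#' The relative loss of robustness when mutations accumulate:
#' `E = 1 - R_accumulated / R_single`. A motif whose class survives
#' single mutations but drifts under sustained mutational pressure has
#' high evolvability.
#'
#' @param single,accumulated 6x6 transition matrices; alternatively pass
#'   a single `"ffl_transitions"` object as `single`.
#' @return Evolvability value, expected in `[0, 1]`; values outside the
#'   interval are returned as-is with a warning.
#' @examples
#' tms <- ffl_reference_transitions("single")
#' tma <- ffl_reference_transitions("accumulated")
#' evolvability(tms$C1, tma$C1)
#' @export
evolvability <- function(single, accumulated = NULL) {
  if (inherits(single, "ffl_transitions")) {
    accumulated <- single$accumulated
    single <- single$single
  }
  rs <- robustness(single)
  ra <- robustness(accumulated)
  if (rs <= 0) stop("single-mutation robustness is zero; evolvability ",
                    "undefined", call. = FALSE)
  e <- 1 - ra / rs
  if (e < 0 || e > 1) {
    warning("evolvability ", format(e), " outside [0, 1]", call. = FALSE)
  }
  e
}
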