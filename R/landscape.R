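#' Estimate the motif-function probability landscape
#'
#' For each topology, draws `n_sets_per_motif` random sign-consistent
#' parameter sets from the prior, simulates the response to input onset
#' and classifies it. The conditional probability of class j given motif i
#' is the fraction of *classified* samples landing in j; samples that show
#' no response, are tie-ambiguous, or fail to integrate are excluded from
#' the denominator and reported separately, so each row is row-stochastic
#' by construction.
#'
#' Reproducibility: one master `seed` yields a deterministic child seed
#' per motif, so the full table is reproducible and independent of the
#' order in which motifs are processed.
#'
#' @param n_sets_per_motif Monte-Carlo sample size per motif.
#' @param seed Optional master seed.
#' @param prior An [ffl_prior()].
#' @param rel_tol Classification tolerance.
#' @param motifs Motif ids to include (all eight by default).
#' @param n_grid Output grid density for classification.
#' @return A list of class `"ffl_landscape"` with elements `table`
#'   (row-stochastic matrix, motifs x classes), `counts` (raw class
#'   counts), `excluded` (data frame of per-motif exclusion counts),
#'   `n_per_motif` and `seed`.
#' @examples
#' \donttest{
#' ls <- estimate_landscape(50, seed = 1)
#' rowSums(ls$table)
#' }
#' @export
estimate_landscape <- function(n_sets_per_motif, seed = NULL,
                               prior = ffl_prior(), rel_tol = 0.01,
                               motifs = ffl_motif_ids(), n_grid = 2001) {
  stopifnot(n_sets_per_motif >= 1)
  classes <- ffl_classes()
  counts <- matrix(0L, length(motifs), length(classes),
                   dimnames = list(motifs, classes))
  excl <- data.frame(motif = motifs, no_response = 0L, ambiguous = 0L,
                     failed = 0L, stringsAsFactors = FALSE)
  for (i in seq_along(motifs)) {
    child <- if (is.null(seed)) NULL else
      (seed + 104729L * match(motifs[i], ffl_motif_ids())) %% 2147483647L
    sets <- sample_parameters(motifs[i], n_sets_per_motif, seed = child,
                              prior = prior)
    for (p in sets) {
      cls <- simulate_class(p, rel_tol = rel_tol, n_grid = n_grid)
      if (cls %in% classes) {
        counts[i, cls] <- counts[i, cls] + 1L
      } else if (cls == "no-response") {
        excl$no_response[i] <- excl$no_response[i] + 1L
      } else if (cls == "ambiguous") {
        excl$ambiguous[i] <- excl$ambiguous[i] + 1L
      } else {
        excl$failed[i] <- excl$failed[i] + 1L
      }
    }
    n_excl <- excl$no_response[i] + excl$ambiguous[i] + excl$failed[i]
    if (n_excl > n_sets_per_motif / 2) {
      warning("motif ", motifs[i], ": ", n_excl, " of ", n_sets_per_motif,
              " samples excluded from classification", call. = FALSE)
    }
  }
  tab <- counts / pmax(rowSums(counts), 1L)
  structure(list(table = tab, counts = counts, excluded = excl,
                 n_per_motif = n_sets_per_motif, seed = seed),
            class = "ffl_landscape")
}

#' @export
print.ffl_landscape <- function(x, ...) {
  cat(sprintf("FFL function landscape (%d samples per motif):\n",
              x$n_per_motif))
  print(round(x$table, 3))
  n_excl <- sum(x$excluded[, -1])
  cat(sprintf("excluded samples (no-response/ambiguous/failed): %d\n",
              n_excl))
  invisible(x)
}

#' Total-variation distance between two probability tables
#'
#' Average over motifs of half the L1 distance between matching rows;
#' used to monitor Monte-Carlo convergence of the landscape estimate.
#'
#' @param a,b Row-stochastic matrices with identical dimnames.
#' @return A single number in `[0, 1]`.
#' @export
tv_distance <- function(a, b) {
  stopifnot(identical(dimnames(a), dimnames(b)))
  mean(rowSums(abs(a - b)) / 2)
}
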