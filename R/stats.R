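#' Configuration of the plasticity scale
#'
#' The peakedness of a motif's six-class probability distribution is
#' measured by the bias-corrected sample kurtosis over the class
#' probabilities. Two analytic extremes anchor the scale: the fully
#' specialized one-hot distribution, and the fully flexible uniform
#' distribution (a removable 0/0 singularity of the estimator, resolved
#' by a symmetric-perturbation limit that yields `-2(n-1)/(n-3)`, i.e.
#' -10/3 for n = 6). The reference point `k0` for the plasticity score
#' defaults to the midpoint of the interval.
#'
#' @param n_classes Number of function classes (6).
#' @param k0 Reference kurtosis; midpoint of the extremes by default.
#' @return A list of class `"plasticity_config"` with fields `n_classes`,
#'   `k_specialized`, `k_flexible`, `k0`.
#' @examples
#' plasticity_config()  # k_specialized = 6, k_flexible = -10/3, k0 = 4/3
#' @export
plasticity_config <- function(n_classes = 6L, k0 = NULL) {
  n <- as.integer(n_classes)
  if (n < 4L) stop("the sample-kurtosis estimator needs n >= 4",
                   call. = FALSE)
  onehot <- c(1, rep(0, n - 1))
  k_s <- sample_kurtosis_raw(onehot)
  k_f <- -2 * (n - 1) / (n - 3)   # symmetric-perturbation limit
  if (is.null(k0)) k0 <- (k_f + k_s) / 2
  structure(list(n_classes = n, k_specialized = k_s, k_flexible = k_f,
                 k0 = k0),
            class = "plasticity_config")
}

# estimator without the degenerate-sigma branch (used to derive extremes)
sample_kurtosis_raw <- function(p) {
  n <- length(p)
  m <- mean(p)
  s <- stats::sd(p)
  n * (n + 1) / ((n - 1) * (n - 2) * (n - 3)) * sum(((p - m) / s)^4) -
    3 * (n - 1)^2 / ((n - 2) * (n - 3))
}

#' Sample kurtosis of a class-probability vector
#'
#' Bias-corrected sample kurtosis (excess, i.e. 0 for a normal sample)
#' of the n class probabilities, with the sample standard deviation
#' (denominator n - 1):
#' \deqn{K = \frac{n(n+1)}{(n-1)(n-2)(n-3)}
#'   \sum_j \left(\frac{p_j - \bar p}{\sigma}\right)^4
#'   - \frac{3(n-1)^2}{(n-2)(n-3)}}
#' A numerically uniform vector (sigma below `1e-12`) returns the
#' flexible-limit value from `cfg`.
#'
#' @param p Probability vector (nonnegative, sums to 1 within 1e-3).
#' @param cfg A [plasticity_config()]; its `n_classes` must match
#'   `length(p)`.
#' @return A single kurtosis value in `[k_flexible, k_specialized]`.
#' @examples
#' sample_kurtosis(c(1, 0, 0, 0, 0, 0))   # 6
#' sample_kurtosis(rep(1 / 6, 6))         # -10/3
#' @export
sample_kurtosis <- function(p, cfg = plasticity_config()) {
  check_prob_vector(p, cfg$n_classes)
  if (stats::sd(p) < 1e-12) return(cfg$k_flexible)
  sample_kurtosis_raw(p)
}

#' Shannon entropy of a class-probability vector, in bits
#'
#' @inheritParams sample_kurtosis
#' @param n_classes Expected length of `p`.
#' @return Entropy in `[0, log2(n_classes)]`; `0 * log2(0)` is taken as 0.
#' @examples
#' shannon_entropy(rep(1 / 6, 6))  # log2(6)
#' @export
shannon_entropy <- function(p, n_classes = length(p)) {
  check_prob_vector(p, n_classes)
  pos <- p[p > 0]
  -sum(pos * log2(pos)) + 0  # + 0 normalizes IEEE negative zero
}

check_prob_vector <- function(p, n) {
  if (length(p) != n) {
    stop("expected a probability vector of length ", n, call. = FALSE)
  }
  if (any(!is.finite(p)) || any(p < 0)) {
    stop("probabilities must be finite and nonnegative", call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-3) {
    stop("probabilities must sum to 1 within 1e-3 (got ", sum(p), ")",
         call. = FALSE)
  }
  invisible(p)
}

#' Plasticity score
#'
#' Distance of the kurtosis magnitude from the reference point `k0`
#' midway between the flexible and specialized extremes. Low values mean
#' the motif balances specialization and flexibility (high plasticity);
#' high values mean commitment to either extreme. The score is not
#' clamped and may be negative when `|K| < k0`.
#'
#' @param K Kurtosis value (within the configured extremes).
#' @param cfg A [plasticity_config()].
#' @return `|K| - k0`.
#' @export
psi_score <- function(K, cfg = plasticity_config()) {
  if (any(K < cfg$k_flexible - 1e-9 | K > cfg$k_specialized + 1e-9)) {
    stop("kurtosis outside [", round(cfg$k_flexible, 4), ", ",
         cfg$k_specialized, "]", call. = FALSE)
  }
  abs(K) - cfg$k0
}

#' Predicted motif abundance from plasticity scores
#'
#' Normalized inverse plasticity: motifs whose kurtosis magnitude sits
#' close to the midpoint of the flexibility-specialization scale are
#' predicted to be frequent.
#'
#' @param psis Vector of positive plasticity scores (one per motif).
#' @return Vector of the same length summing to 1:
#'   `rho_i = psi_i^-1 / sum_j psi_j^-1`.
#' @examples
#' rho_score(c(1, 1, 1, 1))  # all equal -> 1/4 each
#' @export
rho_score <- function(psis) {
  if (any(!is.finite(psis)) || any(psis <= 0)) {
    stop("all plasticity scores must be positive to invert", call. = FALSE)
  }
  inv <- 1 / psis
  out <- inv / sum(inv)
  names(out) <- names(psis)
  out
}

#' Score every row of a probability table
#'
#' Applies [sample_kurtosis()], [shannon_entropy()], [psi_score()] and
#' [rho_score()] to each motif's class-probability row.
#'
#' @param table Row-stochastic matrix (motifs x classes) or an
#'   `"ffl_landscape"` object.
#' @param cfg A [plasticity_config()].
#' @return A data frame with columns `motif`, `kurtosis`, `entropy_bits`,
#'   `psi`, `rho`.
#' @examples
#' score_table(ffl_reference_table2())
#' @export
score_table <- function(table, cfg = plasticity_config()) {
  if (inherits(table, "ffl_landscape")) table <- table$table
  stopifnot(is.matrix(table), ncol(table) == cfg$n_classes)
  K <- apply(table, 1, sample_kurtosis, cfg = cfg)
  H <- apply(table, 1, shannon_entropy)
  psi <- psi_score(K, cfg)
  data.frame(motif = rownames(table), kurtosis = K, entropy_bits = H,
             psi = psi, rho = rho_score(psi),
             row.names = NULL, stringsAsFactors = FALSE)
}
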