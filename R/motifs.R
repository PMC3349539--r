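#' Feed-forward loop motif topologies
#'
#' The feed-forward loop (FFL) is a three-gene motif in which a signal
#' protein X regulates a target gene Z both directly and indirectly via an
#' intermediate Y. Each of the three edges (X->Y, X->Z, Y->Z) is either
#' activating (+1) or inhibiting (-1), giving eight distinct sign patterns.
#' A motif is *coherent* when the sign of the direct X->Z edge equals the
#' product of the signs along the indirect X->Y->Z path, and *incoherent*
#' otherwise. The standard taxonomy labels the coherent types C1-C4 and the
#' incoherent types I1-I4.
#'
#' @return A data frame with one row per motif and columns `motif`,
#'   `sign_xy`, `sign_yz`, `sign_xz` (each +1 or -1) and `coherent`
#'   (logical).
#' @examples
#' ffl_motifs()
#' @export
ffl_motifs <- function() {
  data.frame(
    motif    = c("C1", "C2", "C3", "C4", "I1", "I2", "I3", "I4"),
    sign_xy  = c(+1, -1, +1, -1, +1, -1, +1, -1),
    sign_yz  = c(+1, +1, -1, -1, -1, -1, +1, +1),
    sign_xz  = c(+1, -1, -1, +1, +1, -1, -1, +1),
    coherent = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' @rdname ffl_motifs
#' @export
ffl_motif_ids <- function() ffl_motifs()$motif

#' Look up a single FFL topology
#'
#' @param motif A motif identifier (`"C1"` ... `"I4"`) or an object already
#'   returned by `ffl_motif()`.
#' @return A list of class `"ffl_motif"` with fields `motif`, `sign_xy`,
#'   `sign_yz`, `sign_xz` and `coherent`.
#' @examples
#' ffl_motif("I1")
#' @export
ffl_motif <- function(motif) {
  if (inherits(motif, "ffl_motif")) return(motif)
  tab <- ffl_motifs()
  i <- match(motif, tab$motif)
  if (is.na(i)) {
    stop("unknown motif '", motif, "'; expected one of ",
         paste(tab$motif, collapse = ", "), call. = FALSE)
  }
  structure(as.list(tab[i, , drop = FALSE]), class = "ffl_motif")
}

#' @export
print.ffl_motif <- function(x, ...) {
  arrow <- function(s) if (s > 0) "activates" else "inhibits"
  cat(sprintf("FFL motif %s (%s):\n", x$motif,
              if (x$coherent) "coherent" else "incoherent"))
  cat(sprintf("  X %s Y, X %s Z, Y %s Z\n",
              arrow(x$sign_xy), arrow(x$sign_xz), arrow(x$sign_yz)))
  invisible(x)
}

#' Six qualitative response classes
#'
#' Labels of the six dynamical response classes of the output Z upon input
#' onset: graders (`G+`, `G-`) approach the new steady state monotonically;
#' pulsers overshoot or undershoot first and are annotated by the sign of
#' the initial slope (`P+`/`P-`) and of the final target level relative to
#' the pre-input level (`T+`/`T-`).
#'
#' @return Character vector of the six class labels, in the canonical order
#'   used by all tables in this package.
#' @export
ffl_classes <- function() c("G+", "G-", "P+T+", "P+T-", "P-T-", "P-T+")
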