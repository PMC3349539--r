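#' Pearson product-moment correlation
#'
#' Computed from scratch (centered cross-products over the product of
#' standard deviations) so the statistic used throughout the analysis is
#' self-contained; it matches `stats::cor` to machine precision and is
#' cross-checked against it in the test suite.
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return Correlation coefficient in `[-1, 1]`.
#' @examples
#' pearson_r(1:8, 2 * (1:8) + 1)  # 1
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  dx <- x - mean(x)
  dy <- y - mean(y)
  vx <- sum(dx^2)
  vy <- sum(dy^2)
  if (vx == 0 || vy == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  sum(dx * dy) / sqrt(vx * vy)
}

#' Correlation report across scores, evolvability and abundances
#'
#' Assembles the cross-correlations at the heart of the analysis: the
#' predicted abundance rho, the plasticity psi and the evolvability E
#' against each observed abundance vector, plus the species-independent
#' E-vs-psi correlation; also reports rank orderings and whether the two
#' most abundant motifs are the two most evolvable ones.
#'
#' @param scores Data frame from [score_table()] (columns `motif`, `psi`,
#'   `rho`, ...).
#' @param evolvability Named numeric vector of per-motif E values.
#' @param abundances Data frame with columns `motif`, `abundance`,
#'   `source` (zero or more sources); defaults to the packaged synthetic
#'   approximation.
#' @return A list of class `"ffl_report"` with elements `correlations`
#'   (data frame: source, r_rho, r_psi, r_evolvability), `r_E_psi`,
#'   `rank_by_E`, `rank_by_rho` and `top2_by_E`.
#' @examples
#' scores <- score_table(ffl_reference_table2())
#' single <- ffl_reference_transitions("single")
#' acc <- ffl_reference_transitions("accumulated")
#' E <- mapply(evolvability, single, acc)
#' rep <- compare_report(scores, E)
#' rep$r_E_psi
#' @export
compare_report <- function(scores, evolvability,
                           abundances = ffl_reference_abundance()) {
  motifs <- scores$motif
  if (is.null(names(evolvability)) ||
      !setequal(names(evolvability), motifs)) {
    stop("evolvability must be named by the same motifs as `scores`",
         call. = FALSE)
  }
  E <- evolvability[motifs]
  cors <- NULL
  if (!is.null(abundances) && nrow(abundances) > 0) {
    cors <- do.call(rbind, lapply(split(abundances, abundances$source),
                                  function(blk) {
      if (!setequal(blk$motif, motifs)) {
        stop("abundance source '", blk$source[1],
             "' does not cover the same motifs as `scores`",
             call. = FALSE)
      }
      ab <- blk$abundance[match(motifs, blk$motif)]
      data.frame(source = blk$source[1],
                 r_rho = pearson_r(scores$rho, ab),
                 r_psi = pearson_r(scores$psi, ab),
                 r_evolvability = pearson_r(E, ab),
                 stringsAsFactors = FALSE)
    }))
    rownames(cors) <- NULL
  }
  rank_E <- motifs[order(E, decreasing = TRUE)]
  structure(list(
    correlations = cors,
    r_E_psi = pearson_r(E, scores$psi),
    rank_by_E = rank_E,
    rank_by_rho = motifs[order(scores$rho, decreasing = TRUE)],
    top2_by_E = rank_E[1:2]
  ), class = "ffl_report")
}

#' @export
print.ffl_report <- function(x, ...) {
  cat("FFL correlation report\n")
  cat(sprintf("  Pearson r (evolvability vs psi): %.3f\n", x$r_E_psi))
  cat("  most evolvable motifs:", paste(x$top2_by_E, collapse = ", "),
      "\n")
  if (!is.null(x$correlations)) {
    cat("  correlations with abundance sources:\n")
    print(cbind(x$correlations[1],
                round(x$correlations[-1], 3)), row.names = FALSE)
  }
  invisible(x)
}

#' Write a correlation report as JSON
#'
#' @param report An `"ffl_report"`.
#' @param path Output file.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
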