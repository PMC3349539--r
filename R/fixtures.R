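extdata_path <- function(file) {
  path <- system.file("extdata", file, package = "fflscape")
  if (!nzchar(path)) stop("fixture '", file, "' not found", call. = FALSE)
  path
}

#' Reference motif-function probability table
#'
#' The published conditional probabilities P(class | motif) for all eight
#' FFL topologies over the six response classes, transcribed once into a
#' machine-readable fixture. These values are the authoritative input for
#' the downstream plasticity statistics; the Monte-Carlo estimator
#' ([estimate_landscape()]) is a reproduction apparatus whose priors are
#' not published, so its output is compared to this table only
#' qualitatively.
#'
#' @param path Optional path to a CSV in the same layout (columns
#'   `motif,G+,G-,P+T+,P+T-,P-T-,P-T+`); defaults to the packaged fixture.
#' @return An 8 x 6 row-stochastic matrix with motif rownames and class
#'   colnames.
#' @examples
#' ffl_reference_table2()["C1", "G+"]  # 0.4862
#' @export
ffl_reference_table2 <- function(path = extdata_path("table2_probabilities.csv")) {
  read_probability_table(path)
}

#' Reference plasticity scores
#'
#' The published per-motif kurtosis, plasticity (psi) and predicted
#' abundance (rho), as a fixture for regression checks. [score_table()]
#' applied to [ffl_reference_table2()] reproduces these columns within
#' +/- 0.005.
#'
#' @return A data frame with columns `motif`, `kurtosis`, `psi`, `rho`.
#' @export
ffl_reference_table1 <- function() {
  df <- utils::read.csv(extdata_path("table1_reference.csv"),
                        check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(identical(df$motif, ffl_motif_ids()))
  df
}

#' Reference mutation-transition matrices
#'
#' The published 6 x 6 class-transition frequency matrices for each motif
#' under the two mutation regimes. Entries are joint frequencies of
#' (initial class, final class) events; the diagonal is the functionally
#' invariant fraction. Grand totals are approximately 1 per motif as
#' printed (the C3 single-mutation block totals 1.106 in the source and
#' is kept verbatim; the loader warns).
#'
#' @param regime `"single"` or `"accumulated"`.
#' @param path Optional path to a long-format CSV (columns
#'   `motif,from,<6 class labels>`); defaults to the packaged fixture.
#' @return A named list of eight 6 x 6 matrices in canonical class order.
#' @examples
#' robustness(ffl_reference_transitions("single")$C1)  # 0.948
#' @export
ffl_reference_transitions <- function(regime = c("single", "accumulated"),
                                      path = NULL) {
  regime <- match.arg(regime)
  if (is.null(path)) {
    path <- extdata_path(paste0("transitions_", regime, ".csv"))
  }
  read_transition_matrices(path)
}

#' Approximate natural motif abundances (synthetic fixture)
#'
#' Approximate relative FFL abundances in the E. coli and yeast
#' transcription networks. These values are *synthetic*: they were
#' eyeballed from a published figure, are not authoritative, and are
#' shipped only so that qualitative ranking checks (C1 and I1 dominate)
#' can run without a download. Quantitative replication of
#' abundance-score correlations requires user-supplied abundance data in
#' the same CSV layout (`motif,abundance,source`).
#'
#' @param path Optional path to an abundance CSV.
#' @return A data frame with columns `motif`, `abundance`, `source`;
#'   abundances sum to 1 per source.
#' @export
ffl_reference_abundance <- function(path = extdata_path("abundance_approx_synthetic.csv")) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  stopifnot(all(c("motif", "abundance", "source") %in% names(df)))
  if (any(df$abundance < 0)) stop("negative abundance", call. = FALSE)
  sums <- tapply(df$abundance, df$source, sum)
  if (any(abs(sums - 1) > 1e-3)) {
    stop("abundances must sum to 1 per source", call. = FALSE)
  }
  df
}

#' Verify fixture checksums
#'
#' The reference tables were transcribed once and are never regenerated;
#' this check guards against accidental edits.
#'
#' @return `TRUE` invisibly if all fixture MD5 sums match the packaged
#'   manifest; stops otherwise.
#' @export
verify_fixtures <- function() {
  man <- utils::read.csv(extdata_path("MANIFEST.csv"),
                         stringsAsFactors = FALSE)
  for (i in seq_len(nrow(man))) {
    sum_i <- unname(tools::md5sum(extdata_path(man$file[i])))
    if (!identical(sum_i, man$md5[i])) {
      stop("fixture '", man$file[i], "' does not match its recorded ",
           "checksum", call. = FALSE)
    }
  }
  invisible(TRUE)
}
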