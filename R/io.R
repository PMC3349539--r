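#' Read and write probability tables
#'
#' Probability tables travel as CSV with header
#' `motif,G+,G-,P+T+,P+T-,P-T-,P-T+`. Reading validates shape, entry
#' range and row sums (tolerance 1e-3); writing formats numbers with
#' enough digits that a read/write/read round trip is bit-identical.
#'
#' @param path File path.
#' @return `read_probability_table()` returns a motifs x classes matrix;
#'   `write_probability_table()` returns `path` invisibly.
#' @export
read_probability_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (!identical(names(df), c("motif", ffl_classes()))) {
    stop("malformed probability table: expected columns motif,",
         paste(ffl_classes(), collapse = ","), call. = FALSE)
  }
  tab <- as.matrix(df[, -1])
  rownames(tab) <- df$motif
  if (any(!is.finite(tab)) || any(tab < 0) || any(tab > 1)) {
    stop("probability-table entries must lie in [0, 1]", call. = FALSE)
  }
  bad <- abs(rowSums(tab) - 1) > 1e-3
  if (any(bad)) {
    stop("rows not summing to 1 within 1e-3: ",
         paste(rownames(tab)[bad], collapse = ", "), call. = FALSE)
  }
  tab
}

#' @rdname read_probability_table
#' @param table Motifs x classes matrix (or `"ffl_landscape"` object).
#' @export
write_probability_table <- function(table, path) {
  if (inherits(table, "ffl_landscape")) table <- table$table
  df <- data.frame(motif = rownames(table),
                   format(table, digits = 15, scientific = FALSE,
                          trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("motif", colnames(table))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write transition-matrix bundles
#'
#' Long-format CSV with columns `motif,from,<class labels>`, six `from`
#' rows per motif; columns are mapped to the canonical class order by
#' label, never by position.
#'
#' @param path File path.
#' @return `read_transition_matrices()` returns a named list of 6 x 6
#'   matrices.
#' @export
read_transition_matrices <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  classes <- ffl_classes()
  if (!all(c("motif", "from", classes) %in% names(df))) {
    stop("malformed transition table: need columns motif, from and the ",
         "six class labels", call. = FALSE)
  }
  out <- list()
  for (mo in unique(df$motif)) {
    block <- df[df$motif == mo, ]
    if (nrow(block) != 6 || !setequal(block$from, classes)) {
      stop("motif ", mo, ": expected one row per class", call. = FALSE)
    }
    m <- as.matrix(block[match(classes, block$from), classes])
    dimnames(m) <- list(classes, classes)
    if (any(!is.finite(m)) || any(m < 0)) {
      stop("motif ", mo, ": negative or non-finite entries",
           call. = FALSE)
    }
    if (abs(sum(m) - 1) > 0.02) {
      warning("motif ", mo, ": transition frequencies total ",
              format(sum(m)), call. = FALSE)
    }
    out[[mo]] <- m
  }
  out
}

#' @rdname read_transition_matrices
#' @param matrices Named list of 6 x 6 matrices.
#' @export
write_transition_matrices <- function(matrices, path) {
  classes <- ffl_classes()
  rows <- lapply(names(matrices), function(mo) {
    m <- matrices[[mo]]
    data.frame(motif = mo, from = classes,
               format(m[classes, classes], digits = 15,
                      scientific = FALSE, trim = TRUE),
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  names(df) <- c("motif", "from", classes)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a trajectory as CSV
#'
#' Columns `t`, `Y`, `Z`.
#'
#' @param traj An `"ffl_trajectory"`.
#' @param path File path.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(data.frame(t = traj$t, Y = traj$y, Z = traj$z),
                   path, row.names = FALSE)
  invisible(path)
}
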