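## File formats: NEXUS DATA blocks (datatype=standard, MrBayes-compatible)
## and a simple TSV dialect with a sidecar of true rates and classes.

#' Write a character matrix as a NEXUS DATA block
#'
#' Emits `datatype=standard symbols="01" missing=? gap=- interleave=no`,
#' the conventional layout consumed by MrBayes and PAUP*.
#'
#' @param x A [char_matrix()].
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_nexus_data <- function(x, file) {
  stopifnot(inherits(x, "char_matrix"))
  tx <- taxa(x)
  if (any(grepl("[[:space:];()\\[\\]]", tx)))
    stop("taxon labels must not contain whitespace or NEXUS punctuation")
  rows <- apply(x$states, 1L, paste, collapse = "")
  pad <- formatC(tx, width = max(nchar(tx)) + 2L, flag = "-")
  con <- file(file, "w"); on.exit(close(con))
  writeLines(c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(x$states), ncol(x$states)),
    "  FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=? GAP=- INTERLEAVE=NO;",
    "  MATRIX",
    paste0("    ", pad, rows),
    "  ;",
    "END;"), con)
  invisible(file)
}

#' Read a NEXUS DATA block into a character matrix
#'
#' Wraps [ape::read.nexus.data()]. True rates are not stored in NEXUS
#' files; read them from a TSV sidecar with [read_matrix_tsv()] if needed.
#'
#' @param file Path to a NEXUS file with a standard-datatype DATA block.
#' @return A [char_matrix()] without `true_rates`.
#' @export
read_nexus_data <- function(file) {
  lst <- ape::read.nexus.data(file)
  st <- do.call(rbind, lst)
  rownames(st) <- names(lst)
  st[!(st %in% c("0", "1", "?"))] <- "?"   # treat gaps like missing
  char_matrix(st)
}

#' Write/read a character matrix as TSV with a rate sidecar
#'
#' The main file has one row per taxon (first column `taxon`, then one
#' column per character). The sidecar records each character's true
#' simulating rate and parsimony-informativeness class, so rate-class
#' operations survive a round trip.
#'
#' @param x A [char_matrix()].
#' @param file Main TSV path.
#' @param rates_file Sidecar path; default `<file>.rates.tsv`. Set `NULL`
#'   to skip (on write) or to read a matrix without rates.
#' @return `read_matrix_tsv()` returns a [char_matrix()].
#' @export
write_matrix_tsv <- function(x, file, rates_file = paste0(file, ".rates.tsv")) {
  stopifnot(inherits(x, "char_matrix"))
  df <- data.frame(taxon = taxa(x), x$states, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("taxon", paste0("c", seq_len(ncol(x$states))))
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(rates_file) && !is.null(x$true_rates)) {
    side <- data.frame(character = seq_len(ncol(x$states)),
                       true_rate = x$true_rates,
                       class = as.character(classify_characters(x, warn = FALSE)),
                       rate_mode = x$rate_mode %||% NA_character_)
    write.table(side, rates_file, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(file)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(file, rates_file = paste0(file, ".rates.tsv")) {
  df <- read.table(file, sep = "\t", header = TRUE, check.names = FALSE,
                   colClasses = "character")
  st <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(st) <- list(df[[1L]], NULL)
  rates <- NULL; mode <- NULL
  if (!is.null(rates_file) && file.exists(rates_file)) {
    side <- read.table(rates_file, sep = "\t", header = TRUE)
    rates <- side$true_rate
    if (!is.null(side$rate_mode) && !all(is.na(side$rate_mode)))
      mode <- as.character(side$rate_mode[1L])
  }
  char_matrix(st, true_rates = rates, rate_mode = mode)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write posterior trees and parameter trace to disk
#'
#' Trees go to a NEXUS TREES block (MrBayes `.t`-file style) and the
#' parameter trace to TSV (generation, log-likelihood, gamma shape, tree
#' length).
#'
#' @param fit An `mk_bayes` object.
#' @param tree_file,trace_file Output paths (`NULL` to skip either).
#' @return Invisibly, the paths written.
#' @export
write_posterior <- function(fit, tree_file = NULL, trace_file = NULL) {
  stopifnot(inherits(fit, "mk_bayes"))
  if (!is.null(tree_file))
    write_nexus_trees(posterior_trees(fit), tree_file)
  if (!is.null(trace_file))
    write.table(fit$trace, trace_file, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(c(tree_file, trace_file))
}
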