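## CharacterMatrix container: taxa x binary characters ("0"/"1"/"?"), with
## the true simulating rate of every character carried alongside so that
## rate-class operations stay well-defined through filtering and deletion.

#' Construct a character matrix
#'
#' @param states Character matrix (rows = taxa with rownames, columns =
#'   characters) with entries `"0"`, `"1"` or `"?"`.
#' @param true_rates Optional numeric vector, one positive rate per
#'   character (expected changes per character summed over the whole tree).
#' @param rate_mode `"single"` or `"per_character"`, recorded for
#'   downstream rate-class operations; `NULL` when unknown (e.g. data read
#'   from a file without a rate sidecar).
#' @param meta Free-form list of simulation metadata.
#' @return An object of class `char_matrix`.
#' @export
char_matrix <- function(states, true_rates = NULL, rate_mode = NULL,
                        meta = list()) {
  stopifnot(is.matrix(states), is.character(states))
  if (is.null(rownames(states)) || anyDuplicated(rownames(states)))
    stop("states must have unique taxon rownames")
  bad <- !(states %in% c("0", "1", "?"))
  if (any(bad))
    stop("states must be '0', '1' or '?'; found: ",
         paste(unique(states[bad]), collapse = ", "))
  if (!is.null(true_rates)) {
    stopifnot(is.numeric(true_rates), length(true_rates) == ncol(states))
    if (any(true_rates <= 0)) stop("true_rates must be positive")
  }
  structure(list(states = states, true_rates = true_rates,
                 rate_mode = rate_mode, meta = meta),
            class = "char_matrix")
}

#' @export
dim.char_matrix <- function(x) dim(x$states)

#' @export
as.matrix.char_matrix <- function(x, ...) x$states

#' Taxon labels of a character matrix
#' @param x A `char_matrix`.
#' @return Character vector of taxon labels.
#' @export
taxa <- function(x) rownames(x$states)

#' Subset a character matrix
#'
#' Column subsets keep `true_rates` aligned; row subsets reorder or drop
#' taxa. Indices follow usual matrix conventions.
#'
#' @param x A `char_matrix`.
#' @param i,j Row (taxon) and column (character) indices.
#' @param ... Ignored.
#' @export
`[.char_matrix` <- function(x, i, j, ...) {
  st <- x$states
  if (missing(i)) i <- seq_len(nrow(st))
  if (missing(j)) j <- seq_len(ncol(st))
  rates <- x$true_rates
  if (!is.null(rates)) {
    jj <- seq_len(ncol(st))[j]  # resolve logical/negative indexing once
    rates <- rates[jj]
  }
  char_matrix(st[i, j, drop = FALSE], true_rates = rates,
              rate_mode = x$rate_mode, meta = x$meta)
}

#' @export
print.char_matrix <- function(x, ...) {
  d <- dim(x$states)
  cat("Binary character matrix:", d[1L], "taxa x", d[2L], "characters\n")
  miss <- mean(x$states == "?")
  cat(sprintf("  missing cells: %.1f%%\n", 100 * miss))
  if (d[2L] > 0) {
    cl <- classify_characters(x, warn = FALSE)
    tb <- table(cl)
    cat("  classes:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
  if (!is.null(x$true_rates))
    cat(sprintf("  true rates: mean %.3g (mode %s)\n",
                mean(x$true_rates),
                if (is.null(x$rate_mode)) "?" else x$rate_mode))
  invisible(x)
}

#' Classify binary characters by parsimony informativeness
#'
#' Counts are taken over non-missing entries: a character is `invariant`
#' when at most one state is present, `parsimony_informative` when both
#' states occur in at least two taxa, and `variable_uninformative`
#' otherwise (autapomorphies). All-missing columns are degenerate and are
#' classified `invariant` with a warning.
#'
#' @param x A `char_matrix`, a character matrix, or a single character
#'   vector (one column).
#' @param warn Warn on all-missing columns (default `TRUE`).
#' @return Factor with levels `invariant`, `variable_uninformative`,
#'   `parsimony_informative`, one per character.
#' @export
classify_characters <- function(x, warn = TRUE) {
  st <- if (inherits(x, "char_matrix")) x$states else x
  if (!is.matrix(st)) st <- matrix(st, ncol = 1L)
  n0 <- colSums(st == "0")
  n1 <- colSums(st == "1")
  cls <- ifelse(n0 == 0 | n1 == 0, "invariant",
         ifelse(pmin(n0, n1) >= 2, "parsimony_informative",
                "variable_uninformative"))
  if (warn && any(n0 + n1 == 0) && ncol(st) > 0)
    warning(sum(n0 + n1 == 0), " all-missing column(s) classified invariant")
  factor(cls, levels = c("invariant", "variable_uninformative",
                         "parsimony_informative"))
}

#' Filter a character matrix by an acquisition scheme
#'
#' Emulates observer-defined character collection: `variable_only` drops
#' invariant characters; `parsimony_informative_only` additionally drops
#' autapomorphies and other uninformative variable characters;
#' `unfiltered` is the identity. Column order and the `true_rates`
#' alignment are preserved.
#'
#' @param x A `char_matrix`.
#' @param scheme One of `"unfiltered"`, `"variable_only"`,
#'   `"parsimony_informative_only"`.
#' @return A filtered `char_matrix` (possibly with zero columns, with a
#'   warning).
#' @export
filter_matrix <- function(x, scheme = c("unfiltered", "variable_only",
                                        "parsimony_informative_only")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(x, "char_matrix"))
  if (scheme == "unfiltered") return(x)
  cls <- classify_characters(x, warn = FALSE)
  keep <- if (scheme == "variable_only") cls != "invariant"
          else cls == "parsimony_informative"
  if (!any(keep)) warning("filtering removed every character")
  x[, which(keep)]
}

#' Assign characters to rate tertiles
#'
#' Characters are sorted ascending by their true simulating rate and cut
#' into three contiguous classes of near-equal size (slow, intermediate,
#' fast). When the count is not divisible by three the earlier (slower)
#' classes take the extra columns; rate ties keep original column order.
#'
#' @param x A `char_matrix` with per-character `true_rates`.
#' @return Factor with levels `slow`, `intermediate`, `fast`, one entry per
#'   character in original column order.
#' @export
assign_rate_classes <- function(x) {
  stopifnot(inherits(x, "char_matrix"))
  if (is.null(x$true_rates))
    stop("matrix carries no true rates")
  if (!identical(x$rate_mode, "per_character"))
    stop("rate classes are undefined for single-rate matrices")
  n <- ncol(x$states)
  base <- n %/% 3L; rem <- n %% 3L
  sizes <- c(base + (rem > 0L), base + (rem > 1L), base)
  ord <- order(x$true_rates)  # stable: ties keep column order
  cls <- rep(c("slow", "intermediate", "fast"), times = sizes)
  out <- character(n)
  out[ord] <- cls
  factor(out, levels = c("slow", "intermediate", "fast"))
}

#' Delete a random fraction of one rate class's characters
#'
#' Removes `round(fraction * class_size)` (round half up) uniformly chosen
#' columns of the requested rate tertile; other classes are untouched.
#'
#' @param x A `char_matrix` with per-character rates.
#' @param rate_class `"slow"`, `"intermediate"` or `"fast"`.
#' @param fraction Fraction of the class to delete, in \[0, 1\].
#' @param seed Optional integer seed (deterministic deletion).
#' @return A `char_matrix` with the sampled columns removed.
#' @export
delete_rate_class <- function(x, rate_class = c("slow", "intermediate", "fast"),
                              fraction, seed = NULL) {
  rate_class <- match.arg(rate_class)
  stopifnot(fraction >= 0, fraction <= 1)
  cls <- assign_rate_classes(x)
  idx <- which(cls == rate_class)
  k <- round_half_up(fraction * length(idx))
  if (k == 0L) return(x)
  drop <- with_seed(seed, sort(sample(idx, k)))
  x[, -drop]
}

#' Concentrate missing data in fossil taxa
#'
#' For each taxon flagged as a fossil on `tree` (see [fossil_taxa()]),
#' sets `round(fraction * n_characters)` (round half up) uniformly chosen
#' cells of that taxon's row to `"?"`. Non-fossil rows are untouched.
#' Fossil taxa are processed in sorted label order, so the result does not
#' depend on the row order of the matrix.
#'
#' @param x A `char_matrix`.
#' @param tree A `phylo` carrying fossil flags.
#' @param fraction Fraction of each fossil row to mask, in \[0, 1\].
#' @param seed Optional integer seed.
#' @return The masked `char_matrix`.
#' @export
mask_fossil_cells <- function(x, tree, fraction, seed = NULL) {
  stopifnot(inherits(x, "char_matrix"), fraction >= 0, fraction <= 1)
  fos <- fossil_taxa(tree)
  if (!length(fos)) stop("tree has no fossil taxa flagged")
  bad <- setdiff(fos, taxa(x))
  if (length(bad))
    stop("fossil taxa absent from matrix: ", paste(bad, collapse = ", "))
  n <- ncol(x$states)
  k <- round_half_up(fraction * n)
  if (k == 0L) return(x)
  st <- x$states
  with_seed(seed, {
    for (tx in sort(fos)) {
      cols <- sample.int(n, k)
      st[tx, cols] <- "?"
    }
  })
  char_matrix(st, true_rates = x$true_rates, rate_mode = x$rate_mode,
              meta = x$meta)
}
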