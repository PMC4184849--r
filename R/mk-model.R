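## Binary Mk likelihood machinery: transition probabilities, pruning
## likelihoods (compiled), discrete-gamma rate heterogeneity, and the
## ascertainment-bias corrections for variable-only (Mkv) and
## parsimony-informative-only (Mk-parsinf) character sampling.

#' Inference-side Mk model settings
#'
#' @param ascertainment How character collection was filtered:
#'   `"none"` (uncorrected Mk), `"variable"` (Mkv: condition on characters
#'   being variable) or `"parsimony_informative"` (condition on characters
#'   being parsimony-informative).
#' @param gamma_shape Positive shape of gamma-distributed among-character
#'   rate variation, or `NULL` for a rate-homogeneous likelihood. In
#'   [mk_bayes()] a non-`NULL` value also switches on sampling of the shape
#'   (the value is the chain's starting point).
#' @param n_rate_categories Number of equi-probable discrete-gamma
#'   categories (default 4).
#' @return An object of class `mk_params`.
#' @export
mk_params <- function(ascertainment = c("none", "variable",
                                        "parsimony_informative"),
                      gamma_shape = NULL, n_rate_categories = 4L) {
  ascertainment <- match.arg(ascertainment)
  if (!is.null(gamma_shape)) stopifnot(gamma_shape > 0)
  stopifnot(n_rate_categories >= 1)
  structure(list(ascertainment = ascertainment, gamma_shape = gamma_shape,
                 n_rate_categories = as.integer(n_rate_categories)),
            class = "mk_params")
}

#' Binary Mk transition probability
#'
#' With the rate matrix normalized to one expected change per unit branch
#' length, P(stay) = 1/2 + 1/2 exp(-2t) and P(change) = 1/2 - 1/2 exp(-2t).
#'
#' @param i,j States in `{0, 1}` (vectorized).
#' @param t Branch length in expected changes per character (>= 0).
#' @return Transition probability/ies.
#' @examples
#' binary_transition_probability(0, 1, 0.5) # 0.5 * (1 - exp(-1))
#' @export
binary_transition_probability <- function(i, j, t) {
  stopifnot(all(i %in% 0:1), all(j %in% 0:1))
  if (any(t < 0)) stop("branch length must be non-negative")
  e <- exp(-2 * t)
  ifelse(i == j, 0.5 + 0.5 * e, 0.5 - 0.5 * e)
}

#' Mean-of-category discrete-gamma rates
#'
#' Equi-probable category rates for a gamma(shape, shape) distribution
#' (mean 1), each category represented by its conditional mean.
#'
#' @param shape Positive gamma shape.
#' @param k Number of categories.
#' @return Numeric vector of length `k` with mean 1.
#' @export
discrete_gamma_rates <- function(shape, k = 4L) {
  stopifnot(shape > 0, k >= 1)
  if (k == 1L) return(1)
  q <- qgamma(seq_len(k - 1L) / k, shape = shape, rate = shape)
  pg <- pgamma(q, shape = shape + 1, rate = shape)
  k * diff(c(0, pg, 1))
}

category_rates <- function(params) {
  if (is.null(params$gamma_shape)) return(1)
  discrete_gamma_rates(params$gamma_shape, params$n_rate_categories)
}

## ---- internal pattern plumbing --------------------------------------------

# map "0"/"1"/"?" to 0/1/2 integers
states_to_int <- function(st) {
  out <- matrix(2L, nrow(st), ncol(st))
  out[st == "0"] <- 0L
  out[st == "1"] <- 1L
  bad <- !(st %in% c("0", "1", "?"))
  if (any(bad)) stop("states must be '0', '1' or '?'")
  rownames(out) <- rownames(st)
  out
}

# collapse duplicate site patterns; returns (npat x ntip) matrix + weights
compress_patterns <- function(int_states) {
  keys <- apply(int_states, 2L, paste, collapse = "")
  ux <- !duplicated(keys)
  idx <- match(keys, keys[ux])
  w <- tabulate(idx, nbins = sum(ux))
  list(patterns = t(int_states[, ux, drop = FALSE]), weights = w)
}

# postorder edge list of a phylo for the compiled pruning kernel
phylo_postorder <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  po <- ape::reorder.phylo(tree, "postorder")
  list(edge = po$edge, elen = po$edge.length,
       labels = po$tip.label, ntip = length(po$tip.label))
}

# per-pattern log-likelihoods; patterns is (npat x ntip) in tree tip order
pattern_logliks <- function(post, patterns, params) {
  rates <- category_rates(params)
  mk_pattern_loglik_cpp(post$edge, post$elen, post$ntip,
                        patterns, as.numeric(rates))
}

# the dummy patterns excluded by an ascertainment mode, in tip-index order
excluded_patterns <- function(ntip, mode) {
  if (mode == "none") return(matrix(integer(0), 0, ntip))
  pats <- rbind(rep(0L, ntip), rep(1L, ntip))
  if (mode == "parsimony_informative") {
    for (t in seq_len(ntip)) {
      p0 <- rep(0L, ntip); p0[t] <- 1L
      p1 <- rep(1L, ntip); p1[t] <- 0L
      pats <- rbind(pats, p0, p1)
    }
  }
  unname(pats)
}

## ---- exported likelihood operations ---------------------------------------

#' Likelihood of a single character on a tree
#'
#' Felsenstein pruning with stationary root frequencies (1/2, 1/2);
#' missing entries (`"?"`) contribute the uninformative partial (1, 1).
#' With gamma heterogeneity the conditional likelihood is averaged over the
#' equi-probable category rates. No ascertainment correction is applied
#' here (see [matrix_log_likelihood()]).
#'
#' @param tree Binary `phylo` with branch lengths.
#' @param column Character vector of states (`"0"`, `"1"`, `"?"`), either
#'   named by taxon or in tree tip order.
#' @param params An [mk_params()].
#' @return The site likelihood (probability).
#' @export
site_likelihood <- function(tree, column, params = mk_params()) {
  post <- phylo_postorder(tree)
  if (!is.null(names(column))) {
    if (!setequal(names(column), post$labels))
      stop("column names do not match tree leaves")
    column <- column[post$labels]
  } else if (length(column) != post$ntip) {
    stop("column length does not match number of leaves")
  }
  st <- states_to_int(matrix(column, ncol = 1,
                             dimnames = list(post$labels, NULL)))
  exp(pattern_logliks(post, t(st), params))
}

#' Total probability of the patterns excluded by an ascertainment mode
#'
#' For `"variable"` this is the probability of the two constant patterns;
#' for `"parsimony_informative"` it additionally includes the 2N singleton
#' (autapomorphic) patterns; for `"none"` it is 0. Gamma heterogeneity is
#' averaged inside the per-pattern likelihoods.
#'
#' @param tree Binary `phylo` with branch lengths.
#' @param params An [mk_params()].
#' @return A probability in \[0, 1\].
#' @export
excluded_pattern_probability <- function(tree, params = mk_params()) {
  if (params$ascertainment == "none") return(0)
  post <- phylo_postorder(tree)
  pats <- excluded_patterns(post$ntip, params$ascertainment)
  sum(exp(pattern_logliks(post, pats, params)))
}

#' Ascertainment-corrected log-likelihood of a character matrix
#'
#' Sums per-site log-likelihoods and applies the conditional-likelihood
#' correction for acquisition bias: subtracting
#' `M * log(1 - excluded_pattern_probability)` conditions every one of the
#' M characters on belonging to the collectable (variable or
#' parsimony-informative) set, following the unobserved-character counting
#' construction. The corrected log-likelihood is never smaller than the
#' uncorrected one.
#'
#' @param tree Binary `phylo` with branch lengths whose leaves match the
#'   matrix taxa.
#' @param x A [char_matrix()].
#' @param params An [mk_params()]. A warning is issued when the matrix
#'   visibly contradicts the ascertainment mode (invariant columns under
#'   `"variable"`, uninformative columns under `"parsimony_informative"`);
#'   such misspecification is permitted but not corrected for.
#' @return The log-likelihood (scalar).
#' @export
matrix_log_likelihood <- function(tree, x, params = mk_params()) {
  stopifnot(inherits(x, "char_matrix"))
  post <- phylo_postorder(tree)
  if (!setequal(taxa(x), post$labels))
    stop("matrix taxa do not match tree leaves")
  if (ncol(x$states) == 0L) {
    warning("empty matrix; log-likelihood is 0")
    return(0)
  }
  cls <- classify_characters(x, warn = FALSE)
  if (params$ascertainment == "variable" && any(cls == "invariant"))
    warning("ascertainment 'variable' but matrix contains invariant columns")
  if (params$ascertainment == "parsimony_informative" &&
      any(cls != "parsimony_informative"))
    warning("ascertainment 'parsimony_informative' but matrix contains ",
            "uninformative columns")
  ist <- states_to_int(x$states)[post$labels, , drop = FALSE]
  cp <- compress_patterns(ist)
  ll <- sum(cp$weights * pattern_logliks(post, cp$patterns, params))
  if (params$ascertainment != "none") {
    pex <- excluded_pattern_probability(tree, params)
    if (pex >= 1 - 1e-12)
      stop("excluded-pattern probability is 1 (degenerate tree); ",
           "conditional likelihood undefined")
    ll <- ll - ncol(x$states) * log1p(-pex)
  }
  ll
}
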