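## Synthetic-data generation: model trees with many short branches and a
## fossil subset, and binary-character simulation under the Mk process with
## single-rate or per-character gamma rate heterogeneity.

#' Generate a model tree with many short branches
#'
#' Stand-in for empirical trees used in simulation studies of morphological
#' inference: a random fully resolved rooted topology whose branch lengths
#' are drawn from a right-skewed gamma distribution (shape
#' `1/short_branch_bias`) and rescaled to sum to `total_length`, so larger
#' bias values give many short internal branches. A subset of leaves is
#' flagged as fossil taxa (by default the leaves subtending the shortest
#' terminal branches, mimicking poorly-sampled fossil specimens).
#'
#' @param n_taxa Number of leaves (>= 4; default 75).
#' @param fossil_fraction Fraction of leaves flagged fossil, in \[0, 1);
#'   `ceiling(fossil_fraction * n_taxa)` leaves are flagged.
#' @param total_length Sum of all branch lengths after rescaling. Only the
#'   relative lengths matter to [simulate_characters()], which normalizes
#'   by total tree length.
#' @param short_branch_bias Positive skew parameter; values > 1 concentrate
#'   length in a few branches, leaving many short ones.
#' @param seed Optional integer seed (same seed, same tree).
#' @param fossil_selection `"short_terminal"` (default) flags the leaves
#'   with the shortest pendant edges; `"random"` flags a uniform subset.
#' @return A rooted binary `phylo` with branch lengths and fossil flags
#'   (see [fossil_taxa()]).
#' @examples
#' tr <- generate_model_tree(20, seed = 1)
#' length(bipartitions(tr)) # 17
#' @export
generate_model_tree <- function(n_taxa = 75, fossil_fraction = 0.2,
                                total_length = 1, short_branch_bias = 3,
                                seed = NULL,
                                fossil_selection = c("short_terminal",
                                                     "random")) {
  fossil_selection <- match.arg(fossil_selection)
  if (n_taxa < 4) stop("n_taxa must be >= 4")
  stopifnot(fossil_fraction >= 0, fossil_fraction < 1,
            total_length > 0, short_branch_bias > 0)
  with_seed(seed, {
    phy <- ape::rtopology(n_taxa, rooted = TRUE,
                          tip.label = sprintf("t%02d", seq_len(n_taxa)))
    ne <- nrow(phy$edge)
    len <- rgamma(ne, shape = 1 / short_branch_bias, rate = 1)
    len <- pmax(len, 1e-9)
    phy$edge.length <- len / sum(len) * total_length
    k <- ceiling(fossil_fraction * n_taxa)
    if (k > 0) {
      if (fossil_selection == "random") {
        fos <- sample(phy$tip.label, k)
      } else {
        tipedge <- match(seq_len(n_taxa), phy$edge[, 2L])
        pend <- phy$edge.length[tipedge]
        fos <- phy$tip.label[order(pend, seq_len(n_taxa))[seq_len(k)]]
      }
      fossil_taxa(phy) <- fos
    }
    phy
  })
}

#' Simulation settings for binary Mk characters
#'
#' @param n_characters Number of characters to simulate (the reference
#'   study sizes are 350 and 1000).
#' @param rate_mode `"single"`: one rate draw shared by all characters;
#'   `"per_character"`: independent rate draws (rate heterogeneity).
#' @param gamma_shape Shape of the gamma distribution rates are drawn from
#'   (mean `mean_rate`); `Inf` makes the draw degenerate at `mean_rate`
#'   exactly, which is how grid conditions pin the x-axis rate.
#' @param mean_rate Target expected number of changes per character summed
#'   over the whole tree (so 1 means one expected change per character).
#' @param seed Optional integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_characters = 350,
                       rate_mode = c("single", "per_character"),
                       gamma_shape = 1, mean_rate = 1, seed = NULL) {
  rate_mode <- match.arg(rate_mode)
  stopifnot(n_characters >= 1, mean_rate > 0, gamma_shape > 0)
  structure(list(n_characters = as.integer(n_characters),
                 rate_mode = rate_mode, gamma_shape = gamma_shape,
                 mean_rate = mean_rate, seed = seed),
            class = "sim_config")
}

#' Simulate binary characters along a tree under the Mk process
#'
#' Each character's root state is drawn from the stationary frequencies
#' (1/2, 1/2) and evolved down every branch under the symmetric two-state
#' continuous-time Markov process. A character with rate r expects r
#' changes summed over the whole tree: the effective length of branch b is
#' `b * r / total_tree_length`, and the flip probability along it is
#' `1/2 (1 - exp(-2 t_eff))`.
#'
#' @param tree Rooted binary `phylo` with branch lengths.
#' @param config A [sim_config()].
#' @return A [char_matrix()] whose `true_rates` record the simulating rate
#'   of every character.
#' @export
simulate_characters <- function(tree, config) {
  stopifnot(inherits(tree, "phylo"), inherits(config, "sim_config"))
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  ntip <- length(tree$tip.label)
  nch <- config$n_characters
  tot <- sum(tree$edge.length)
  if (tot <= 0) stop("tree has zero total length")
  with_seed(config$seed, {
    rates <- if (is.finite(config$gamma_shape)) {
      ndraw <- if (config$rate_mode == "single") 1L else nch
      rgamma(ndraw, shape = config$gamma_shape,
             rate = config$gamma_shape / config$mean_rate)
    } else config$mean_rate
    rates <- rep_len(rates, nch)
    if (any(rates <= 0)) stop("simulating rates must be positive")
    po <- ape::reorder.phylo(tree, "postorder")
    nnode <- ntip + po$Nnode
    states <- matrix(NA_integer_, nnode, nch)
    root <- po$edge[nrow(po$edge), 1L]
    states[root, ] <- rbinom(nch, 1L, 0.5)
    for (e in rev(seq_len(nrow(po$edge)))) {  # preorder: parents first
      p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
      pd <- 0.5 * (1 - exp(-2 * po$edge.length[e] * rates / tot))
      flip <- rbinom(nch, 1L, pd)
      states[ch, ] <- bitwXor(states[p, ], flip)
    }
    st <- matrix(as.character(states[seq_len(ntip), , drop = FALSE]),
                 ntip, nch)
    rownames(st) <- po$tip.label
    char_matrix(st, true_rates = rates, rate_mode = config$rate_mode,
                meta = list(mean_rate = config$mean_rate,
                            gamma_shape = config$gamma_shape,
                            seed = config$seed,
                            tree_total_length = tot))
  })
}
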