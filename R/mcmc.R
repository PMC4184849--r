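## Metropolis-Hastings MCMC over topology, branch lengths, and gamma shape
## under the Mk likelihood. Single cold chain.
##
## Moves and Hastings ratios:
##  * NNI: pick a uniform internal edge (u,v), swap one uniform neighbour
##    of u with one of v (branch lengths travel with their subtrees). The
##    proposal is symmetric: HR = 1.
##  * SPR: pick a uniform directed edge (u,v) with u internal; detach the
##    subtree containing v, suppress u (its two incident edges of lengths
##    la, lb fuse into one of length la+lb), then reattach on a uniform
##    edge f of the remaining tree at a uniform point along its length.
##    Forward attachment density 1/l_f, reverse 1/(la+lb), edge-choice
##    counts cancel, so HR = l_f / (la + lb).
##  * Branch-length multiplier: l' = l * m, m = exp(lambda (U - 1/2));
##    HR = m (the usual multiplier Jacobian).
##  * Shape multiplier on the discrete-gamma shape alpha, likewise HR = m.
##
## Priors: iid exponential branch lengths, exponential gamma shape,
## uniform over fully resolved unrooted topologies (constant, so it drops
## out of the acceptance ratio).

#' Bayesian Mk inference of topology, branch lengths and gamma shape
#'
#' Runs a single-chain Metropolis-Hastings sampler under the binary Mk
#' likelihood (with optional ascertainment correction and discrete-gamma
#' rate heterogeneity from `params`) and returns the sampled posterior,
#' summarized by majority-rule consensus via [summarize_posterior()].
#'
#' @param x A [char_matrix()]; in prior-only mode, alternatively a
#'   character vector of taxon labels.
#' @param params An [mk_params()]. A non-`NULL` `gamma_shape` switches on
#'   gamma rate heterogeneity with the shape sampled under its exponential
#'   prior (the supplied value starts the chain).
#' @param n_generations Number of proposals (default 20000, sized for
#'   ~20-taxon problems; scale up for larger trees).
#' @param sample_every Thinning interval for the recorded trace.
#' @param burnin_fraction Default fraction of records discarded by
#'   [summarize_posterior()].
#' @param branch_length_prior_mean Mean of the exponential branch-length
#'   prior (expected changes per character; default 0.1).
#' @param shape_prior_mean Mean of the exponential prior on the gamma
#'   shape (default 1).
#' @param move_weights Named positive weights for moves `nni`, `spr`,
#'   `blen`, `shape` (normalized internally; `shape` is dropped when the
#'   likelihood is rate-homogeneous).
#' @param start_tree Optional starting `phylo` (binary, matching leaf
#'   set); missing branch lengths are drawn from the prior. Default: a
#'   random topology with prior-drawn lengths.
#' @param prior_only If `TRUE` the likelihood is identically 1 and the
#'   chain samples the joint prior (used for sampler validation).
#' @param seed Optional integer seed; the trace is reproducible under it.
#' @return An object of class `mk_bayes` with components `trees` (sampled
#'   newick strings), `trace` (generation, log-likelihood, log-prior,
#'   gamma shape, tree length), and `acceptance` (per-move rates).
#' @seealso [summarize_posterior()], [mk_parsimony()]
#' @export
mk_bayes <- function(x, params = mk_params(),
                     n_generations = 20000L, sample_every = 20L,
                     burnin_fraction = 0.25,
                     branch_length_prior_mean = 0.1,
                     shape_prior_mean = 1.0,
                     move_weights = c(nni = 0.25, spr = 0.15,
                                      blen = 0.5, shape = 0.1),
                     start_tree = NULL, prior_only = FALSE,
                     seed = NULL) {
  stopifnot(n_generations >= 1, sample_every >= 1,
            burnin_fraction >= 0, burnin_fraction < 1,
            branch_length_prior_mean > 0, shape_prior_mean > 0)
  if (prior_only && is.character(x)) {
    labels <- x
  } else {
    stopifnot(inherits(x, "char_matrix"))
    labels <- taxa(x)
    if (!prior_only && ncol(x$states) == 0L)
      stop("empty character matrix; use prior_only = TRUE to sample the prior")
  }
  ntip <- length(labels)
  if (ntip < 4) stop("need at least 4 taxa")
  estimate_gamma <- !is.null(params$gamma_shape)
  ncat <- params$n_rate_categories
  asc <- params$ascertainment

  mw <- move_weights[c("nni", "spr", "blen", if (estimate_gamma) "shape")]
  if (anyNA(mw) || any(mw < 0) || sum(mw) <= 0)
    stop("move_weights must name positive weights for nni, spr, blen, shape")
  mw <- mw / sum(mw)
  lambda_blen <- 2 * log(3)   # multiplier window ~ [1/3, 3]
  lambda_shape <- 2 * log(2)

  out <- with_seed(seed, {
    ## starting state
    if (is.null(start_tree)) {
      phy <- ape::rtopology(ntip, rooted = FALSE, tip.label = labels)
      phy$edge.length <- rexp(nrow(phy$edge), 1 / branch_length_prior_mean)
    } else {
      stopifnot(inherits(start_tree, "phylo"))
      if (!setequal(start_tree$tip.label, labels))
        stop("start_tree leaves do not match the data taxa")
      phy <- start_tree
      if (is.null(phy$edge.length))
        phy$edge.length <- rexp(nrow(phy$edge),
                                1 / branch_length_prior_mean)
      phy$edge.length <- pmax(phy$edge.length, 1e-8)
    }
    ut <- ut_from_phylo(phy)
    alpha <- if (estimate_gamma) params$gamma_shape else NA_real_

    ## data preparation (pattern compression; tip order = ut$labels)
    if (!prior_only) {
      ist <- states_to_int(x$states)[ut$labels, , drop = FALSE]
      cp <- compress_patterns(ist)
      tips_pat <- cp$patterns
      wts <- cp$weights
      M <- ncol(x$states)
      expats <- excluded_patterns(ntip, asc)
    }

    state_loglik <- function(ut, alpha) {
      if (prior_only) return(0)
      po <- ut_postorder(ut)
      rates <- if (estimate_gamma) discrete_gamma_rates(alpha, ncat) else 1
      ll <- sum(wts * mk_pattern_loglik_cpp(po$edge, po$elen, ntip,
                                            tips_pat, as.numeric(rates)))
      if (asc != "none") {
        pex <- sum(exp(mk_pattern_loglik_cpp(po$edge, po$elen, ntip,
                                             expats, as.numeric(rates))))
        if (pex >= 1 - 1e-12) return(-Inf)
        ll <- ll - M * log1p(-pex)
      }
      ll
    }
    state_logprior <- function(ut, alpha) {
      em <- ut_edges(ut)
      lp <- sum(dexp(em[, "len"], rate = 1 / branch_length_prior_mean,
                     log = TRUE))
      if (estimate_gamma)
        lp <- lp + dexp(alpha, rate = 1 / shape_prior_mean, log = TRUE)
      lp
    }

    cur_ll <- state_loglik(ut, alpha)
    cur_lp <- state_logprior(ut, alpha)
    if (!is.finite(cur_ll) || !is.finite(cur_lp))
      stop("starting state has non-finite log-posterior (log-likelihood = ",
           format(cur_ll), ", log-prior = ", format(cur_lp), ")")

    nsamp <- floor(n_generations / sample_every) + 1L
    tr_gen <- integer(nsamp); tr_ll <- tr_lp <- tr_alpha <- tr_tl <-
      numeric(nsamp)
    tr_nwk <- character(nsamp)
    record <- function(k, gen) {
      tr_gen[k] <<- gen; tr_ll[k] <<- cur_ll; tr_lp[k] <<- cur_lp
      tr_alpha[k] <<- alpha
      tr_tl[k] <<- sum(ut_edges(ut)[, "len"])
      tr_nwk[k] <<- ut_newick(ut)
    }
    record(1L, 0L)
    k <- 1L
    prop_n <- acc_n <- stats::setNames(integer(length(mw)), names(mw))

    for (gen in seq_len(n_generations)) {
      move <- names(mw)[sample.int(length(mw), 1L, prob = mw)]
      loghr <- 0
      new_ut <- ut; new_alpha <- alpha
      if (move == "nni") {
        em <- ut_edges(ut)
        em <- em[em[, "u"] > ntip & em[, "v"] > ntip, , drop = FALSE]
        r <- em[sample.int(nrow(em), 1L), ]
        u <- as.integer(r[["u"]]); v <- as.integer(r[["v"]])
        ca <- ut$adj[[u]][ut$adj[[u]] != v]
        cc <- ut$adj[[v]][ut$adj[[v]] != u]
        a <- ca[sample.int(2L, 1L)]
        cc <- cc[sample.int(2L, 1L)]
        la <- ut_edge_length(ut, u, a)
        lc <- ut_edge_length(ut, v, cc)
        new_ut <- ut_disconnect(ut, u, a)
        new_ut <- ut_disconnect(new_ut, v, cc)
        new_ut <- ut_connect(new_ut, u, cc, lc)
        new_ut <- ut_connect(new_ut, v, a, la)
      } else if (move == "spr") {
        em <- ut_edges(ut)
        du <- c(em[em[, "u"] > ntip, "u"], em[em[, "v"] > ntip, "v"])
        dv <- c(em[em[, "u"] > ntip, "v"], em[em[, "v"] > ntip, "u"])
        i <- sample.int(length(du), 1L)
        u <- du[i]; v <- dv[i]
        luv <- ut_edge_length(ut, u, v)
        new_ut <- ut_disconnect(ut, u, v)
        new_ut <- ut_suppress(new_ut, u)
        fused <- attr(new_ut, "fused")
        comp <- ut_component(new_ut, fused$a)
        te <- ut_edges_within(new_ut, comp)
        r <- te[sample.int(nrow(te), 1L), ]
        w <- runif(1)
        new_ut <- ut_subdivide(new_ut, as.integer(r[["u"]]),
                               as.integer(r[["v"]]), u, w)
        new_ut <- ut_connect(new_ut, u, v, luv)
        loghr <- log(r[["len"]]) - log(fused$la + fused$lb)
      } else if (move == "blen") {
        em <- ut_edges(ut)
        r <- em[sample.int(nrow(em), 1L), ]
        m <- exp(lambda_blen * (runif(1) - 0.5))
        new_ut <- ut_set_length(ut, as.integer(r[["u"]]),
                                as.integer(r[["v"]]), r[["len"]] * m)
        loghr <- log(m)
      } else { # shape
        m <- exp(lambda_shape * (runif(1) - 0.5))
        new_alpha <- alpha * m
        loghr <- log(m)
      }
      prop_n[move] <- prop_n[move] + 1L
      new_ll <- state_loglik(new_ut, new_alpha)
      new_lp <- state_logprior(new_ut, new_alpha)
      lratio <- (new_ll + new_lp) - (cur_ll + cur_lp) + loghr
      if (is.finite(new_ll + new_lp) && log(runif(1)) < lratio) {
        ut <- new_ut; alpha <- new_alpha
        cur_ll <- new_ll; cur_lp <- new_lp
        acc_n[move] <- acc_n[move] + 1L
      }
      if (gen %% sample_every == 0L) {
        k <- k + 1L
        record(k, gen)
      }
    }

    list(trees = tr_nwk[seq_len(k)],
         trace = data.frame(generation = tr_gen[seq_len(k)],
                            log_likelihood = tr_ll[seq_len(k)],
                            log_prior = tr_lp[seq_len(k)],
                            gamma_shape = tr_alpha[seq_len(k)],
                            tree_length = tr_tl[seq_len(k)]),
         acceptance = data.frame(move = names(mw),
                                 proposed = as.integer(prop_n),
                                 accepted = as.integer(acc_n),
                                 rate = ifelse(prop_n > 0,
                                               acc_n / pmax(prop_n, 1L),
                                               NA_real_),
                                 row.names = NULL))
  })

  structure(c(out, list(n_generations = as.integer(n_generations),
                        sample_every = as.integer(sample_every),
                        burnin_fraction = burnin_fraction,
                        params = params, prior_only = prior_only,
                        taxa = labels,
                        priors = list(
                          branch_length_mean = branch_length_prior_mean,
                          shape_mean = shape_prior_mean),
                        seed = seed, call = match.call())),
            class = "mk_bayes")
}

#' Summarize a posterior sample by majority-rule consensus
#'
#' Discards the first `burnin_fraction` of the recorded samples and
#' returns the majority-rule consensus of the retained trees together with
#' the frequency of every observed split.
#'
#' @param fit An `mk_bayes` object.
#' @param burnin_fraction Fraction of records to discard (default: the
#'   value stored in the fit).
#' @return A list of class `mk_posterior` with `consensus` (a `phylo`,
#'   possibly with polytomies), `split_frequencies` (data frame), and
#'   `n_trees` retained.
#' @export
summarize_posterior <- function(fit, burnin_fraction = NULL) {
  stopifnot(inherits(fit, "mk_bayes"))
  if (is.null(burnin_fraction)) burnin_fraction <- fit$burnin_fraction
  stopifnot(burnin_fraction >= 0, burnin_fraction < 1)
  n <- length(fit$trees)
  keep <- seq.int(floor(burnin_fraction * n) + 1L, n)
  if (!length(keep)) stop("no post-burnin samples retained")
  trees <- posterior_trees(fit, keep)
  structure(list(consensus = majority_rule_consensus(trees),
                 split_frequencies = split_frequencies(trees),
                 n_trees = length(trees),
                 burnin_fraction = burnin_fraction),
            class = "mk_posterior")
}

# parse stored newick samples back into phylo objects
posterior_trees <- function(fit, which = seq_along(fit$trees)) {
  txt <- paste(fit$trees[which], collapse = "\n")
  tr <- ape::read.tree(text = txt)
  if (inherits(tr, "phylo")) list(tr) else unclass(tr)
}

#' @export
print.mk_posterior <- function(x, ...) {
  cat("Majority-rule consensus of", x$n_trees, "posterior trees",
      sprintf("(burn-in %.0f%%)\n", 100 * x$burnin_fraction))
  cat("  consensus splits:", sum(x$split_frequencies$freq > 0.5), "\n")
  top <- head(x$split_frequencies[, c("split", "freq")], 8L)
  if (nrow(top)) {
    cat("  top split frequencies:\n")
    for (i in seq_len(nrow(top)))
      cat(sprintf("    %.3f  {%s}\n", top$freq[i], top$split[i]))
  }
  invisible(x)
}

#' @export
print.mk_bayes <- function(x, ...) {
  cat("Bayesian Mk fit", if (x$prior_only) "(prior-only)", "\n")
  cat("  taxa:", length(x$taxa),
      " generations:", x$n_generations,
      " samples:", length(x$trees), "\n")
  cat("  ascertainment:", x$params$ascertainment,
      " gamma:", if (is.null(x$params$gamma_shape)) "off"
                 else paste0(x$params$n_rate_categories, " categories"), "\n")
  if (!x$prior_only) {
    post <- x$trace$log_likelihood[-seq_len(
      floor(x$burnin_fraction * nrow(x$trace)))]
    cat(sprintf("  mean post-burnin log-likelihood: %.2f\n", mean(post)))
  }
  cat("  acceptance rates:",
      paste(sprintf("%s %.2f", x$acceptance$move, x$acceptance$rate),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.mk_bayes <- function(object, burnin_fraction = NULL, ...) {
  print(object)
  s <- summarize_posterior(object, burnin_fraction)
  print(s)
  invisible(s)
}

#' @export
logLik.mk_bayes <- function(object, ...) {
  n <- nrow(object$trace)
  post <- object$trace$log_likelihood[-seq_len(
    floor(object$burnin_fraction * n))]
  structure(mean(post), df = NA_integer_, class = "logLik")
}

#' @export
plot.mk_bayes <- function(x, ...) {
  plot(x$trace$generation, x$trace$log_likelihood, type = "l",
       xlab = "generation", ylab = "log-likelihood",
       main = "MCMC trace", ...)
  invisible(x)
}

#' Maximum split-frequency disagreement between two fits
#'
#' Convergence diagnostic in the spirit of comparing independent runs:
#' the largest absolute difference in posterior split frequencies between
#' two chains run on the same data with different seeds.
#'
#' @param fit1,fit2 `mk_bayes` objects on the same taxa.
#' @return The maximum absolute split-frequency difference.
#' @export
split_freq_agreement <- function(fit1, fit2) {
  s1 <- summarize_posterior(fit1)$split_frequencies
  s2 <- summarize_posterior(fit2)$split_frequencies
  keys <- union(s1$key, s2$key)
  f1 <- s1$freq[match(keys, s1$key)]; f1[is.na(f1)] <- 0
  f2 <- s2$freq[match(keys, s2$key)]; f2[is.na(f2)] <- 0
  if (!length(keys)) return(0)
  max(abs(f1 - f2))
}
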