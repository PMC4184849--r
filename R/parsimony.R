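## Equal-weights parsimony engine: Fitch scoring with missing data,
## random-addition starting trees, TBR branch swapping with retention of
## equally optimal topologies.

# tip state-set bitmasks (1={0}, 2={1}, 3={0,1}) in a given taxon order
states_to_masks <- function(st) {
  out <- matrix(3L, nrow(st), ncol(st))
  out[st == "0"] <- 1L
  out[st == "1"] <- 2L
  rownames(out) <- rownames(st)
  out
}

# compress mask columns into patterns (npat x ntip) + weights
compress_masks <- function(masks) {
  keys <- apply(masks, 2L, paste, collapse = "")
  ux <- !duplicated(keys)
  idx <- match(keys, keys[ux])
  list(patterns = t(masks[, ux, drop = FALSE]),
       weights = as.numeric(tabulate(idx, nbins = sum(ux))))
}

# Fitch score of a utree given pattern data aligned to its tip ids
fitch_ut <- function(ut, pat) {
  po <- ut_postorder(ut)
  fitch_score_cpp(po$edge, ut$ntip, pat$patterns, pat$weights)
}

#' Fitch parsimony score of a character matrix on a tree
#'
#' Minimum number of state changes summed over characters under equal
#' weights; `"?"` tips carry the full state set. The score does not depend
#' on rooting.
#'
#' @param tree Fully resolved `phylo` whose leaves match the matrix taxa.
#' @param x A [char_matrix()] (an empty matrix scores 0 with a warning).
#' @return Non-negative integer score.
#' @export
fitch_score <- function(tree, x) {
  stopifnot(inherits(tree, "phylo"), inherits(x, "char_matrix"))
  if (ncol(x$states) == 0L) {
    warning("empty matrix; parsimony score is 0")
    return(0L)
  }
  ut <- ut_from_phylo(tree, default_len = 1)
  if (!setequal(taxa(x), ut$labels))
    stop("matrix taxa do not match tree leaves")
  masks <- states_to_masks(x$states)[ut$labels, , drop = FALSE]
  as.integer(fitch_ut(ut, compress_masks(masks)))
}

# star utree on the first three shuffled taxa; ids: tips 1..ntip in `labels`
# order, internals ntip+1.. allocated as taxa are added
ut_start3 <- function(labels, first3) {
  ntip <- length(labels)
  n_nodes <- 2L * ntip - 2L
  adj <- rep(list(integer(0)), n_nodes)
  len <- rep(list(numeric(0)), n_nodes)
  ut <- list(ntip = ntip, labels = labels, adj = adj, len = len)
  hub <- ntip + 1L
  for (t in first3) ut <- ut_connect(ut, hub, t, 1)
  ut
}

#' Random-addition starting tree
#'
#' Shuffles the taxa and inserts them stepwise, each on the edge that
#' minimizes the Fitch score of the growing tree (ties broken uniformly at
#' random). This is the classic random-addition-sequence starting tree for
#' branch swapping.
#'
#' @param x A [char_matrix()] with at least 4 taxa.
#' @param seed Optional integer seed (same seed, same tree).
#' @return A fully resolved unrooted `phylo` (no branch lengths).
#' @export
random_addition_tree <- function(x, seed = NULL) {
  stopifnot(inherits(x, "char_matrix"))
  labels <- taxa(x)
  if (length(labels) < 4) stop("need at least 4 taxa")
  masks_full <- states_to_masks(x$states)
  with_seed(seed, {
    ut <- random_addition_ut(labels, masks_full)
    ut_to_phylo(ut, branch_lengths = FALSE)
  })
}

# workhorse (no seed handling); masks_full rows named by taxon
random_addition_ut <- function(labels, masks_full) {
  ntip <- length(labels)
  ord <- sample.int(ntip)
  ut <- ut_start3(labels, ord[1:3])
  next_internal <- ntip + 2L
  present <- ord[1:3]
  for (step in 4:ntip) {
    tnew <- ord[step]
    present <- c(present, tnew)
    # data restricted to taxa present so far (tip ids unchanged)
    sub <- masks_full[ut$labels[present], , drop = FALSE]
    pat <- compress_masks(sub)
    # remap rows: patterns are (npat x |present|) in `present` order; the
    # Fitch kernel needs columns indexed by tip id 1..ntip. Build a full
    # width matrix with absent taxa missing (mask 3) - they are leaves of
    # degree 0, unreachable, so the postorder never touches them.
    full <- matrix(3L, nrow(pat$patterns), ntip)
    full[, present] <- pat$patterns
    pat$patterns <- full
    em <- ut_edges(ut)
    best <- Inf; best_edges <- list()
    for (i in seq_len(nrow(em))) {
      u <- as.integer(em[i, "u"]); v <- as.integer(em[i, "v"])
      ut2 <- ut_subdivide(ut, u, v, next_internal)
      ut2 <- ut_connect(ut2, next_internal, tnew, 1)
      s <- fitch_score_cpp(ut_postorder_from(ut2, tnew)$edge, ntip,
                           pat$patterns, pat$weights)
      if (s < best - 1e-9) { best <- s; best_edges <- list(c(u, v)) }
      else if (s <= best + 1e-9) best_edges <- c(best_edges, list(c(u, v)))
    }
    pick <- best_edges[[sample.int(length(best_edges), 1L)]]
    ut <- ut_subdivide(ut, pick[1L], pick[2L], next_internal)
    ut <- ut_connect(ut, next_internal, tnew, 1)
    next_internal <- next_internal + 1L
  }
  ut
}

# postorder rooted at an arbitrary present leaf (partial trees during
# stepwise addition do not contain leaf 1)
ut_postorder_from <- function(ut, root) {
  n_nodes <- length(ut$adj)
  visited <- logical(n_nodes)
  parent <- integer(n_nodes)
  bfs <- integer(n_nodes)
  bfs[1L] <- root; visited[root] <- TRUE
  cnt <- 1L; i <- 1L
  while (i <= cnt) {
    v <- bfs[i]
    for (w in ut$adj[[v]]) if (!visited[w]) {
      visited[w] <- TRUE; parent[w] <- v; cnt <- cnt + 1L; bfs[cnt] <- w
    }
    i <- i + 1L
  }
  ord <- rev(bfs[seq_len(cnt)])
  ord <- ord[ord != root]
  list(edge = cbind(parent[ord], ord), root = root)
}

## ---- TBR neighbourhood ----------------------------------------------------

# Enumerate TBR move descriptors: bisect every edge; reconnect every edge
# pair across the two fragments. Pendant-edge bisections reduce to leaf
# SPR. The no-op reconnection (both merged edges) is skipped.
tbr_moves <- function(ut) {
  ntip <- ut$ntip
  em <- ut_edges(ut)
  moves <- vector("list", 0L)
  for (i in seq_len(nrow(em))) {
    u <- as.integer(em[i, "u"]); v <- as.integer(em[i, "v"])
    if (u <= ntip) { tmp <- u; u <- v; v <- tmp }   # ensure u internal
    if (u <= ntip) next                             # both leaves: impossible N>=4
    if (v <= ntip) {
      # pendant bisection: fragment2 = leaf v
      cut <- ut_disconnect(ut, u, v)
      cut <- ut_suppress(cut, u)
      fused <- attr(cut, "fused")
      e1 <- ut_edges_within(cut, ut_component(cut, fused$a))
      for (a in seq_len(nrow(e1))) {
        f1 <- as.integer(e1[a, c("u", "v")])
        if (setequal(f1, c(fused$a, fused$b))) next  # recreates original
        moves[[length(moves) + 1L]] <-
          list(type = 1L, u = u, v = v, f1 = f1)
      }
    } else {
      cut <- ut_disconnect(ut, u, v)
      cut <- ut_suppress(cut, u)
      fu <- attr(cut, "fused")
      cut <- ut_suppress(cut, v)
      fv <- attr(cut, "fused")
      comp1 <- ut_component(cut, fu$a)
      e1 <- ut_edges_within(cut, comp1)
      e2 <- ut_edges_within(cut, ut_component(cut, fv$a))
      for (a in seq_len(nrow(e1))) {
        f1 <- as.integer(e1[a, c("u", "v")])
        same1 <- setequal(f1, c(fu$a, fu$b))
        for (b in seq_len(nrow(e2))) {
          f2 <- as.integer(e2[b, c("u", "v")])
          if (same1 && setequal(f2, c(fv$a, fv$b))) next
          moves[[length(moves) + 1L]] <-
            list(type = 2L, u = u, v = v, f1 = f1, f2 = f2)
        }
      }
    }
  }
  moves
}

tbr_apply <- function(ut, mv) {
  luv <- ut_edge_length(ut, mv$u, mv$v)
  ut2 <- ut_disconnect(ut, mv$u, mv$v)
  ut2 <- ut_suppress(ut2, mv$u)
  if (mv$type == 2L) ut2 <- ut_suppress(ut2, mv$v)
  ut2 <- ut_subdivide(ut2, mv$f1[1L], mv$f1[2L], mv$u)
  if (mv$type == 2L)
    ut2 <- ut_subdivide(ut2, mv$f2[1L], mv$f2[2L], mv$v)
  ut_connect(ut2, mv$u, mv$v, luv)
}

#' Parsimony tree search with random addition and TBR swapping
#'
#' For each replicate, builds a random-addition starting tree and
#' hill-climbs by first-improvement over the (randomly ordered) TBR
#' neighbourhood until no neighbour improves the Fitch score. Equally
#' optimal topologies encountered along the way are pooled across
#' replicates; the result is the set of distinct topologies attaining the
#' pooled best score, deduplicated by bipartition-set identity and capped
#' at `max_trees` (a warning notes truncation).
#'
#' @param x A [char_matrix()] with at least 4 taxa.
#' @param n_replicates Number of random-addition replicates (the reference
#'   analyses use 1000; desk-scale runs use far fewer).
#' @param swap `"tbr"` (default) or `"none"` (keep the addition trees).
#' @param max_trees Cap on the retained equally-optimal set.
#' @param seed Optional integer seed.
#' @return An object of class `mk_parsimony` with `trees` (list of
#'   `phylo`), `score`, `n_trees`, and `truncated`.
#' @seealso [score_solution_set()], [mk_bayes()]
#' @export
mk_parsimony <- function(x, n_replicates = 10L,
                         swap = c("tbr", "none"),
                         max_trees = 1000L, seed = NULL) {
  swap <- match.arg(swap)
  stopifnot(inherits(x, "char_matrix"), n_replicates >= 1, max_trees >= 1)
  labels <- taxa(x)
  if (length(labels) < 4) stop("need at least 4 taxa")
  if (ncol(x$states) == 0L) warning("empty matrix; all trees score 0")
  masks_full <- states_to_masks(x$states)
  pool <- new.env(hash = TRUE, parent = emptyenv())  # signature -> newick
  pool_score <- new.env(hash = TRUE, parent = emptyenv())
  overflow <- FALSE
  pool_n <- 0L
  add_tree <- function(ut, s, always = FALSE) {
    if (!always && pool_n >= 5L * max_trees) { overflow <<- TRUE; return() }
    sig <- ut_signature(ut)
    if (is.null(pool_score[[sig]])) {
      pool[[sig]] <- ut_newick(ut, branch_lengths = FALSE)
      pool_score[[sig]] <- s
      pool_n <<- pool_n + 1L
    }
  }
  best_overall <- Inf
  with_seed(seed, {
    for (rep in seq_len(n_replicates)) {
      ut <- random_addition_ut(labels, masks_full)
      pat <- compress_masks(masks_full[ut$labels, , drop = FALSE])
      s <- fitch_ut(ut, pat)
      if (swap == "tbr") {
        repeat {
          improved <- FALSE
          mvs <- tbr_moves(ut)
          for (mi in sample.int(length(mvs))) {
            ut2 <- tbr_apply(ut, mvs[[mi]])
            s2 <- fitch_ut(ut2, pat)
            if (s2 < s) {
              ut <- ut2; s <- s2; improved <- TRUE
              break
            } else if (s2 == s && s2 <= best_overall) {
              add_tree(ut2, s2)
            }
          }
          if (!improved) break
        }
      }
      add_tree(ut, s, always = TRUE)
      if (s < best_overall) best_overall <- s
    }
  })
  sigs <- ls(pool)
  scores <- vapply(sigs, function(k) pool_score[[k]], numeric(1))
  keep <- sigs[scores <= best_overall]
  truncated <- overflow || length(keep) > max_trees
  if (truncated) {
    warning("equally-optimal set truncated at max_trees = ", max_trees)
    keep <- head(keep, max_trees)
  }
  trees <- lapply(keep, function(k) ape::read.tree(text = pool[[k]]))
  structure(list(trees = trees, score = best_overall,
                 n_trees = length(trees), truncated = truncated,
                 n_replicates = as.integer(n_replicates), swap = swap,
                 taxa = labels, seed = seed, call = match.call()),
            class = "mk_parsimony")
}

#' @export
print.mk_parsimony <- function(x, ...) {
  cat("Parsimony fit (", x$swap, " swapping, ", x$n_replicates,
      " random-addition replicates)\n", sep = "")
  cat("  best score:", x$score, "  equally optimal trees:", x$n_trees,
      if (x$truncated) "(truncated)", "\n")
  invisible(x)
}

#' @export
summary.mk_parsimony <- function(object, ...) {
  print(object)
  if (object$n_trees > 1) {
    cons <- majority_rule_consensus(object$trees)
    cat("  consensus splits:", length(split_keys(cons)), "of",
        length(object$taxa) - 3L, "\n")
  }
  invisible(object)
}

#' Score a set of equally optimal trees against the model tree
#'
#' Returns both summaries used for parsimony solution sets: the symmetric
#' distance averaged over the trees, and the symmetric distance of their
#' majority-rule consensus.
#'
#' @param trees A list of `phylo` objects, or an `mk_parsimony` fit.
#' @param true_tree The model tree (same leaf set).
#' @return List with `mean_rf`, `consensus_rf`, and the corresponding
#'   rescaled errors `mean_error_pct`, `consensus_error_pct`.
#' @export
score_solution_set <- function(trees, true_tree) {
  if (inherits(trees, "mk_parsimony")) trees <- trees$trees
  trees <- as_tree_list(trees)
  n <- length(true_tree$tip.label)
  rfs <- vapply(trees, rf_distance, numeric(1), t2 = true_tree)
  cons <- majority_rule_consensus(trees)
  crf <- rf_distance(cons, true_tree)
  list(mean_rf = mean(rfs), consensus_rf = crf,
       mean_error_pct = rescaled_error(mean(rfs), n),
       consensus_error_pct = rescaled_error(crf, n))
}
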