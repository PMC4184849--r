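# Independent oracles used across the suite. All are deliberately
# brute-force (enumeration / closed form) and share no code with the
# implementation paths they check.

# site likelihood by exhaustive enumeration over the states of all
# internal nodes and all missing tips (rates: gamma-category multipliers,
# averaged with equal weight)
enum_site_likelihood <- function(tree, column, rates = 1) {
  phy <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  root <- phy$edge[nrow(phy$edge), 1L]
  if (!is.null(names(column))) column <- column[phy$tip.label]
  known <- integer(ntip + nnode) * NA_integer_
  known[seq_len(ntip)] <- suppressWarnings(
    ifelse(column == "?", NA_integer_, as.integer(column)))
  free <- which(is.na(known))
  total <- 0
  for (r in rates) {
    tot_r <- 0
    for (mask in 0:(2^length(free) - 1)) {
      s <- known
      s[free] <- bitwAnd(bitwShiftR(mask, seq_along(free) - 1L), 1L)
      p <- 0.5  # root frequency
      for (e in seq_len(nrow(phy$edge))) {
        t_eff <- phy$edge.length[e] * r
        same <- s[phy$edge[e, 1L]] == s[phy$edge[e, 2L]]
        p <- p * (0.5 + (if (same) 0.5 else -0.5) * exp(-2 * t_eff))
      }
      tot_r <- tot_r + p
    }
    total <- total + tot_r / length(rates)
  }
  total
}

# Fitch score of one column by minimizing over all internal-node states
# and all states of '?' tips
brute_fitch_column <- function(tree, column) {
  phy <- ape::reorder.phylo(ape::unroot(tree), "postorder")
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  if (!is.null(names(column))) column <- column[phy$tip.label]
  known <- rep(NA_integer_, ntip + nnode)
  known[seq_len(ntip)] <- suppressWarnings(
    ifelse(column == "?", NA_integer_, as.integer(column)))
  free <- which(is.na(known))
  best <- Inf
  for (mask in 0:(2^length(free) - 1)) {
    s <- known
    s[free] <- bitwAnd(bitwShiftR(mask, seq_along(free) - 1L), 1L)
    ch <- sum(s[phy$edge[, 1L]] != s[phy$edge[, 2L]])
    if (ch < best) best <- ch
  }
  best
}

brute_fitch <- function(tree, x) {
  st <- as.matrix(x)
  sum(vapply(seq_len(ncol(st)), function(j) {
    col <- st[, j]; names(col) <- rownames(st)
    brute_fitch_column(tree, col)
  }, numeric(1)))
}

# non-trivial bipartitions by explicit edge removal + BFS on an adjacency
# list (independent of the implementation's postorder accumulation)
bip_oracle <- function(tree) {
  phy <- ape::unroot(tree)
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  adj <- rep(list(integer(0)), nn)
  for (e in seq_len(nrow(phy$edge))) {
    a <- phy$edge[e, 1L]; b <- phy$edge[e, 2L]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  out <- list()
  for (e in seq_len(nrow(phy$edge))) {
    a <- phy$edge[e, 1L]; b <- phy$edge[e, 2L]
    # BFS from b with the removed edge (a,b) blocked
    seen <- logical(nn); seen[b] <- TRUE; q <- b
    while (length(q)) {
      v <- q[1L]; q <- q[-1L]
      for (w in adj[[v]]) {
        if ((v == a && w == b) || (v == b && w == a)) next
        if (!seen[w]) { seen[w] <- TRUE; q <- c(q, w) }
      }
    }
    blk <- sort(phy$tip.label[which(seen[seq_len(ntip)])])
    if (length(blk) >= 2 && length(blk) <= ntip - 2)
      out[[length(out) + 1L]] <- blk
  }
  unique(out)
}

# small random character matrix (entries 0/1/? with given missing rate)
rand_cm <- function(taxa, nchar, p_missing = 0, seed = NULL) {
  mkmorph:::with_seed(seed, {
    st <- matrix(sample(c("0", "1"), length(taxa) * nchar, replace = TRUE),
                 length(taxa), nchar, dimnames = list(taxa, NULL))
    if (p_missing > 0)
      st[runif(length(st)) < p_missing] <- "?"
    char_matrix(st)
  })
}

# every binary pattern on n taxa as a character matrix column list
all_patterns <- function(n) {
  lapply(0:(2^n - 1), function(mask)
    as.character(bitwAnd(bitwShiftR(mask, seq_len(n) - 1L), 1L)))
}

# canonical split-set signature of a tree
topo_signature <- function(tree) {
  paste(sort(mkmorph:::split_keys(tree)), collapse = ";")
}
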