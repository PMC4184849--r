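## Internal unrooted-tree representation used by the samplers.
##
## A "utree" is an adjacency-list form of an unrooted binary tree: node ids
## 1..ntip are leaves (in the order of `labels`), ids ntip+1..2*ntip-2 are
## internal (degree 3). `adj[[i]]` holds i's neighbours and `len[[i]]` the
## matching branch lengths (each edge stored in both directions). Node ids
## are stable under the surgery operations (prune/regraft re-use the ids
## they free), which keeps move bookkeeping simple.

ut_from_phylo <- function(phy, default_len = NULL) {
  stopifnot(inherits(phy, "phylo"))
  phy <- ape::unroot(phy)
  ntip <- length(phy$tip.label)
  if (!ape::is.binary(phy))
    stop("tree must be fully resolved (binary)")
  nnode <- ntip + phy$Nnode
  el <- phy$edge.length
  if (is.null(el)) {
    if (is.null(default_len))
      stop("tree has no branch lengths")
    el <- rep_len(default_len, nrow(phy$edge))
  }
  adj <- vector("list", nnode)
  len <- vector("list", nnode)
  for (i in seq_len(nnode)) { adj[[i]] <- integer(0); len[[i]] <- numeric(0) }
  for (e in seq_len(nrow(phy$edge))) {
    a <- phy$edge[e, 1L]; b <- phy$edge[e, 2L]; l <- el[e]
    adj[[a]] <- c(adj[[a]], b); len[[a]] <- c(len[[a]], l)
    adj[[b]] <- c(adj[[b]], a); len[[b]] <- c(len[[b]], l)
  }
  list(ntip = ntip, labels = phy$tip.label, adj = adj, len = len)
}

# Postorder edge list rooted at leaf 1: every internal node then has exactly
# two children, which both the pruning likelihood and the Fitch pass rely on.
ut_postorder <- function(ut) {
  n_nodes <- length(ut$adj)
  root <- 1L
  visited <- logical(n_nodes)
  parent <- integer(n_nodes)
  bfs <- integer(n_nodes)
  bfs[1L] <- root; visited[root] <- TRUE
  cnt <- 1L; i <- 1L
  while (i <= cnt) {
    v <- bfs[i]
    for (w in ut$adj[[v]]) {
      if (!visited[w]) {
        visited[w] <- TRUE
        parent[w] <- v
        cnt <- cnt + 1L
        bfs[cnt] <- w
      }
    }
    i <- i + 1L
  }
  ord <- rev(bfs[seq_len(cnt)])
  ord <- ord[ord != root]
  edge <- cbind(parent[ord], ord)
  elen <- vapply(seq_along(ord), function(k) {
    v <- ord[k]
    ut$len[[v]][match(parent[v], ut$adj[[v]])]
  }, numeric(1))
  list(edge = edge, elen = elen, root = root, n_used = cnt)
}

ut_edges <- function(ut) {
  us <- integer(0); vs <- integer(0); ls <- numeric(0)
  for (u in seq_along(ut$adj)) {
    nb <- ut$adj[[u]]
    sel <- nb > u
    if (any(sel)) {
      us <- c(us, rep.int(u, sum(sel)))
      vs <- c(vs, nb[sel])
      ls <- c(ls, ut$len[[u]][sel])
    }
  }
  cbind(u = us, v = vs, len = ls)
}

ut_edge_length <- function(ut, u, v) ut$len[[u]][match(v, ut$adj[[u]])]

ut_connect <- function(ut, u, v, l) {
  ut$adj[[u]] <- c(ut$adj[[u]], v); ut$len[[u]] <- c(ut$len[[u]], l)
  ut$adj[[v]] <- c(ut$adj[[v]], u); ut$len[[v]] <- c(ut$len[[v]], l)
  ut
}

ut_disconnect <- function(ut, u, v) {
  i <- match(v, ut$adj[[u]]); j <- match(u, ut$adj[[v]])
  ut$adj[[u]] <- ut$adj[[u]][-i]; ut$len[[u]] <- ut$len[[u]][-i]
  ut$adj[[v]] <- ut$adj[[v]][-j]; ut$len[[v]] <- ut$len[[v]][-j]
  ut
}

ut_set_length <- function(ut, u, v, l) {
  ut$len[[u]][match(v, ut$adj[[u]])] <- l
  ut$len[[v]][match(u, ut$adj[[v]])] <- l
  ut
}

# remove a degree-2 node, fusing its two incident edges (lengths add);
# returns the fused edge endpoints and lengths for Hastings bookkeeping
ut_suppress <- function(ut, u) {
  stopifnot(length(ut$adj[[u]]) == 2L)
  a <- ut$adj[[u]][1L]; b <- ut$adj[[u]][2L]
  la <- ut$len[[u]][1L]; lb <- ut$len[[u]][2L]
  ut <- ut_disconnect(ut, u, a)
  ut <- ut_disconnect(ut, u, b)
  ut <- ut_connect(ut, a, b, la + lb)
  attr(ut, "fused") <- list(a = a, b = b, la = la, lb = lb)
  ut
}

# split edge (p,q) at new node `mid`, placing it at fraction w from p
ut_subdivide <- function(ut, p, q, mid, w = 0.5) {
  l <- ut_edge_length(ut, p, q)
  ut <- ut_disconnect(ut, p, q)
  ut <- ut_connect(ut, p, mid, l * w)
  ut <- ut_connect(ut, mid, q, l * (1 - w))
  ut
}

# node ids reachable from `start` in the current adjacency
ut_component <- function(ut, start) {
  n_nodes <- length(ut$adj)
  visited <- logical(n_nodes)
  stack <- start; visited[start] <- TRUE
  out <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    out <- c(out, v)
    for (w in ut$adj[[v]]) if (!visited[w]) { visited[w] <- TRUE; stack <- c(stack, w) }
  }
  out
}

# edges with both endpoints restricted to `nodes`
ut_edges_within <- function(ut, nodes) {
  inset <- logical(length(ut$adj)); inset[nodes] <- TRUE
  em <- ut_edges(ut)
  em[inset[em[, "u"]] & inset[em[, "v"]], , drop = FALSE]
}

# newick string with a trifurcating basal node (standard unrooted form),
# so every branch of the unrooted tree appears exactly once
ut_newick <- function(ut, digits = 10, branch_lengths = TRUE) {
  fmt <- function(l) formatC(l, digits = digits, format = "g")
  rec <- function(v, par) {
    kids <- ut$adj[[v]][ut$adj[[v]] != par]
    body <- if (!length(kids)) ut$labels[v] else {
      inner <- vapply(kids, rec, character(1), par = v)
      paste0("(", paste(inner, collapse = ","), ")")
    }
    if (branch_lengths)
      body <- paste0(body, ":", fmt(ut_edge_length(ut, par, v)))
    body
  }
  root <- ut$adj[[1L]][1L]   # internal node next to leaf 1
  inner <- vapply(ut$adj[[root]], rec, character(1), par = root)
  paste0("(", paste(inner, collapse = ","), ");")
}

ut_to_phylo <- function(ut, branch_lengths = TRUE) {
  ape::read.tree(text = ut_newick(ut, branch_lengths = branch_lengths))
}

# canonical topology signature (sorted split keys) for deduplication
ut_signature <- function(ut) {
  paste(sort(split_keys(ut_to_phylo(ut, branch_lengths = FALSE))),
        collapse = ";")
}
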