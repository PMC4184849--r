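## Tree utilities: newick parsing, bipartitions, Robinson-Foulds distance,
## rescaled topological error, and majority-rule consensus.
##
## Trees are ape "phylo" objects throughout. Topology comparison always
## treats trees as unrooted; model (simulation) trees are rooted and fully
## resolved. Fossil flags are carried as a character attribute "fossil"
## holding a subset of the tip labels (see fossil_taxa()).

#' Parse a newick string into a tree
#'
#' Thin, validating wrapper around [ape::read.tree()]. Malformed strings
#' (unbalanced parentheses, empty input) produce an error naming the
#' offending character position; branch lengths are optional.
#'
#' @param text A newick string (terminated by `;`).
#' @return An object of class `phylo`.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' bipartitions(tr)
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty newick string")
  depth <- 0L
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("malformed newick: unmatched ')' at position ", i)
    }
  }
  if (depth != 0L)
    stop("malformed newick: ", depth, " unclosed '(' by position ",
         length(chars))
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("malformed newick: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("malformed newick: could not parse tree")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  tr
}

#' Serialize a tree to newick
#'
#' @param tree A `phylo` object.
#' @param file Optional path; if `NULL` the newick string is returned.
#' @param branch_lengths Emit branch lengths if present (default `TRUE`).
#' @return The newick string (invisibly when writing to a file).
#' @export
write_newick <- function(tree, file = NULL, branch_lengths = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  if (!branch_lengths) tree$edge.length <- NULL
  s <- ape::write.tree(tree)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Fossil-taxon flags on a tree
#'
#' Fossil taxa are stored as an attribute holding a subset of the tip labels.
#' `mask_fossil_cells()` concentrates missing data in these taxa.
#'
#' @param tree A `phylo` object.
#' @param value Character vector of tip labels to flag as fossils.
#' @return `fossil_taxa()` returns a character vector (possibly empty).
#' @export
fossil_taxa <- function(tree) {
  f <- attr(tree, "fossil")
  if (is.null(f)) character(0) else f
}

#' @rdname fossil_taxa
#' @export
`fossil_taxa<-` <- function(tree, value) {
  stopifnot(inherits(tree, "phylo"), is.character(value))
  bad <- setdiff(value, tree$tip.label)
  if (length(bad))
    stop("fossil labels not in tree: ", paste(bad, collapse = ", "))
  attr(tree, "fossil") <- value
  tree
}

## ---- bipartition machinery ------------------------------------------------

# Canonical split keys for the non-trivial bipartitions of an (un)rooted
# binary tree. A key is the membership string ("0"/"1") of one block over
# sort(tip labels), normalised so the block containing the first sorted
# label is the "1" block. Equal splits therefore compare equal as strings.
split_keys <- function(tree, ref_labels = NULL) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  if (ntip < 4L) return(character(0))
  if (is.null(ref_labels)) ref_labels <- sort(tree$tip.label)
  phy <- ape::unroot(tree)
  phy <- ape::reorder.phylo(phy, "postorder")
  nnode <- ntip + phy$Nnode
  desc <- matrix(FALSE, nnode, ntip)
  pos <- match(phy$tip.label, ref_labels)
  if (anyNA(pos)) stop("tree labels do not match reference label set")
  desc[cbind(seq_len(ntip), pos)] <- TRUE
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1L]; ch <- phy$edge[e, 2L]
    desc[p, ] <- desc[p, ] | desc[ch, ]
  }
  keys <- character(0)
  for (e in seq_len(nrow(phy$edge))) {
    ch <- phy$edge[e, 2L]
    if (ch <= ntip) next          # trivial (pendant) split
    blk <- desc[ch, ]
    k <- sum(blk)
    if (k < 2L || k > ntip - 2L) next
    if (!blk[1L]) blk <- !blk
    keys <- c(keys, paste(as.integer(blk), collapse = ""))
  }
  unique(keys)
}

# expand a key back into its two label blocks
key_to_blocks <- function(key, ref_labels) {
  inb <- strsplit(key, "", fixed = TRUE)[[1L]] == "1"
  list(ref_labels[inb], ref_labels[!inb])
}

#' Non-trivial bipartitions of a tree
#'
#' Removing an internal edge of an unrooted tree splits the leaf set in two;
#' a split is non-trivial when both blocks contain at least two leaves. A
#' fully resolved unrooted tree of N leaves has exactly N - 3 of them.
#'
#' @param tree A `phylo` object (rooted trees are unrooted first).
#' @return A list of bipartitions, each a list of two character vectors
#'   (the leaf-label blocks); empty for trees with fewer than four leaves.
#' @examples
#' length(bipartitions(ape::rtree(75))) # 72
#' @export
bipartitions <- function(tree) {
  ref <- sort(tree$tip.label)
  keys <- split_keys(tree, ref)
  out <- lapply(keys, key_to_blocks, ref_labels = ref)
  attr(out, "keys") <- keys
  out
}

#' Robinson-Foulds (symmetric) distance between two trees
#'
#' Counts the non-trivial bipartitions present in exactly one of the two
#' unrooted topologies: incorrect splits that are present plus correct
#' splits that are absent. For two fully resolved N-leaf trees the maximum
#' is 2(N - 3); unresolved (consensus) trees simply contribute fewer splits.
#'
#' @param t1,t2 `phylo` objects on the same leaf-label set.
#' @return A non-negative integer.
#' @examples
#' t1 <- parse_newick("((A,B),(C,D));")
#' t2 <- parse_newick("((A,C),(B,D));")
#' rf_distance(t1, t2) # 2
#' @export
rf_distance <- function(t1, t2) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  l1 <- sort(t1$tip.label); l2 <- sort(t2$tip.label)
  if (!identical(l1, l2)) {
    only1 <- setdiff(l1, l2); only2 <- setdiff(l2, l1)
    stop("leaf sets differ; only in first: {",
         paste(only1, collapse = ", "), "}; only in second: {",
         paste(only2, collapse = ", "), "}")
  }
  k1 <- split_keys(t1, l1)
  k2 <- split_keys(t2, l1)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

#' Rescale a Robinson-Foulds distance to percent topological error
#'
#' Divides by the maximum symmetric distance 2(N - 3) so that total error is
#' 100 percent (all N - 3 splits wrong in each tree).
#'
#' @param rf Non-negative integer symmetric distance.
#' @param n_taxa Number of leaves N (>= 4).
#' @return Error percentage in \[0, 100\].
#' @examples
#' rescaled_error(144, 75) # 100
#' @export
rescaled_error <- function(rf, n_taxa) {
  stopifnot(length(rf) >= 1, n_taxa >= 4)
  maxrf <- 2 * (n_taxa - 3)
  if (any(rf < 0) || any(rf > maxrf))
    stop("rf out of range [0, ", maxrf, "]")
  100 * rf / maxrf
}

## ---- consensus ------------------------------------------------------------

# Count split keys over a list of trees -> named frequency vector.
split_frequency_keys <- function(trees, ref_labels) {
  counts <- new.env(hash = TRUE, parent = emptyenv())
  for (tr in trees) {
    for (k in split_keys(tr, ref_labels)) {
      cur <- counts[[k]]
      counts[[k]] <- if (is.null(cur)) 1L else cur + 1L
    }
  }
  keys <- ls(counts)
  freq <- vapply(keys, function(k) counts[[k]], integer(1)) / length(trees)
  sort(freq, decreasing = TRUE)
}

#' Split frequencies across a sample of trees
#'
#' @param trees A list of `phylo` objects (or a `multiPhylo`) on one leaf set.
#' @return A data frame with columns `split` (labels of the smaller block),
#'   `freq` (fraction of trees containing the split) and `key` (canonical
#'   membership string), ordered by decreasing frequency.
#' @export
split_frequencies <- function(trees) {
  trees <- as_tree_list(trees)
  ref <- sort(trees[[1L]]$tip.label)
  freq <- split_frequency_keys(trees, ref)
  pretty <- vapply(names(freq), function(k) {
    b <- key_to_blocks(k, ref)
    small <- if (length(b[[1L]]) <= length(b[[2L]])) b[[1L]] else b[[2L]]
    paste(small, collapse = " ")
  }, character(1))
  data.frame(split = unname(pretty), freq = unname(freq),
             key = names(freq), row.names = NULL,
             stringsAsFactors = FALSE)
}

as_tree_list <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (inherits(trees, "multiPhylo")) trees <- unclass(trees)
  stopifnot(length(trees) >= 1, all(vapply(trees, inherits, TRUE, "phylo")))
  ref <- sort(trees[[1L]]$tip.label)
  for (tr in trees)
    if (!identical(sort(tr$tip.label), ref))
      stop("trees must share one leaf-label set")
  trees
}

# Build a phylo from a laminar family of clades (logical vectors over
# ref_labels, none containing ref_labels[1]); used by the consensus.
tree_from_clades <- function(clades, ref_labels) {
  n <- length(ref_labels)
  o <- ref_labels[1L]
  if (length(clades)) {
    sizes <- vapply(clades, sum, integer(1))
    ord <- order(sizes, decreasing = TRUE)
    clades <- clades[ord]; sizes <- sizes[ord]
  }
  nc <- length(clades)
  # parent[i]: smallest clade strictly containing clade i (0 = root)
  parent <- integer(nc)
  for (i in seq_len(nc)) {
    parent[i] <- 0L
    for (j in rev(seq_len(i - 1L))) {  # candidates are larger (earlier)
      if (all(!clades[[i]] | clades[[j]])) { parent[i] <- j; break }
    }
  }
  # leaf home: smallest clade containing it
  leaf_home <- integer(n)  # 0 = root
  for (li in seq_len(n)) {
    leaf_home[li] <- 0L
    if (li == 1L) next
    best <- 0L; best_size <- n + 1L
    for (j in seq_len(nc)) {
      if (clades[[j]][li] && sizes[j] < best_size) { best <- j; best_size <- sizes[j] }
    }
    leaf_home[li] <- best
  }
  build <- function(node) {
    kids_cl <- which(parent == node)
    kids_lf <- which(leaf_home == node)
    parts <- c(vapply(kids_cl, build, character(1)), ref_labels[kids_lf])
    if (node == 0L) parts <- c(o, setdiff(parts, o))
    if (length(parts) == 1L) parts else paste0("(", paste(parts, collapse = ","), ")")
  }
  nw <- paste0(build(0L), ";")
  ape::read.tree(text = nw)
}

#' Majority-rule consensus tree
#'
#' Returns the tree containing exactly the non-trivial splits whose
#' frequency among the input trees strictly exceeds `threshold` (default
#' 0.5, the standard majority rule; splits at exactly 50 percent are
#' excluded). Such splits are pairwise compatible, so the consensus always
#' exists; it may contain polytomies.
#'
#' @param trees List of `phylo` objects (or `multiPhylo`) on one leaf set.
#' @param threshold Split-frequency threshold in \[0.5, 1\]; splits with
#'   frequency strictly greater are retained.
#' @return A `phylo` object, possibly unresolved, without branch lengths.
#'   Split frequencies are reported by [split_frequencies()], not annotated
#'   on the tree.
#' @export
majority_rule_consensus <- function(trees, threshold = 0.5) {
  trees <- as_tree_list(trees)
  stopifnot(threshold >= 0.5, threshold <= 1)
  ref <- sort(trees[[1L]]$tip.label)
  freq <- split_frequency_keys(trees, ref)
  keep <- names(freq)[freq > threshold]
  clades <- lapply(keep, function(k) {
    blk <- strsplit(k, "", fixed = TRUE)[[1L]] == "1"
    !blk  # block NOT containing ref[1] = clade when rooted at ref[1]
  })
  tree_from_clades(clades, ref)
}

#' Read and write NEXUS TREES blocks
#'
#' Wrappers around [ape::read.nexus()] / [ape::write.nexus()]. Translate
#' tables are honoured on read and not emitted on write.
#'
#' @param file Path to a NEXUS file.
#' @param trees A `phylo` or list of `phylo` objects.
#' @return `read_nexus_trees()` returns a list of `phylo` objects.
#' @export
read_nexus_trees <- function(file) {
  tr <- ape::read.nexus(file)
  if (inherits(tr, "phylo")) list(tr) else unclass(tr)
}

#' @rdname read_nexus_trees
#' @export
write_nexus_trees <- function(trees, file) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  ape::write.nexus(trees, file = file, translate = FALSE)
  invisible(file)
}
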