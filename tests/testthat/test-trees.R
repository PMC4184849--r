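# Tree machinery: parsing, bipartitions, RF distance, rescaled error,
# majority-rule consensus.

test_that("newick parsing validates input and round-trips topology", {
  tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  expect_s3_class(tr, "phylo")
  expect_equal(length(bipartitions(tr)), 1L)
  b <- bipartitions(tr)[[1L]]
  expect_setequal(b[[1L]], c("A", "B"))
  expect_setequal(b[[2L]], c("C", "D"))

  expect_error(parse_newick("((A,B):1,(C,D);"), "unclosed")
  expect_error(parse_newick("(A,B))C;"), "position")
  expect_error(parse_newick(""), "empty")
  expect_error(parse_newick("((A,B),(A,C));"), "duplicate")

  # round-trip property on random trees: bipartition sets identical
  for (seed in 1:5) {
    phy <- mkmorph:::with_seed(seed, ape::rtree(12))
    back <- parse_newick(write_newick(phy))
    expect_equal(topo_signature(back), topo_signature(phy))
  }
})

test_that("bipartitions match edge-removal enumeration and count N-3", {
  expect_equal(length(bipartitions(ape::rtree(75))), 72L)
  for (seed in 1:5) {
    phy <- mkmorph:::with_seed(seed, ape::rtree(10))
    got <- bipartitions(phy)
    want <- bip_oracle(phy)
    expect_equal(length(got), 7L)
    # canonicalize each split as the sorted block containing the smallest label
    lo <- min(phy$tip.label)
    canon <- function(b1, b2) {
      blk <- if (lo %in% b1) b1 else b2
      paste(sort(blk), collapse = "|")
    }
    got_keys <- sort(vapply(got, function(b) canon(b[[1]], b[[2]]),
                            character(1)))
    want_keys <- sort(vapply(want, function(w)
      canon(w, setdiff(phy$tip.label, w)), character(1)))
    expect_equal(got_keys, want_keys)
  }
  # fewer than 4 leaves: no non-trivial splits
  expect_length(bipartitions(parse_newick("((A,B),C);")), 0L)
})

test_that("rf_distance agrees with an independent implementation and is a metric", {
  skip_if_not_installed("phangorn")
  t1 <- parse_newick("((A,B),(C,D));")
  t2 <- parse_newick("((A,C),(B,D));")
  expect_equal(rf_distance(t1, t2), 2L)
  expect_equal(rf_distance(t1, t1), 0L)
  for (seed in 1:6) {
    trs <- mkmorph:::with_seed(seed, list(ape::rtree(12), ape::rtree(12),
                                          ape::rtree(12)))
    trs <- lapply(trs, function(t) { t$tip.label <- paste0("x", 1:12); t })
    d12 <- rf_distance(trs[[1]], trs[[2]])
    d21 <- rf_distance(trs[[2]], trs[[1]])
    d13 <- rf_distance(trs[[1]], trs[[3]])
    d23 <- rf_distance(trs[[2]], trs[[3]])
    expect_identical(d12, d21)
    expect_lte(d13, d12 + d23)  # triangle inequality
    expect_lte(d12, 2L * (12L - 3L))
    expect_equal(d12, as.integer(phangorn::RF.dist(trs[[1]], trs[[2]])))
  }
  t3 <- parse_newick("((A,B),(C,E));")
  expect_error(rf_distance(t1, t3), "only in")
})

test_that("rescaled error maps RF onto the 0-100% scale", {
  expect_equal(rescaled_error(144, 75), 100)
  expect_equal(rescaled_error(72, 75), 50)
  expect_equal(rescaled_error(0, 10), 0)
  expect_error(rescaled_error(145, 75), "out of range")
  expect_error(rescaled_error(-1, 75), "out of range")
})

test_that("majority-rule consensus keeps exactly the splits above threshold", {
  t1 <- parse_newick("((A,B),(C,D));")
  t2 <- parse_newick("((A,C),(B,D));")
  cons <- majority_rule_consensus(list(t1, t1, t2))
  expect_equal(rf_distance(cons, t1), 0L)  # {A,B}|{C,D} at 2/3 kept
  star <- majority_rule_consensus(list(t1, t2))  # each split at 1/2: dropped
  expect_length(mkmorph:::split_keys(star), 0L)

  # k identical trees, and near-1 threshold on a single tree
  phy <- mkmorph:::with_seed(3, ape::rtree(9))
  expect_equal(rf_distance(majority_rule_consensus(list(phy, phy, phy)), phy), 0L)
  expect_equal(rf_distance(majority_rule_consensus(list(phy), 0.999), phy), 0L)

  # random samples: every consensus split occurs in > half the trees,
  # and the result matches ape's majority-rule consensus
  for (seed in 1:3) {
    trs <- mkmorph:::with_seed(seed, lapply(1:7, function(i) ape::rtree(8)))
    trs <- lapply(trs, function(t) { t$tip.label <- paste0("x", 1:8); t })
    cons <- majority_rule_consensus(trs)
    freqs <- split_frequencies(trs)
    kept <- mkmorph:::split_keys(cons)
    expect_true(all(freqs$freq[match(kept, freqs$key)] > 0.5))
    ac <- ape::consensus(trs, p = 0.5)
    expect_equal(topo_signature(cons), topo_signature(ac))
  }
  expect_error(majority_rule_consensus(list()), "length")
})

test_that("fossil flags attach to tips and survive validation", {
  tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  fossil_taxa(tr) <- c("A", "C")
  expect_setequal(fossil_taxa(tr), c("A", "C"))
  expect_error(fossil_taxa(tr) <- "Z", "not in tree")
})

test_that("NEXUS tree blocks round-trip through read/write", {
  trs <- mkmorph:::with_seed(4, list(ape::rtree(7), ape::rtree(7)))
  trs <- lapply(trs, function(t) { t$tip.label <- paste0("x", 1:7); t })
  f <- withr::local_tempfile(fileext = ".nex")
  write_nexus_trees(trs, f)
  back <- read_nexus_trees(f)
  expect_length(back, 2L)
  expect_equal(rf_distance(back[[1]], trs[[1]]), 0L)
  expect_equal(rf_distance(back[[2]], trs[[2]]), 0L)
})
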