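# Synthetic data: model-tree generation, Mk character simulation,
# classification, filtration, rate classes, deletion, fossil masking.

test_that("generated model trees honour their contract", {
  tr <- generate_model_tree(75, seed = 1)
  expect_equal(length(bipartitions(tr)), 72L)
  expect_true(ape::is.rooted(tr) && ape::is.binary(tr))
  expect_equal(sum(tr$edge.length), 1, tolerance = 1e-9)
  expect_equal(length(fossil_taxa(tr)), ceiling(0.2 * 75))

  t10 <- generate_model_tree(20, total_length = 10, seed = 2)
  expect_equal(sum(t10$edge.length), 10, tolerance = 1e-9)

  # determinism and seed sensitivity
  expect_identical(write_newick(generate_model_tree(20, seed = 5)),
                   write_newick(generate_model_tree(20, seed = 5)))
  expect_false(identical(write_newick(generate_model_tree(20, seed = 5)),
                         write_newick(generate_model_tree(20, seed = 6))))
  expect_error(generate_model_tree(3), ">= 4")

  # short-branch bias skews the length distribution
  skew <- generate_model_tree(50, short_branch_bias = 5, seed = 3)
  flat <- generate_model_tree(50, short_branch_bias = 1, seed = 3)
  expect_gt(median(flat$edge.length), median(skew$edge.length))
})

test_that("simulation matches the two-state closed form and its limits", {
  # two taxa: P(differ) = (1 - exp(-2t)) / 2 with t the character's
  # expected changes over the whole (two-branch) tree
  t2 <- parse_newick("(A:0.15,B:0.05);")
  x <- simulate_characters(t2, sim_config(10000, "single", Inf,
                                          mean_rate = 0.4, seed = 3))
  pd <- mean(x$states["A", ] != x$states["B", ])
  want <- 0.5 * (1 - exp(-2 * 0.4))
  expect_equal(pd, want, tolerance = 4 * sqrt(want * (1 - want) / 10000) / want)

  # rate -> 0: all columns invariant
  tr <- generate_model_tree(10, seed = 4)
  x0 <- simulate_characters(tr, sim_config(200, "single", Inf, 1e-9, seed = 5))
  expect_true(all(classify_characters(x0) == "invariant"))

  # saturation: any taxon pair differs in ~half the characters
  xs <- simulate_characters(t2, sim_config(10000, "single", Inf, 100, seed = 6))
  expect_equal(mean(xs$states["A", ] != xs$states["B", ]), 0.5,
               tolerance = 0.02)

  # stationarity: pooled state frequencies are (1/2, 1/2)
  xf <- simulate_characters(tr, sim_config(500, "per_character", 1, 2, seed = 7))
  expect_equal(mean(xf$states == "1"), 0.5, tolerance = 0.02)

  # determinism under seed
  xa <- simulate_characters(tr, sim_config(50, "per_character", 1, 1, seed = 8))
  xb <- simulate_characters(tr, sim_config(50, "per_character", 1, 1, seed = 8))
  expect_identical(xa$states, xb$states)
  expect_identical(xa$true_rates, xb$true_rates)
})

test_that("per-character rates overdisperse realized change counts", {
  tr <- generate_model_tree(12, seed = 9)
  n <- 2000
  xs <- simulate_characters(tr, sim_config(n, "single", Inf, 1, seed = 10))
  xh <- simulate_characters(tr, sim_config(n, "per_character", 0.5, 1,
                                           seed = 11))
  # proxy for per-character change count: minimum changes on the true tree
  per_col_changes <- function(x) vapply(seq_len(n), function(j)
    fitch_score(tr, x[, j]), numeric(1))
  expect_gt(var(per_col_changes(xh)), var(per_col_changes(xs)))
})

test_that("character classification follows the informativeness rules", {
  expect_equal(as.character(classify_characters(matrix(c("0","0","0","0"), 4))),
               "invariant")
  expect_equal(as.character(classify_characters(matrix(c("1","0","0","0"), 4))),
               "variable_uninformative")
  expect_equal(as.character(classify_characters(matrix(c("1","1","0","0"), 4))),
               "parsimony_informative")
  # missing entries are ignored in the counts
  expect_equal(as.character(classify_characters(matrix(c("1","1","0","?"), 4))),
               "variable_uninformative")
  expect_warning(cl <- classify_characters(matrix(c("?","?","?","?"), 4)),
                 "all-missing")
  expect_equal(as.character(cl), "invariant")
})

test_that("filtration schemes are nested and preserve rate alignment", {
  tr <- generate_model_tree(10, seed = 12)
  x <- simulate_characters(tr, sim_config(300, "per_character", 1, 1, seed = 13))
  expect_identical(filter_matrix(x, "unfiltered"), x)
  xv <- filter_matrix(x, "variable_only")
  xp <- filter_matrix(x, "parsimony_informative_only")
  expect_true(all(classify_characters(xv) != "invariant"))
  expect_true(all(classify_characters(xp) == "parsimony_informative"))
  expect_lte(ncol(xp$states), ncol(xv$states))
  expect_lte(ncol(xv$states), ncol(x$states))
  # the same column keeps the same rate after filtering
  cls <- classify_characters(x)
  expect_identical(xv$true_rates, x$true_rates[cls != "invariant"])
})

test_that("rate tertiles have near-equal sizes with extras going slow-first", {
  tr <- generate_model_tree(8, seed = 14)
  x350 <- simulate_characters(tr, sim_config(350, "per_character", 1, 1,
                                             seed = 15))
  expect_equal(as.integer(table(assign_rate_classes(x350))),
               c(117L, 117L, 116L))
  x1000 <- simulate_characters(tr, sim_config(1000, "per_character", 1, 1,
                                              seed = 16))
  expect_equal(as.integer(table(assign_rate_classes(x1000))),
               c(334L, 333L, 333L))
  # explicit ordering: sorted ascending by true rate
  x3 <- char_matrix(matrix(c("0","1","0","1","0","1","1","0","0","1","0","1"),
                           4, 3, dimnames = list(letters[1:4], NULL)),
                    true_rates = c(10, 0.1, 1), rate_mode = "per_character")
  expect_equal(as.character(assign_rate_classes(x3)),
               c("fast", "slow", "intermediate"))
  xs <- simulate_characters(tr, sim_config(50, "single", 1, 1, seed = 17))
  expect_error(assign_rate_classes(xs), "single-rate")
})

test_that("rate-class deletion removes round-half-up counts from one class", {
  tr <- generate_model_tree(8, seed = 18)
  x <- simulate_characters(tr, sim_config(350, "per_character", 1, 1,
                                          seed = 19))
  expect_identical(delete_rate_class(x, "slow", 0), x)
  expect_equal(ncol(delete_rate_class(x, "slow", 1, seed = 1)$states), 233L)
  xf <- delete_rate_class(x, "fast", 1 / 3, seed = 2)
  expect_equal(ncol(xf$states), 350L - 39L)  # round(116/3 + 0.5) = 39
  # only fast-class columns were removed; slow/intermediate survive intact
  cls <- assign_rate_classes(x)
  gone <- setdiff(x$true_rates, xf$true_rates)
  expect_true(all(gone %in% x$true_rates[cls == "fast"]))
  expect_true(all(x$true_rates[cls != "fast"] %in% xf$true_rates))
  expect_error(delete_rate_class(x, "slow", 1.2), "fraction")
  # determinism
  expect_identical(delete_rate_class(x, "slow", 0.5, seed = 3)$true_rates,
                   delete_rate_class(x, "slow", 0.5, seed = 3)$true_rates)
})

test_that("fossil masking hits only fossil rows, by label, round-half-up", {
  tr <- generate_model_tree(12, fossil_fraction = 0.25, seed = 20)
  fos <- fossil_taxa(tr)
  expect_equal(length(fos), 3L)
  x <- simulate_characters(tr, sim_config(350, "single", Inf, 1, seed = 21))
  xm <- mask_fossil_cells(x, tr, 0.75, seed = 22)
  qs <- rowSums(xm$states == "?")
  expect_true(all(qs[fos] == 263L))  # round(0.75*350 + 0.5)
  expect_true(all(qs[setdiff(taxa(x), fos)] == 0L))
  expect_identical(mask_fossil_cells(x, tr, 0)$states, x$states)
  xm1 <- mask_fossil_cells(x, tr, 1, seed = 23)
  expect_true(all(xm1$states[fos, ] == "?"))

  # row order of the matrix does not matter: masking is label-based
  perm <- rev(seq_len(nrow(x$states)))
  xp <- x[perm, ]
  xmp <- mask_fossil_cells(xp, tr, 0.75, seed = 22)
  expect_identical(xmp$states[taxa(xm), ], xm$states)

  tr_nofos <- generate_model_tree(12, fossil_fraction = 0, seed = 20)
  expect_error(mask_fossil_cells(x, tr_nofos, 0.5), "no fossil")
})
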