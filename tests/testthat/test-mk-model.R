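# Mk likelihood: transition probabilities, discrete gamma, pruning vs
# exhaustive enumeration, ascertainment corrections.

test_that("transition probabilities match the matrix exponential", {
  expect_equal(binary_transition_probability(0, 0, 0), 1)
  expect_equal(binary_transition_probability(0, 1, 1e9), 0.5)
  expect_equal(binary_transition_probability(0, 1, 0.5),
               0.5 * (1 - exp(-1)))
  expect_error(binary_transition_probability(0, 1, -0.1), "non-negative")

  skip_if_not_installed("Matrix")
  Q <- matrix(c(-1, 1, 1, -1), 2, byrow = TRUE)
  for (t in c(0.05, 0.3, 0.7, 2.2)) {
    P <- as.matrix(Matrix::expm(Q * t))
    expect_equal(binary_transition_probability(0, 0, t), P[1, 1],
                 tolerance = 1e-10)
    expect_equal(binary_transition_probability(0, 1, t), P[1, 2],
                 tolerance = 1e-10)
  }
  # rows sum to 1 and Chapman-Kolmogorov holds
  ts <- c(0.11, 0.47, 1.3)
  for (t1 in ts) for (t2 in ts) {
    p_same <- binary_transition_probability(0, 0, t1) *
      binary_transition_probability(0, 0, t2) +
      binary_transition_probability(0, 1, t1) *
      binary_transition_probability(1, 0, t2)
    expect_equal(p_same, binary_transition_probability(0, 0, t1 + t2),
                 tolerance = 1e-12)
    expect_equal(binary_transition_probability(0, 0, t1) +
                 binary_transition_probability(0, 1, t1), 1)
  }
})

test_that("discrete-gamma category rates have mean 1 and match phangorn", {
  for (shape in c(0.3, 1, 2.5)) {
    r <- discrete_gamma_rates(shape, 4)
    expect_length(r, 4L)
    expect_equal(mean(r), 1, tolerance = 1e-9)
    expect_true(all(diff(r) > 0))
  }
  expect_equal(discrete_gamma_rates(1.7, 1), 1)
  skip_if_not_installed("phangorn")
  expect_equal(discrete_gamma_rates(0.8, 4),
               phangorn::discrete.gamma(0.8, 4), tolerance = 1e-8)
})

test_that("pruning equals exhaustive enumeration on small trees", {
  for (seed in 1:4) {
    for (n in 4:5) {
      phy <- mkmorph:::with_seed(seed, ape::rtree(n))
      for (params in list(mk_params(), mk_params(gamma_shape = 0.7))) {
        rates <- if (is.null(params$gamma_shape)) 1 else
          discrete_gamma_rates(params$gamma_shape, 4)
        pats <- all_patterns(n)
        for (pat in pats[c(1, 2, 2^n - 1, sample.int(2^n, 3))]) {
          col <- structure(pat, names = phy$tip.label)
          expect_equal(site_likelihood(phy, col, params),
                       enum_site_likelihood(phy, col, rates),
                       tolerance = 1e-10)
        }
        # total probability over all patterns is 1
        tot <- sum(vapply(pats, function(p) site_likelihood(
          phy, structure(p, names = phy$tip.label), params), numeric(1)))
        expect_equal(tot, 1, tolerance = 1e-10)
      }
    }
  }
})

test_that("missing data and degenerate trees behave exactly", {
  phy <- parse_newick("((A:0.1,B:0.2):0.15,(C:0.3,D:0.05):0.2);")
  expect_equal(site_likelihood(phy, c(A="?", B="?", C="?", D="?")), 1)
  # partially missing column equals enumeration
  col <- c(A="0", B="?", C="1", D="?")
  expect_equal(site_likelihood(phy, col), enum_site_likelihood(phy, col),
               tolerance = 1e-12)
  # zero-length tree: only the root frequency remains
  z <- parse_newick("((A:0,B:0):0,(C:0,D:0):0);")
  expect_equal(site_likelihood(z, c(A="0", B="0", C="0", D="0")), 0.5)
  # two-taxon closed form by hand enumeration over root states
  t2 <- parse_newick("(A:0.12,B:0.23);")
  expect_equal(site_likelihood(t2, c(A="0", B="1")),
               0.5 * (0.5 - 0.5 * exp(-2 * 0.35)), tolerance = 1e-12)
})

test_that("likelihood is invariant to rerooting", {
  phy <- mkmorph:::with_seed(5, ape::rtree(6))
  x <- rand_cm(phy$tip.label, 20, p_missing = 0.1, seed = 6)
  base <- matrix_log_likelihood(phy, x, mk_params(gamma_shape = 1.2))
  for (og in c(2, 4)) {
    re <- ape::root(ape::unroot(phy), outgroup = og, resolve.root = TRUE)
    expect_equal(matrix_log_likelihood(re, x, mk_params(gamma_shape = 1.2)),
                 base, tolerance = 1e-8)
  }
})

test_that("ascertainment corrections normalize the conditional distribution", {
  for (seed in 1:3) {
    for (n in 4:5) {
      phy <- mkmorph:::with_seed(seed, ape::rtree(n))
      for (gs in list(NULL, 0.9)) {
        pv <- mk_params("variable", gamma_shape = gs)
        pp <- mk_params("parsimony_informative", gamma_shape = gs)
        expect_equal(excluded_pattern_probability(phy, mk_params()), 0)
        pats <- all_patterns(n)
        liks <- vapply(pats, function(p) site_likelihood(
          phy, structure(p, names = phy$tip.label), pv), numeric(1))
        nvar <- vapply(pats, function(p) length(unique(p)) == 1L, logical(1))
        ninf <- vapply(pats, function(p)
          min(table(factor(p, c("0", "1")))) < 2, logical(1))
        # excluded mass matches direct summation of excluded patterns
        expect_equal(excluded_pattern_probability(phy, pv), sum(liks[nvar]),
                     tolerance = 1e-10)
        expect_equal(excluded_pattern_probability(phy, pp), sum(liks[ninf]),
                     tolerance = 1e-10)
        # conditional pattern probabilities sum to 1 over the retained sets
        cond_sum <- function(params, keep) {
          sum(vapply(pats[keep], function(p) {
            cm <- char_matrix(matrix(p, n, 1,
                                     dimnames = list(phy$tip.label, NULL)))
            exp(matrix_log_likelihood(phy, cm, params))
          }, numeric(1)))
        }
        expect_equal(cond_sum(pv, !nvar), 1, tolerance = 1e-8)
        expect_equal(cond_sum(pp, !ninf), 1, tolerance = 1e-8)
      }
    }
  }
})

test_that("corrected log-likelihoods exceed uncorrected and warn on misuse", {
  phy <- generate_model_tree(8, seed = 8)
  x <- simulate_characters(phy, sim_config(60, "single", Inf, 1, seed = 9))
  xv <- filter_matrix(x, "variable_only")
  ll0 <- matrix_log_likelihood(phy, xv, mk_params("none"))
  llv <- matrix_log_likelihood(phy, xv, mk_params("variable"))
  llp <- suppressWarnings(
    matrix_log_likelihood(phy, xv, mk_params("parsimony_informative")))
  expect_gt(llv, ll0)
  expect_gt(llp, llv)  # larger excluded mass, larger correction
  expect_warning(matrix_log_likelihood(phy, x, mk_params("variable")),
                 "invariant")
})
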