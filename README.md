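# mkmorph

Bayesian inference under the binary Mk model versus equally-weighted
parsimony for discrete morphological characters — the full simulation
pipeline, at desk scale.

Paleontological data sets are typically small matrices of binary
morphological characters with strong rate heterogeneity, observer-filtered
characters, and missing data concentrated in fossil taxa. `mkmorph`
provides everything needed to study how the two standard estimators behave
under those conditions:

* **Simulation** — model trees with many short branches and a flagged
  fossil subset (`generate_model_tree()`), binary characters evolved under
  the two-state Mk process with single or per-character gamma rates
  (`simulate_characters()`), observer filtration (`filter_matrix()`),
  rate-tertile deletion (`delete_rate_class()`) and fossil-cell masking
  (`mask_fossil_cells()`).
* **Likelihood** — Felsenstein pruning for binary states in compiled code,
  discrete-gamma rate heterogeneity, and exact ascertainment-bias
  corrections. With transition probabilities
  `P(same) = 1/2 + 1/2 exp(-2t)` and excluded-pattern probability `p`,
  the corrected log-likelihood of an M-column matrix is
  `sum(log L_c) - M log(1 - p)`, the excluded set being the 2 constant
  patterns (Mkv) or additionally the 2N singleton patterns (Mk-parsinf).
* **Estimators** — `mk_bayes()`, a Metropolis–Hastings sampler over
  topology (NNI + SPR), branch lengths and gamma shape, summarized by
  majority-rule consensus; and `mk_parsimony()`, Fitch scoring with
  random-addition starting trees and TBR branch swapping, retaining all
  equally optimal topologies.
* **Scoring and experiments** — Robinson–Foulds distance rescaled so the
  maximum `2(N-3)` is 100% error (`rf_distance()`, `rescaled_error()`),
  and a factorial experiment layer (`run_condition()`,
  `replicate_figure()`) that reruns each comparison (rate sweeps, rate
  heterogeneity, missing-data schemes, data-set size, ascertainment
  parameterizations) as tidy tables.

See `vignettes/mk-vs-parsimony.Rmd` for the models, algorithms, priors and
design choices in detail.

## Worked example

```r
library(mkmorph)

tree <- generate_model_tree(n_taxa = 12, seed = 101)   # short-branch model tree
x <- simulate_characters(tree, sim_config(n_characters = 350,
                                          rate_mode = "single",
                                          gamma_shape = Inf,  # rate pinned at 1
                                          mean_rate = 1, seed = 102))
x
#> Binary character matrix: 12 taxa x 350 characters
#>   missing cells: 0.0%
#>   classes: invariant=152, variable_uninformative=90, parsimony_informative=108
#>   true rates: mean 1 (mode single)

xv <- filter_matrix(x, "variable_only")   # observer keeps variable characters
fit <- mk_bayes(xv, mk_params("variable"),          # Mkv correction
                n_generations = 10000, sample_every = 10,
                start_tree = random_addition_tree(xv, seed = 103), seed = 104)
fit
#> Bayesian Mk fit
#>   taxa: 12  generations: 10000  samples: 1001
#>   ascertainment: variable  gamma: off
#>   mean post-burnin log-likelihood: -705.57
#>   acceptance rates: nni 0.29, spr 0.11, blen 0.60

post <- summarize_posterior(fit)
rescaled_error(rf_distance(post$consensus, tree), 12)
#> [1] 33.33333

pars <- mk_parsimony(xv, n_replicates = 5, seed = 105)
pars
#> Parsimony fit (tbr swapping, 5 random-addition replicates)
#>   best score: 238   equally optimal trees: 9
unlist(score_solution_set(pars, tree))
#>      mean_rf        consensus_rf      mean_error_pct consensus_error_pct
#>     10.00000             8.00000            55.55556            44.44444
```

One expected change per character over a 12-taxon tree riddled with short
branches is a hard problem: the Bayesian consensus gets two thirds of the
splits right (33% rescaled error, where 100% would mean every bipartition
wrong), while the nine equally-parsimonious trees average 56% error (44%
through their consensus). Longer chains, more characters, or easier trees
shrink both numbers; the Bayesian advantage is largest at high rates of
character change.

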