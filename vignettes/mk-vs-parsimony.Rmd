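---
title: "Bayesian Mk versus parsimony for discrete morphological characters: models, algorithms and design choices"
author: "mkmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian Mk versus parsimony: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mkmorph)
```

# The problem

Most phylogenies built from discrete morphological characters — above all in
paleontology, where molecular data are unavailable — are still estimated
with equally-weighted parsimony. Likelihood-based alternatives exist: the Mk
model treats each character as a continuous-time Markov chain with symmetric
change probabilities and uniform stationary frequencies, which for binary
characters is exactly a two-state Jukes–Cantor process. `mkmorph`
re-implements, at desk scale, the simulation machinery needed to compare
Bayesian inference under the binary Mk model against parsimony across the
conditions that make morphological data hard: overall rates of change from
near-zero to strongly saturated, among-character rate heterogeneity,
observer filtering of characters (ascertainment bias), and missing data
concentrated in fossil taxa.

Everything is measured as topological error: the Robinson–Foulds symmetric
distance between the estimated and the generating topology. An unrooted
binary tree on $N$ taxa has $N-3$ non-trivial bipartitions, so the maximum
symmetric distance between two resolved trees is $2(N-3)$ — 144 for 75
taxa — and we rescale by that maximum so total error is 100%.

# The Mk likelihood

For a branch of length $t$ (measured in expected changes per character) the
binary transition probabilities are

$$P(\text{same}) = \tfrac12 + \tfrac12 e^{-2t}, \qquad
  P(\text{different}) = \tfrac12 - \tfrac12 e^{-2t},$$

the rate matrix being normalized to one expected change per unit length.
Site likelihoods are computed by Felsenstein's pruning algorithm (in
compiled code, with partial-likelihood rescaling against underflow), with
root frequencies $(\tfrac12,\tfrac12)$ and missing entries contributing the
uninformative partial $(1,1)$; a column that is entirely `?` has likelihood
exactly 1. Among-character rate variation uses the standard discrete-gamma
approximation with equi-probable categories represented by their
conditional means (mean 1 by construction); four categories by default.

## Ascertainment corrections

Morphologists rarely record invariant characters, and often record only
parsimony-informative ones. Conditioning the likelihood on
"collectability" corrects the resulting rate inflation. With $p_{\mathrm{excl}}$
the total probability of the excluded patterns, the corrected
log-likelihood of an $M$-column matrix is

$$\ell_{\mathrm{corr}} = \sum_{c=1}^{M} \log L_c - M \log(1 - p_{\mathrm{excl}}).$$

For binary characters the excluded mass is computed exactly by summing
dummy patterns: the 2 constant patterns for the variable-only correction
(Mkv), plus the $2N$ singleton (autapomorphic) patterns for the
parsimony-informative-only correction (Mk-parsinf). This is exact and
cheap; no data augmentation is involved. The corrected per-site
log-likelihood always exceeds the uncorrected one (division by a
probability below 1), and the conditional pattern distribution sums to one
over the retained pattern set — both are verified by enumeration in the
test suite. Evaluating a correction on data that contradict it (e.g. Mkv
on unfiltered data) is permitted with a warning; the package exposes but
does not study model misspecification.

# The Bayesian sampler

`mk_bayes()` runs a single cold Metropolis–Hastings chain over topology,
branch lengths, and (optionally) the gamma shape. Priors: independent
exponential branch lengths (mean 0.1 changes per character by default),
an exponential prior on the gamma shape (mean 1), and a uniform prior over
fully resolved unrooted topologies. Moves, chosen by weight each
generation:

* **NNI** on a uniform internal edge; branch lengths travel with their
  subtrees; the proposal is symmetric.
* **SPR**: a uniform directed edge is pruned; the two edges fused by
  suppressing the detachment node (lengths $l_a, l_b$) merge into one of
  length $l_a+l_b$; the subtree reattaches at a uniform point on a uniform
  edge $f$ of the remaining tree. The attachment-position densities give
  the Hastings ratio $l_f/(l_a+l_b)$.
* **Branch-length multiplier** $l' = l\,e^{\lambda(U-1/2)}$ with Hastings
  ratio $l'/l$; likewise a **shape multiplier** on $\alpha$.

These choices mirror common defaults of Bayesian phylogenetics software
without claiming to replicate any particular program's settings. There is
no Metropolis coupling: desk-scale problems (about 20 taxa) mix adequately
with NNI+SPR, which we verified directly — prior-only runs recover the
uniform topology distribution (chi-square) and the exponential
branch-length prior (Kolmogorov–Smirnov) at ten thousand samples, which
exercises every Hastings ratio above. Convergence on data can be checked
by split-frequency agreement between two independent seeds
(`split_freq_agreement()`).

The posterior is summarized by the majority-rule consensus of the
post-burn-in sample (default burn-in 25%): exactly the splits with
sampled frequency strictly above 0.5, ties at exactly 50% excluded.
Consensus trees may contain polytomies; when scored against the resolved
model tree, their missing splits count as absences under the standard
unweighted symmetric distance. This is the conventional reading of
"symmetric distance" for partially resolved estimates, and it means an
agnostic consensus is penalized at most half as much as a confidently
wrong resolved tree — a property worth keeping in mind when reading the
high-rate comparisons.

# The parsimony engine

`mk_parsimony()` is a classic two-phase search: random-addition starting
trees (taxa shuffled, each inserted on the edge minimizing the Fitch
score, ties uniform) followed by TBR branch swapping. Fitch scoring
treats `?` as the full state set and is computed in compiled code on
compressed site patterns. The TBR neighbourhood bisects every edge and
reconnects every edge pair across the two fragments (pendant-edge
bisection degenerates to leaf SPR), so it strictly contains the NNI
neighbourhood. Hill-climbing is first-improvement over a randomized
neighbour order — much faster than steepest ascent on flat morphological
landscapes — and the guard property is checked in the tests: with
modest replicate counts the search attains the global optimum found by
exhaustive enumeration of all topologies on six and seven taxa.

All equally optimal topologies encountered are pooled across replicates,
deduplicated by bipartition-set identity, and capped (`max_trees`, with a
warning on truncation — completely flat landscapes such as zero-variable
matrices would otherwise retain everything). Solution sets are scored
both ways used in practice: the symmetric distance averaged over the set,
and the distance of the set's majority-rule consensus; the two are
reported side by side and agree closely in the experiments.

# The simulator

`generate_model_tree()` emulates the kind of empirical tree such studies
simulate along: a random resolved topology whose branch lengths are drawn
from a right-skewed gamma (shape `1/short_branch_bias`, default bias 3)
and rescaled to a fixed total — many short internal branches, as is
typical when fossil taxa are included. A fraction of leaves (default 20%)
is flagged as fossils; by default the leaves with the shortest pendant
edges, which is where poorly preserved material tends to sit, with a
uniform-random alternative. Any user-supplied rooted binary newick tree
can be used instead.

Characters evolve independently under the binary Mk process. A character
with rate $r$ expects $r$ changes summed over the whole tree: branch $b$
gets effective length $b \cdot r / T$ with $T$ the total tree length, so
"one expected change per character" is literally `mean_rate = 1`,
regardless of the tree's absolute scale. Two rate regimes match the study
design: `single` (one gamma draw shared by all characters of a data set)
and `per_character` (independent draws — rate heterogeneity). The gamma
shape of the rate draw defaults to 1 and its mean to `mean_rate`; the
originating study names the gamma family but no parameters, so both are
configurable and recorded in the output metadata. Grid experiments pin
the rate exactly (`gamma_shape = Inf`, a degenerate draw) so that the
x-axis of a rate sweep is the true simulating rate rather than a noisy
draw around it.

Filtration (`filter_matrix()`) reproduces observer bias: dropping
invariant columns, or everything except parsimony-informative columns
(both states in at least two taxa). Classification counts non-missing
entries only; all-missing columns are classified invariant with a warning
rather than an error so batch experiments keep running. Missing-data
schemes: `assign_rate_classes()` cuts characters into rate tertiles by
their true simulating rate (known here — no estimation step), slow
classes taking the remainder columns; `delete_rate_class()` removes a
random fraction of one tertile's columns; `mask_fossil_cells()` turns a
random fraction of each fossil taxon's cells into `?`, iterating taxa in
sorted label order so results are invariant to row order. All deletion
and masking counts use round-half-up; both rounding rules are arbitrary
but fixed and documented.

# Desk-scale experiments

`run_condition()` executes one factorial cell — simulate, filter, inject
missing data, estimate with each method, score against the model tree —
and `replicate_figure()` packages the factorial presets (single-rate
sweeps with and without fossil masking, heterogeneous-rate sweeps,
rate-class deletion, 350- vs 1000-character comparison, the three
ascertainment parameterizations, averaged-vs-consensus parsimony
scoring). Presets default to 20 taxa, 350 characters, short chains
(12–20 thousand generations started from a random-addition tree) and
around ten replicates per condition; these sizes keep a full single-rate
sweep in the ten-minute range on one core while preserving the factorial
structure, and every engine setting can be overridden per call for larger
runs. Sub-seeds for simulation, masking, and both estimators derive
deterministically from one base seed, so any record is exactly
reproducible from its condition descriptor.

What the synthetic conditions do *not* emulate: correlated characters,
multistate characters, asymmetric state frequencies, non-stationary
processes, and estimation error in rate-class assignment (classes come
from the true rates). Passing tests therefore demonstrate correctness of
the machinery and the direction of the method contrasts under the Mk
generating process, not robustness of either method to violations of it.

# Numerical and degenerate-input choices

* Likelihood partials rescale at $10^{-260}$; site log-likelihoods are
  accumulated in log space, and the ascertainment term uses `log1p`.
  A tree whose excluded-pattern probability reaches 1 (all lengths zero
  under Mkv) raises an error rather than returning `-Inf`.
* Majority-rule threshold is *strictly greater than* the given fraction;
  at the default 0.5 the retained splits are always pairwise compatible.
* Empty filtered matrices and all-missing columns warn instead of
  erroring; an empty matrix has log-likelihood 0 and Fitch score 0.
* Multiplier-move windows are $e^{\pm\log 3}$ (branch lengths) and
  $e^{\pm\log 2}$ (shape); with the defaults these give acceptance rates
  in the 0.2–0.8 band across the experiment grid.
* Tie-breaks: random-addition insertion ties are sampled uniformly;
  rate-tertile ties keep original column order.

# Limitations

The sampler is a single cold chain; heavily multimodal posteriors (large
trees, saturated data) would need longer runs or coupling. The parsimony
cap on equally-optimal trees truncates pathologically flat landscapes,
and the retained subset is then an arbitrary sample of the optimum set.
Branch-length and divergence-time estimation are out of scope — only
topology is ever scored.
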