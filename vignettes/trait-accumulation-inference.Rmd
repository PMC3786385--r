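---
title: "Inferring trait-accumulation pathways on hypercubic landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring trait-accumulation pathways on hypercubic landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitpaths)
```

## The scientific problem

Complex phenotypes such as C4 photosynthesis are built from many
individually scorable traits -- anatomical (enlarged bundle-sheath cells,
reduced vein spacing), cellular (organelle number and placement) and
biochemical (enzyme abundances and their cell-specific expression). The
same derived phenotype has evolved convergently in many lineages, and
extant C3--C4 intermediate species exhibit partial combinations of the
derived traits. Because convergent lineages are distantly related, the
usual phylogenetic machinery for ancestral-state reconstruction is of
limited use; instead, this package treats each intermediate species as a
noisy sample from *somewhere along* an evolutionary trajectory and asks:
in what order are the traits acquired, is there one pathway or several,
and what can we predict about traits nobody has measured?

## The model

With `L` binary traits, every possible phenotype is a length-`L`
bitstring, a node of the `L`-dimensional hypercube (`2^16 = 65,536` nodes
at the study's trait count). Evolution is modelled as a Markov chain on
this graph that starts at the all-zeros node (the ancestral C3 state),
gains exactly one trait per step, and is absorbed at the all-ones node
(the full C4 syndrome): loss of an acquired trait and simultaneous
multi-trait steps are excluded as second-order effects. A **transition
network** assigns a positive weight `w_ij` to every monotone edge;
probabilities are the row-normalized weights. This puts a start- and
end-constrained stochastic process -- a discrete analogue of a Brownian
bridge -- on the hypercube.

Observed species enter through a hidden-Markov emission picture. A
species' **phenotype string** over `{0,1,2}` (absent / present / missing)
is *compatible* with a hypercube node when every non-missing locus
agrees; `2` acts as a wildcard on either side:

```{r}
compatibility("001", "201")
compatibility("100", "001")
```

The likelihood of a dataset `B` given a network is, per species, the
probability that a trajectory on the network emits a signal compatible
with that species, with the constant emission probability dropped (only
likelihood ratios are ever used). It is estimated by simulating an
ensemble of `N_chain` trajectories once and summing, over trajectories
and over their **intermediate** nodes (steps `1..L-1`; the fixed
endpoints carry no information), the compatibility with each species:

```{r}
set.seed(1)
net <- uniform_network(2)
ensemble_log_likelihood(net, "12", n_chain = 1e4)$loglik
exhaustive_log_likelihood(net, "12")$loglik  # exactly log(1/2)
```

A trajectory visiting `k` compatible nodes contributes `k`, not 1 -- the
likelihood sums signals within chains. A species never matched by any
intermediate node gives a `-Inf` sentinel (the species is reported), so
the sampler can reject such networks cleanly rather than raise. Only
C3--C4 intermediates enter the likelihood: C3 and C4 species define the
endpoints by construction.

`exhaustive_log_likelihood()` propagates the full occupancy distribution
level by level -- an exact enumeration of all `L!` monotone paths -- and
is the oracle against which the Monte-Carlo estimator is tested (it is
itself tested against literal path enumeration at small `L`).

## Posterior sampling and what the sampler targets

Metropolis MCMC explores networks: each proposal multiplies every edge
weight by `exp(N(0, sigma^2))` (symmetric in log-weight space, so no
Hastings correction), the proposal's likelihood is estimated with a fresh
ensemble, and acceptance compares log-likelihoods against `log r`,
`r ~ U(0,1)` drawn on the open interval. Key configuration, with
study-scale defaults: `sigma = 0.1`, `2e4` burn-in, `2e5` sampling steps,
`N_chain = 2e4`, 40 independent runs. The desk-scale preset used by the
test suite (`scaled_mcmc_config()`) is `L <= 8`, burn-in `1e3`, `1e4`
steps, `N_chain = 2e3`, thinning 100, 4 runs; the study-scale preset is
provided but long-running.

Two modelling points deserve emphasis.

**Stored likelihood estimates.** The incumbent network's Monte-Carlo
log-likelihood is stored when accepted and not re-estimated
(pseudo-marginal style); `refresh_incumbent = TRUE` switches to
re-estimating it each iteration. With the ensemble sizes used here the
two variants gave indistinguishable posterior summaries in our checks.

**The implicit prior.** The acceptance rule compares bare likelihood
ratios, so the implicit prior over log-weights is improper-uniform: the
weight random walk has no stationary distribution of its own. In
directions the data constrain, the likelihood pins the chain; in
directions the data do *not* constrain, each chain diffuses and
spontaneously breaks symmetry (e.g. toward some arbitrary within-block
order when only between-block order is identified). Two practical
consequences, both visible in the test suite:

* The Bayes estimate of the summary dynamics in weakly constrained
  directions is recovered by averaging **independent runs**, not by
  running one chain longer. Run averages are exactly symmetric in
  expectation by trait exchangeability. The diagonal proof-of-principle
  experiments use 16 runs of the scaled preset; the block-linked
  experiment uses 160 short chains (burn-in 200, 800 sampling steps),
  since within-block order is entirely unconstrained there and the
  cross-run Monte-Carlo error of the mean matrix scales as one over the
  square root of the run count.
* For strongly constrained small-`L` cases the sampler concentrates on
  the near-deterministic networks maximizing the likelihood, so the
  exhaustive small-`L` oracle is the likelihood-weighted enumeration over
  all `L!` deterministic orderings. For a dataset forcing trait 1 first,
  that oracle gives `pi[1,1] = 1` and the sampled posterior mean comes
  out a touch below it. A posterior regularized by the initialization
  prior (i.i.d. `exp(N(0,1))` weights) would be different -- flatter --
  but it is not what this acceptance rule targets, and we follow the
  rule as specified.

## Summary dynamics, contingency, predictions

The **summary matrix** `pi[i, n]` is the probability that trait `i` is
the `n`-th acquisition, estimated per network by counting over the
trajectory ensemble -- by construction every empirical `pi` is exactly
doubly stochastic, and posterior means inherit this. `pi` is computed
from *all* trajectories simulated on each retained network: the ensemble
definition is unconditional, and a compatible-paths-only variant would
condition the dynamics on the data twice. `coarse_grain()` block-sums
steps (quartiles by default) for the 16-step-to-4-quartile view.

The **contingency table** `gamma[i, j]` conditions on trait `i` being
acquired first: trajectories are restarted from the node with only `i`
present and the next acquisition recorded, averaged over posterior
networks. Mechanistically linked pairs show elevated `gamma[i, j]` and
`gamma[j, i]`; the uniform-network value is `1/(L-1)` per off-diagonal
cell, which the test suite checks by simulation against enumeration.

**Missing-trait prediction** records, over each retained network's
ensemble, the values carried at a species' missing loci by compatible
intermediate nodes. The per-network statistic is the proportion of
encounters carrying a 1; the posterior mean and sd are taken **across
networks**, so the sd measures posterior rather than sampling spread
(the grouping level was open; this choice makes "strict" a statement
about posterior confidence). Calls use the 0.25/0.75 bands, boundary
values neutral; `strict` additionally requires the band edge to lie
outside one posterior sd. `occlusion_experiment()` validates this
leave-one-out style: occlude one observed entry, re-run inference,
predict it back, tally strict-correct / strict false positive /
strict false negative / neutral (non-strict calls count as neutral).

The **deterministic-ordering search** asks whether any single fixed
acquisition sequence accounts for all species. A species is accounted for
by an ordering exactly when every observed-present trait precedes every
observed-absent trait in it -- the monotone prefix chain then passes
through a compatible node. The subset-lattice dynamic programme counts
each species at the step completing its observed-present set and is
verified against brute-force permutation enumeration. Because
"unaccounted" admits several granularities, the result reports
unaccounted species, conflicting observations under the best ordering,
and the distinct traits involved.

## Dataset curation

Quantitative, cross-comparable measurements are binarized by two
clustering routes: a one-dimensional two-component Gaussian mixture fit
by EM (unequal variances and proportions; responsibilities of exactly
0.5 fall to absence) and complete-linkage hierarchical clustering cut at
two groups (common-variance view). The cluster whose mean lies in the
derived-state direction scores 1 -- e.g. vein spacing decreases toward
C4, so there the low-mean cluster is presence. Study-specific
measurements are scored by closeness to the original study's C3/C4
controls, with exact ties conservatively scored 0 (quantified immunoblot
band intensities route through the same rule); immunolocalisation
patterns score 1 only for complete absence from one cell type.
`assemble_phenotype_strings()` combines the per-trait routes, records a
per-trait report (method, fitted parameters, EM-vs-hierarchical
disagreements), encodes missing measurements as `2`, anchors C3/C4
reference species at all-0/all-1, and retains all-missing intermediates
as all-2 strings (they constrain nothing) with a warning.

`pca_em_impute()` provides the companion ordination: missing entries are
iterated against a rank-`k` reconstruction until the imputed values
stabilise (relative change below `1e-8`, cap 1000 iterations,
non-convergence is an error carrying diagnostics); on complete data it
is exactly `prcomp()`.

## Synthetic data: what it does and does not emulate

`generate_diagonal()` and `generate_block_linked()` reproduce the
structure of the validation datasets: strings sampled as prefixes of a
fixed ordering (ground truth `pi = I`) or at block boundaries (ground
truth uniform within blocks), with `occlude()` adding a missing-data
burden (exactly `round(fraction * entries)` entries, seeded). Defaults
-- 40 species, sampling steps uniform over `1..L-1` -- are this
package's choice where the study conditions are unstated. These
generators emulate phenotype strings, occlusion and ground-truth
orderings; they do **not** emulate measurement error in binarization,
phylogenetic non-independence of species, or trait correlations beyond
the imposed ordering, so passing the synthetic recoveries demonstrates
the machinery, not the biology of any real dataset. The packaged trait
matrix accompanying the transcribed species table is likewise a clearly
labelled synthetic reconstruction with ~50% missingness; analyses of it
validate the pipeline shape at `L = 16`, not the study's reported trait
orderings.

## Numerical choices

* Locus `k` of a phenotype string is bit `k - 1` of the node index
  (locus 1 least significant); the orientation is fixed here because it
  is otherwise arbitrary.
* Weights are clipped to `[1e-300, 1e300]` before normalization;
  non-finite perturbation draws are redrawn.
* All perturbations act on every edge each proposal; a one-edge-at-a-time
  kernel is the obvious alternative and would only slow mixing here.
* Dense weight storage is `2^L x L`; `L > 20` is refused.
* Thinning defaults to every 100th post-burn-in state to bound memory;
  thinned networks are retained for prediction/contingency by default at
  `L <= 12`.
* Every stochastic entry point is driven by R's RNG; multirun seeds are
  `seed + run - 1`, and fixed seeds give bit-reproducible samplers.

## Limitations

Backward steps, simultaneous acquisitions and continuous-time waiting
are out of model. The improper implicit prior means single chains must
not be interpreted in unconstrained directions (use run averages, as
above). The emission probability is never quantified, only assumed
constant; partial-emission models are out of scope. Desk-scale problem
sizes in this document and the test suite are `L <= 8` with the scaled
preset -- study-scale inference at `L = 16` uses the default
configuration and is long-running.
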