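---
title: "Methods: bipartite link prediction, evaluation, and missing-edge bounds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bipartite link prediction, evaluation, and missing-edge bounds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`biplink` predicts missing edges in unweighted bipartite networks — the
motivating case being drug–disease indication networks, where an edge
records that a drug is indicated to treat a disease and an absent edge may
be either a true non-interaction or an undiscovered one. This vignette
explains the models and procedures, the defaults and why they are set
where they are, the numerical conventions, and what the synthetic-data
experiments do and do not demonstrate.

```{r setup}
library(biplink)
```

## The data model

A network is a pair of ordered label sets (drugs, diseases) plus an edge
set of (drug, disease) index pairs; the incidence matrix `B` has
`B[u, v] = 1` iff the edge is present. Node identity is by string label;
indices are dense integers in first-appearance order, so every matrix
downstream has a deterministic layout for a given input file. Isolated
nodes are representable (declared via `#!drug` / `#!disease` directives in
the edge-list format) because edge holdout can strip a node of its last
edge, and predictors must cope: every score defined here is finite at
degree zero, with 0/0 similarity defined as 0.

All predictors produce a `score_table` over *candidate pairs* — by default
every unconnected pair of the scored network, higher score meaning more
likely a true missing edge. Scoring of existing edges is available behind
`include_edges = TRUE` for auditing suspect records, but the standard task
never ranks training edges: a held-out edge should compete only with true
non-edges.

## Predictors

**Degree product.** `x(u,v) = d_u d_v`. A pure popularity heuristic; it
is the baseline that any structure-aware method should beat, and it is
also the exact one-component limit of PLSA (see below), which the tests
exploit as an oracle.

**Similarity sums.** `x(u,v) = Σ_{v' ∈ N(u)} σ(v,v')`, where σ is one of
five common-neighbour measures on the disease side (count, cosine,
Jaccard, Dice, hub-suppressed). The drug-side variant
`x(u,v) = Σ_{u' ∈ N(v)} σ(u,u')` is available via
`direction = "drug_side"`, but the disease side is the default: on
indication data, evidence of the form "this drug already treats diseases
similar to v" is distinctly more informative than the converse. The sums
are evaluated as the matrix product `B Σ` with Σ the dense similarity
matrix; diagonal entries of Σ only ever matter when existing edges are
deliberately scored.

**Katz similarity.** Common-neighbour counts see only paths of length
two between same-side nodes; the Katz variant counts paths of every even
length `2ℓ` with weight `αℓ`, summed in closed form as
`(I − αM)⁻¹ αM` with `M = BᵀB`, convergent for
`α < 1/λ_max(M)` (λ_max(M) is the squared largest singular value of B).
The default `α = 0.5 / λ_max(M)` sits safely inside the convergence disk;
it is a convergence-safe heuristic, not an externally tuned value, and a
divergent user-supplied α is rejected with the threshold in the message.
As α → 0 the ranking approaches the common-neighbour ranking (the leading
series term), which the tests verify.

**Truncated SVD** (`K = 60` by default). Scores are the entries of the
rank-K reconstruction `U S_K Vᵀ`, the Frobenius-optimal rank-K
approximation of `B`. Computed with base R's LAPACK `svd()`; agreement
with other backends is promised at tolerance (1e-8 on scores), not
bit-exactly.

**PLSA** (`K = 90`). The aspect model
`P(u,v) = Σ_k P(k) P(u|k) P(v|k) = r_u · s_v`, fitted by plain
(untempered, unsmoothed) expectation–maximization on the observed edge
multiset, each edge one count: the E step computes the posterior over
components per edge, the M step renormalizes in closed form. The
log-likelihood is non-decreasing by construction and iteration stops at
`max_iter` (200) or when the gain drops below `tol` (1e-8). Scores
`r_u · s_v` are non-negative and sum to one over all pairs. At `K = 1`
the maximum-likelihood solution is exactly `(d_u/m)(d_v/m)`, reproducing
the degree-product ranking — a closed-form oracle the tests assert.

**NNMF** (`K = 80`). `B ≈ WH`, non-negative factors, Frobenius objective,
classic multiplicative updates (the simplest scheme monotone for
mean-squared error); `tol` is a relative objective change of 1e-5 with
`max_iter` 500. A small epsilon (1e-12) in the update denominators guards
against division by zero; monotonicity is asserted numerically at 1e-8.

Both PLSA and NNMF start from strictly positive uniform-random factors
drawn from the seeded stream and run 5 restarts by default, keeping the
best final objective — the standard defence against EM/NNMF local optima.

**Degree-corrected SBM.** The bipartite Poisson degree-corrected block
model places `A_uv ~ Poisson(θ_u θ_v ω_{g_u g_v})` with separate group
sets per side (within-side cells are structurally empty). With the rates
profiled at their maximum-likelihood values the log-likelihood depends on
the partition alone:

$$\ell = \sum_u d_u \log d_u + \sum_v d_v \log d_v
  + \sum_{rs} m_{rs}\log m_{rs}
  - \sum_r \kappa_r \log \kappa_r - \sum_s \kappa_s \log \kappa_s - m,$$

with 0 log 0 = 0. Partitions are sampled by single-node Metropolis moves
(propose one node's group uniformly, accept with `min(1, exp(Δℓ))`, a
flat prior over labelings); the hot loop is C++. Full conjugate-prior
marginalization over rates is a defensible alternative; profiling was
chosen because it keeps every Δℓ closed-form in the sufficient
statistics, which is also what makes the exhaustive-recomputation oracle
test possible at 1e-9. Group counts are fixed per run (30 + 30 by
default, the scale such models typically find on indication data); there
is no model selection over K and no nested/hierarchical variant.

A candidate's score is the change in this profile log-likelihood when the
single edge is added — each count bump contributing
`(x+1)log(x+1) − x log x` — averaged over up to 150 retained states
(defaults: 2000 sweeps, 500 burn-in, thin 10). Because the likelihood is
re-profiled after the edge addition, the one-group-per-side limit tracks
the degree product through the increasing map
`f(d) = (d+1)log(d+1) − d log d ≈ log d` rather than reproducing its
ranking identically; the correspondence is asserted as near-perfect rank
agreement, and it is exact in the alternative fixed-rate convention
(score `log θ_u θ_v ω`), which was rejected because it assigns −∞ to
degree-zero nodes and empty cells, violating score finiteness.

## Evaluation protocol

`make_holdout()` removes `round(fraction · m)` edges uniformly at random
(default fraction 0.10). Negatives are all pairs never connected in the
*original* network, so the candidate set of a score table computed on the
training network is exactly positives ∪ negatives; all negatives are used
(no negative sampling — feasible even at millions of pairs).

* **AUROC** is computed by the Mann–Whitney rank statistic, ties counted
  ½; it equals trapezoidal integration of the ROC curve exactly, which the
  suite verifies to 1e-12 against an independent implementation.
* **AUPR** is stepwise average precision — the mean of precision at each
  recalled positive — not trapezoidal PR interpolation; this matches the
  usual convention for very sparse positives. Reported in percent.
* **Normalized AUPR** divides by prevalence, the precision of a no-skill
  classifier, giving fold-improvement over chance; a perfect ranking
  attains 1/prevalence.
* **Top-k precision** (default k = 100) is the fraction of the k
  highest-ranked candidates that are held-out positives.

All rankings break score ties by the deterministic pair index (row-major
position in the incidence matrix): a randomized tie-break would change
top-k precision run to run. `run_benchmark()` repeats the protocol
(default 50 repetitions) with per-repetition seeds fanned out from the
master seed, so every predictor sees identical splits and comparisons are
paired; predictor failures are recorded per repetition and excluded from
means, and standard errors are `sd/√n`.

One statistical caveat: stepwise average precision is a biased estimator
under a no-skill ranking, with expectation `(p+1)/(n+1)` rather than
`p/n` for `p` positives among `n` candidates — a relative excess of about
`1/p`. The no-skill calibration checks therefore use splits with several
hundred positives, where this O(1/p) bias is far below the Monte-Carlo
standard error being tested against.

`extrapolate_auroc()` fits AUROC against holdout fraction by (optionally
inverse-variance weighted) least squares, linear in the fraction, and
reports the intercept and its standard error. Linearity is a modelling
choice — over the narrow fraction ranges in practice (2–10%) any smooth
trend is locally linear — and the returned standard error is conditional
on that form.

## Missing-edge and false-positive bounds

If a fraction μ of the unconnected pairs are in truth edges, then held-out
positives and hidden true edges are exchangeable for any scorer, so the
expected AUROC satisfies `A ≤ (1−μ)·1 + μ·½ = 1 − μ/2`. Inverting gives
`μ ≤ 2(1−A)` (clamped to [0, 1]); `missing_edge_bound()` converts this to
a maximum count of discoverable interactions
(`round(μ_max · unconnected pairs)`) and, by the symmetric argument on
the observed edges, a maximum count of false-positive records
(`round(ν_max · m)`). It requires `A ∈ [0.5, 1]`. Hidden true edges also
depress precision-type metrics by the factor `1 − μ`, so
`precision_correction()` returns `[measured, measured/(1 − μ_max)]`.

The suite validates the bound constructively: generate a full synthetic
network, hide a fraction μ of its edges to make the "observed" network,
cross-validate any predictor on the observed network, and check
`mean(A) ≤ 1 − μ/2 + 3·SE`. Hidden and removed edges are uniform draws
from the same edge pool, so the exchangeability assumption holds by
construction; the planted-truth oracle predictor shows the ceiling is
approached, not just trivially respected.

## The synthetic generator

`generate_planted_network()` plants a degree-corrected block structure:
nodes split evenly into groups, per-node Gamma propensities with mean 1
(shape is the single heterogeneity knob; smaller shape gives heavier
tails; propensities are renormalized to mean exactly 1 within each group
for identifiability), and independent Bernoulli edges with probability
`min(1, θ_u θ_v ω)`. Bernoulli-with-cap rather than Poisson multigraph
sampling keeps the graph simple, matching the observed data model; if
more than 1% of pairs hit the cap a "degenerate regime" warning is
raised. `planted_mixing()` builds an assortative rate matrix with a
single contrast knob, scaled so the pre-cap expected edge count hits a
target. The default preset emulates a sparse indication network: 2620 ×
1669 nodes, 30 groups per side, ~8946 expected edges (density ≈ 2×10⁻³),
shape-1 (exponential) propensities for clearly heavy-tailed degrees.

What the generator does *not* emulate: the real network's exact degree
sequence, its nestedness, correlations between a node's degree and its
group, or any covariate structure (drug chemistry, disease ontology).
Passing tests on planted networks therefore demonstrate correctness of
the algorithms and calibration of the metrics under a known generative
model — they do not certify performance levels on real indication data,
where the published orderings (block models strongest on AUROC,
SVD/NNMF strongest on precision) were observed at full scale.

`plant_missing_edges()` hides `h = round(μ(N−m)/(1−μ))` uniformly chosen
edges so the hidden set is exactly fraction μ of the *observed* network's
unconnected pairs, erroring when that would require hiding more edges
than exist (μ cannot exceed the full network's density).

## Problem sizes used by the checks

The test suite and acceptance script run at desk scale, sizes chosen so
the full suite completes in well under a minute while every statistical
assertion retains power: oracle equivalences on ≤ 12-node networks
(exhaustive enumeration), bound-validity simulations on 150 × 100
networks at density ~0.12 (dense enough that μ = 0.10 is feasible, since
μ is capped by the full network's density) over 20 seeds per μ, predictor
orderings on a 300 × 200 planted network with 20 paired repetitions, and
no-skill calibration on a 500 × 320 network with ~800 held-out positives.
The desk-scale fixtures are intentionally denser than the sparse
2620 × 1669 regime, so a small fraction of planted probabilities cap at
1; the affected generator calls expect and silence the degenerate-regime
warning. The acceptance script's random-scorer benchmark uses a
1000 × 600 network with ~3000 edges and 50 repetitions.

## Known limitations

* Fixed group counts in the DCSBM; no posterior over K, no nested model,
  and no non-local (cluster) moves, so mixing on very large or very
  structured networks may need more sweeps than the defaults.
* PLSA is untempered; with large K relative to the edge count it can
  overfit and its restarts only mitigate, not eliminate, local optima.
* The bound calculus assumes missing edges are statistically
  exchangeable with observed ones; systematically biased incompleteness
  (e.g., rare diseases under-recorded) violates it, making `μ ≤ 2(1−A)`
  optimistic.
* External embedding or deep-learning predictors are not reimplemented;
  they plug into `run_benchmark()` as any callable returning a
  `score_table`.
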