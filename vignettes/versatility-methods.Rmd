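---
title: "Versatility: model, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Versatility: model, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(versatility)
```

## The problem and the quantity

Non-overlapping community detection assigns every node to exactly one
community, but for most networks that assignment is not unique: a
stochastic algorithm explores different local optima on different runs,
and the nodes it reassigns are not random — they are the nodes whose
affiliation is genuinely ambiguous. Versatility turns that run-to-run
variability into a per-node number.

The fundamental quantity is the association matrix: over an ensemble of
runs, `p(i,j)` is the fraction of runs in which nodes *i* and *j* share a
community. Versatility of node *j* under the canonical estimator is

$$V(j) = \frac{\sum_i \sin(\pi\, p_{ij})}{\sum_i p_{ij}},$$

a transformed sum of *j*'s association row normalised by the expected
size of *j*'s community. It is 0 exactly when every `p(i,j)` is 0 or 1,
and it is large when many probabilities hover near 1/2.

### The self term

Whether the sums include *i = j* is a genuine design choice; this package
includes it, with `p(j,j) = 1` by convention. The self term adds 0 to the
numerator (since `sin(π) = 0`) and 1 to the denominator, so the
denominator counts *j* itself as a member of its community. This is the
unique reading under which four desirable facts hold simultaneously:
versatility increases with cluster size in the *n-split* model, is
invariant to cluster size in the *n-clusters* model, tends to exactly 2
for a node split evenly between two communities *as the communities grow
large* (the limit qualifier needs the `+1`), and is bounded by $\pi$ over
all networks. Dropping the self term breaks the limit statement and
inflates small-community values.

## The estimator family

Six estimators share the form $V(j) = \frac{1}{g(j)}\sum_i f(p_{ij})$,
with a concave transform $f$ (symmetric about 1/2, $f(0)=f(1)=0$,
$f(1/2)=1$) and a normalisation $g$:

| code | transform $f(x)$ | normalisation $g(j)$ | upper bound |
|------|------------------|----------------------|-------------|
| SU   | $\sin(\pi x)$    | network size $N$     | 1 |
| EU   | $-x\log_2 x - (1-x)\log_2(1-x)$ | $N$   | 1 |
| TU   | $2\min(x, 1-x)$  | $N$                  | 1 |
| SC   | $\sin(\pi x)$    | $\sum_i p_{ij}$      | $\pi$ |
| EC   | entropy          | $\sum_i p_{ij}$      | unbounded |
| TC   | triangle         | $\sum_i p_{ij}$      | 2 |

Two normalisation notes. The triangle wave is implemented as
`2*min(x, 1-x)`: the unscaled piecewise form peaks at 0.5, violating the
family's `f(1/2) = 1` constraint and the TC bound of 2, so the factor-2
version is the consistent member of the family. And SC is deliberately
**not** normalised by $\pi$ or by the finite-$N$ maximum: the attainable
maximum depends on network size (see `max_versatility()`), so a
normalised value would misleadingly suggest comparability across sizes,
and landmark values such as 2 (an even two-way split) would be lost.

The network-size normalisations fail size invariance (adding inert nodes
dilutes them) and EC is unbounded, which is why SC is the default. SC and
EC rank nodes near-identically once the association matrix has converged;
with short ensembles or very fragmented partitions, near-tied values make
ranks noisy, so the package's rank-agreement test uses 2000-run ensembles
at moderate resolutions.

The **participation coefficient**
$PC(i) = 1 - \sum_s (k_{i,s}/k_i)^2$ is included as the classical
degree-based contrast (squared ratios, after the original hub-taxonomy
definition — the linear form evaluates to 0 identically). PC measures
inter-community edge spread of one fixed partition; versatility measures
assignment ambiguity across an ensemble. Hubs with many edges into other
communities score high PC and can still have near-zero versatility.

## Model networks: the synthetic-data generators

Two idealised families state exactly how a hypothetical stochastic
algorithm behaves, so versatility has closed-form oracles there.

**n-split** (`nsplit_spec(n, c, x)`): one indicator node attached once to
each of *n* *c*-cliques; per run it joins one clique's community with
probability 1/*n*; *x* extra nodes sit in an isolated clique and never
interact. The indicator's SC versatility is
$n\,c\,\sin(\pi/n)/(1+c)$ — 0 at $n=1$, $\to 2$ for $n=2$ as
$c\to\infty$.

**n-clusters** (`ncluster_spec(n, c, x, p)`): *n* *c*-cliques, loosely
interconnected; per run each of the other $n-1$ clusters merges into the
indicator cluster's community independently with probability *p*. The
merge topology is a *star* centred on the indicator cluster: independent
pairwise merges between all cluster pairs would not be transitively
consistent, while the star preserves the one quantity the closed form
needs — the pairwise co-assignment probability between the indicator
cluster and every other cluster is exactly *p* (two non-indicator
clusters co-assign with probability $p^2$, through the centre). A node in
the indicator cluster has SC versatility
$(n-1)\sin(\pi p)/(1+(n-1)p)$, independent of *c*.

The samplers are the source of truth, the closed forms are derived from
them, and the Monte-Carlo pipeline (sample → accumulate → versatility) is
tested against the closed forms within three bootstrap standard errors at
$10^4$ runs per configuration.

What the generators emulate is the *partition distribution* of an
idealised algorithm, not the behaviour of any real one: Louvain on the
actual n-split graph is deterministic for a fixed node order and tends to
park the indicator in one clique. Passing the oracle tests therefore
validates the estimator arithmetic and the accumulation machinery; it
does not promise that a particular algorithm on real data explores
partition space this way. That gap is exactly why the convergence
diagnostic and the empirical sweep exist.

**Finite-size maximum.** `max_versatility(N)` searches all integer
n-split configurations with $n\,c \le N-1$ and returns the largest
closed-form SC value. The search covers the full $(n, c)$ lattice rather
than the single-node-cluster family $c=1, n=N-1$, because under the
self-term convention that family is capped at $\pi/2$; the unrestricted
search approaches $\pi$ (e.g. it exceeds $\pi - 0.01$ by
$N = 10^5$) and is provably non-decreasing in $N$.

## The resolution sweep

`sweep_resolution()` runs, per grid value of γ, an ensemble of seeded
Louvain partitions, accumulates the association matrix and averages
versatility over nodes. Choices that matter:

* **Stochasticity and reproducibility.** The bundled Louvain maximises
  $Q_\gamma = \frac{1}{2m}\sum_{ij}[A_{ij} - \gamma k_ik_j/2m]\,\delta(c_i,c_j)$
  (weighted degrees where applicable). Node visitation order is permuted
  per seed — order bias is the very reason Louvain can behave
  deterministically — and run *k* at grid index *g* uses seed
  `derive_seed(base_seed, g, k)`, so ensembles are independent across
  grid points and bit-reproducible end to end. Directed graphs are
  symmetrised as $(A + A^\top)/2$ with a message.
* **Uncertainty.** The SEM on each grid point is a nonparametric
  bootstrap over the ensemble's runs (default 100 resamples, resampling
  runs with replacement and recomputing association and mean
  versatility); it uses the existing runs without extra detector calls.
* **Trivial partitions.** Versatility is also zero at the useless
  extremes — everything in one community, or every node alone. A grid
  point is flagged trivial when the median run has 1 community or at
  least $N-1$ communities, and flagged points are excluded from optimum
  selection.
* **Ensemble size.** Roughly 1000 runs per grid point gives a stable
  mean-versatility estimate on networks of this scale;
  `convergence_diagnostic()` measures the sd of the mean across
  independent replicate ensembles over a ladder of sizes (it shrinks
  roughly as $1/\sqrt{\text{runs}}$) so users can right-size their own
  ensembles.

`find_optima()` reports non-trivial discrete local minima (strictly lower
than their non-trivial neighbours; across a flat run of equal values the
lowest γ is reported) sorted by mean versatility, plus *plateaus*:
maximal stretches of at least `plateau_len` consecutive non-trivial
points all within one SEM of the stretch's minimum. A plateau expresses a
different preference than the global minimum — stability of the
decomposition under small perturbations of γ — and is the natural choice
when the minimum sits in a steep, fragile region.

On the bundled karate-club fixture, a 0.1-step sweep of γ over
[0.1, 2] at 1000 runs per point puts the non-trivial minimum at γ = 0.5
with two communities — the historically attested two-faction split — and
the most versatile node by an order of magnitude is the member with
exactly one friendship on each side.

## Numerical conventions and degenerate inputs

* Transforms are exact at the endpoints: `sinpi()` (not `sin(pi*x)`) and
  the continuous extension $E(0)=E(1)=0$, so deterministic ensembles give
  versatility *exactly* 0, not within rounding.
* Co-assignment counts are accumulated as integers and divided once, so
  accumulation order is irrelevant and the streaming accumulator is
  bit-identical to the batch one.
* Association entries are validated to be multiples of `1/run_count`;
  idealised (expected-value) matrices carry `run_count = NA` and skip
  that check.
* Versatility requires at least two nodes; a one-node network (the
  degenerate n-clusters configuration $n=c=1$) is refused rather than
  given a conventional value.
* Node ids are opaque strings everywhere; vertices are kept sorted by id
  so outputs are stable across readers and platforms.
* Ties in optimum selection break toward lower γ (coarser, more
  conservative decompositions).

## Problem sizes used by the test suite

The shipped tests exercise the oracle grid ($n \le 5$, $c \le 10$, $10^4$
runs per configuration), karate-club sweeps at 1000 runs per grid point,
and property checks on random ensembles of up to 60 nodes; these sizes
were chosen as the smallest at which the statistical assertions are
comfortably stable.

## Known limitations

* The sweep's detector is Louvain-family modularity; other stochastic
  detectors plug in through `detector_adapter()` but none else is
  bundled.
* The idealised samplers cover two model families only; they are oracles
  for the estimator, not generators of realistic networks (no degree
  heterogeneity, no overlapping structure, no noise model).
* Mean versatility is an *informing* objective, not an oracle for the
  "true" resolution: where no meaningful community structure exists the
  curve will still have minima.
* Directed modularity is not implemented; directed input is symmetrised.
* The association matrix is dense ($N \times N$ doubles), which bounds
  practical network size at a few tens of thousands of nodes.
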