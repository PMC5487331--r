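# versatility

Community detection on real networks is an ill-posed problem: run a
stochastic algorithm such as Louvain twice and you will usually get two
different partitions, and some nodes are assigned to a community far less
consistently than others. **versatility** quantifies that per-node
ambiguity and uses it to choose the modularity resolution parameter that
decomposes a network least ambiguously. It is aimed at network
neuroscientists, systems biologists and anyone doing ensemble-based
community analysis.

## The metric

Run any stochastic community-detection algorithm many times and record,
for every pair of nodes *i*, *j*, the sample probability *p(i,j)* that they
land in the same community (the *association matrix* of consensus
clustering). The versatility of node *j* is

```
V(j) = Σ_i sin(π p(i,j)) / Σ_i p(i,j)
```

with both sums over **all** nodes *i*, including *i = j* with
*p(j,j) = 1*; the denominator is therefore the expected size (counting *j*)
of the community containing *j*. Pairs that are always together
(*p* = 1) or always apart (*p* = 0) contribute nothing; pairs that are
together half the time contribute maximally. Key facts:

* `V(j) = 0` exactly when the assignment of *j* is deterministic;
* `V(j) < π` always; the bound is approached only as the network grows
  without limit (`max_versatility(N)` computes the finite-*N* maximum);
* `V(j) = 2` marks a node split evenly between two large equally-sized
  communities;
* versatility depends only on the association matrix — never on degree.

The sine/community-size estimator (`"SC"`) is the default; entropy and
triangle-wave transforms and a network-size normalisation are available
(`estimator_codes()`), and the degree-based participation coefficient is
included for contrast. Idealised *n-split* and *n-clusters* model networks
with exact closed-form oracles back the implementation, and a seeded
resolution sweep turns the global mean versatility into an objective
function for choosing the Louvain resolution parameter γ.

## Worked example: the karate club

Zachary's karate club — 34 members, 78 friendships, famously split into
two factions — ships with the package. Sweep the Louvain resolution
parameter with 1000 seeded runs per grid point:

```r
library(versatility)
g  <- karate_fixture()
sw <- sweep_resolution(g, seq(0.3, 0.7, 0.1), runs_per_gamma = 1000,
                       base_seed = 20)
as.data.frame(sw)
#>   gamma mean_versatility     sem mean_n_communities trivial
#> 1   0.3           0.1168 0.01341               2.00   FALSE
#> 2   0.4           0.0549 0.00861               2.00   FALSE
#> 3   0.5           0.0352 0.00340               2.00   FALSE
#> 4   0.6           0.0387 0.00425               2.00   FALSE
#> 5   0.7           0.2689 0.00782               2.79   FALSE

find_optima(sw)
#>   gamma    kind mean_versatility gamma_lo gamma_hi
#> 1   0.5 minimum           0.0352      0.5      0.5
```

γ = 0.5 minimises the mean versatility over non-trivial partitions and
yields exactly the two known factions. The per-node values tell you *who*
is ambiguous:

```r
ens <- run_ensemble(g, detector_louvain(0.5), 1000, base_seed = 20,
                    gamma_index = 2)
v <- versatility(accumulate(ens))
head(sort(v$values, decreasing = TRUE), 3)
#>     10     31      9
#> 0.5109 0.0564 0.0564
```

Member 10 — the one person with exactly one friendship on each side of
the split — stands out by an order of magnitude: the algorithm genuinely
cannot decide which faction they belong to, which is precisely what
versatility measures. Closed-form oracle check on a model network:

```r
analytic_versatility_nsplit(nsplit_spec(2, 3))
#> [1] 1.5
```

The same pipeline is available from a shell via the installed
`exec/versatility` script (`compute`, `sweep`, `model`, `converge`,
`fixtures` subcommands, all reproducible through `--seed`); every output
directory receives the echoed run configuration and a log.

## File formats

* graphs in: edge-list TSV (`from to [weight]`, `#` comments), adjacency
  CSV (square, ids in header and first column), GraphML;
* partition ensembles: CSV with a `node` column then one column per run
  (`run_0001`, ...), labels compared only within a column;
* results out: TSV tables with JSON sidecars; sweeps additionally as JSON.

Node ids are opaque strings ("01" ≠ "1"); duplicate edges are summed,
self-loops dropped with a warning, negative weights rejected; directed
graphs are symmetrised as (A + Aᵀ)/2 before Louvain.

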