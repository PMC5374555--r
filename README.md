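# dignifi

Disease-gene prioritization from protein-protein interaction (PPI) networks.

Most orphan (rare) diseases are genetic, and for many of them only a handful
of causal genes are known. `dignifi` ranks candidate genes for such a disease
by *guilt by association* on a PPI network: genes that sit close to the
disease's known genes — topologically and functionally — are promoted. It is
aimed at computational biologists who have an edge-list interactome, a set of
seed genes per disease, and optionally GO annotations and a protein-complex
catalog, and who want ranked candidate lists plus a standardized decoy
benchmark for method comparison.

## The method

A PPI network is a weighted undirected graph *G(V, E, W)*; `K_v` is the total
edge weight at gene *v* and *M* the number of interactions. The similarity of
a gene pair is routed by adjacency:

* **Interacting pairs** get a *direct-neighbour* (DN) score — the overlap of
  their self-inclusive neighbourhoods, penalized by the larger strength so
  that hub genes are not automatically similar to everything:

  DN(i, j) = Σ<sub>k ∈ Γ<sub>i</sub> ∩ Γ<sub>j</sub></sub> w(i,k)·w(j,k) / √max(K<sub>i</sub>, K<sub>j</sub>),

  with w(v, v) = 1 and Γ<sub>v</sub> the neighbours of *v* plus *v* itself.

* **Non-interacting pairs** get a *local random walk* (LRW) score — the
  t-step visiting probabilities in both directions, weighted by each source's
  stationary occupancy:

  LRW<sub>ij</sub>(t) = (K<sub>i</sub>/M)·π<sub>ij</sub>(t) + (K<sub>j</sub>/M)·π<sub>ji</sub>(t),

  where π evolves by π(s+1) = Pᵀπ(s) with the row-stochastic transition
  matrix P[i, j] = w(i, j)/K<sub>i</sub>. Truncating at small *t* (default 3)
  keeps the walk local and the cost at O(t·|E|) per seed.

Two biological channels can be blended in:

* **SimGO** — information content of the most specific shared GO term:
  −log(min<sub>k</sub> |S<sub>k</sub>| / S<sub>max</sub>), where |S<sub>k</sub>|
  is the annotation size of shared term k and S<sub>max</sub> the largest
  annotation size in the corpus.
* **SimCOM** — the sum, over protein complexes containing both genes, of a
  network reliability score density(C) · w<sup>in</sup>/(w<sup>in</sup> + w<sup>bound</sup>).

The combined pair score is (1 − α − β)·Topo + α·SimGO + β·SimCOM (defaults
α = β = 0.1), and a candidate's score for a disease is the sum of its
similarities to all known genes. Candidates are ranked by descending score
with pessimistic ties; a candidate scoring zero is ranked at the full
candidate-set size.

Evaluation follows the leave-one-out decoy protocol: each known gene is held
out in turn, mixed with 99 random decoy genes, and ranked from the remaining
seeds; *success@k* is the fraction of trials in which the target ranked in
the top k. A random-walk-with-restart (RWR, restart 0.8) baseline and an
LRW-only comparator are included.

## Worked example

Everything below is self-contained: the fixture generator plants 20 dense
6-gene disease modules in a 500-gene preferential-attachment background
network, with module-specific GO terms and per-module complexes.

```r
library(dignifi)

fx <- generate_fixtures()                       # reference benchmark, seed 42
catalog <- score_catalog(fx$complexes, fx$network)
fx$network
#> PPI network: 620 genes, 1562 interactions (total edge weight 1562)

## rank one held-out module gene among 99 background genes
res <- rank_candidates(fx$network, fx$annotations, catalog,
                       known = fx$diseases$DIS01[-1],
                       candidates = c(fx$diseases$DIS01[1],
                                      sort(setdiff(fx$network$nodes,
                                                   fx$diseases$DIS01))[1:99]))
print(res, n = 3)
#> Candidate ranking (100 candidates, 5 seeds; alpha = 0.1, beta = 0.1, t = 3)
#>     gene     score rank
#> 1  D01G1 4.2338007    1
#> 2 BG0048 0.2667834    2
#> 3 BG0065 0.2310769    3
```

The held-out module gene `D01G1` outranks every decoy: its summed similarity
to the five seeds (4.23) dwarfs the best background gene (0.27). The full
benchmark:

```r
rep <- loocv(fx$network, fx$annotations, catalog, fx$diseases,
             eval_config(method = "simbio", seed = 1))
rep
#> Leave-one-out evaluation: method simbio, 120 trials, 99 decoys per trial
#>     k successes trials    rate
#> 1   1       120    120 100.00%
#> ...
```

All 120 held-out module genes rank first — the planted modules are dense and
carry specific annotations, so recovery is essentially perfect by design;
see the methods vignette for what this does and does not demonstrate.

A command-line front end over the same functions is installed at
`inst/scripts/dignifi` (subcommands `enrich`, `sim`, `rank`, `evaluate`,
`fixtures`).

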