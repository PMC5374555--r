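---
title: "Methods: network similarity, biological channels, and the decoy benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network similarity, biological channels, and the decoy benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(dignifi)
```

## The model and its assumptions

`dignifi` rests on the guilt-by-association premise: genes whose protein
products interact — directly or through short paths — tend to be involved in
phenotypically similar diseases. Given a disease's known causal genes, every
candidate is scored by its summed pairwise similarity to those seeds, and
candidates are ranked by the total. The premise is an assumption about
biology, not a theorem: it holds to the extent that the interactome is a
faithful proxy for functional relatedness, and it inherits all of the
interactome's ascertainment biases (well-studied genes have more recorded
interactions).

The pairwise similarity is routed by adjacency. For an interacting pair the
*direct-neighbour* score measures neighbourhood overlap,

$$DN(i,j) = \frac{\sum_{k \in \Gamma_i \cap \Gamma_j} w(i,k)\,w(j,k)}
  {\sqrt{\max(K_i, K_j)}},$$

with $w(v,v) = 1$ and $\Gamma_v$ the neighbours of $v$ *plus $v$ itself*.
The self-inclusive reading is deliberate: it is the only reading under which
the $w(v,v)=1$ clause of the weight function is ever used, and it gives an
isolated interacting pair a positive score (each endpoint contributes one
unit to the overlap) rather than zero. The $\sqrt{\max(K_i,K_j)}$
denominator depresses hub genes, whose large neighbourhoods would otherwise
overlap with everything.

For a non-interacting pair the *local random walk* score truncates a walk at
$t$ steps,

$$LRW_{ij}(t) = \frac{K_i}{M}\pi_{ij}(t) + \frac{K_j}{M}\pi_{ji}(t),
\qquad \pi(s{+}1) = P^{\top}\pi(s),$$

with $P[i,j] = w(i,j)/K_i$ row-stochastic and $\pi(0)$ the indicator of the
source. Truncation is the point: a short walk concentrates similarity on
genes a few steps away, where the association signal lives, instead of
diffusing it network-wide as stationary methods do. Genes in different
connected components score exactly zero.

On weighted networks we generalise the binary adjacency indicator to the
edge weight and the degree to the strength $K$, so the same code serves
curated binary interactomes and literature-enriched weighted ones; on binary
data the two coincide. Self-similarity is excluded everywhere — a seed gene
is never its own candidate — so $Sim(v,v)$ never needs a value.

Two biological channels reduce the bias of relying on the interactome alone:

* **SimGO**: among the GO terms shared by two genes, the most specific one
  (smallest annotation size $|S_k|$) determines
  $-\log(\min_k |S_k| / S_{max})$. $S_{max}$ is taken over *all* terms in
  the supplied annotation corpus, not just terms of network genes, and all
  three ontology aspects are pooled. Only directly assigned terms are used:
  the score is defined on annotation sets as given, and no ontology graph is
  part of the package's inputs, so there is no ancestor propagation (a
  pre-propagated GAF can of course be supplied).
* **SimCOM**: each catalogued complex gets a network reliability score,
  $density(C) \cdot w^{in}/(w^{in}+w^{bound})$, and a pair's score is the sum
  over complexes containing both genes. Complexes are evaluated on the
  subgraph induced by members present in the network: absent members cannot
  contribute edges, so the density denominator uses the present-member
  count. Complexes with fewer than two present members, or with no internal
  interaction, score zero — both are division-by-zero guards that also make
  biological sense.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `t` | 3 | walk length (steps, dimensionless); 2–4 is the useful range — at 1 the walk cannot leave the neighbourhood, large `t` approaches global diffusion |
| `alpha` | 0.1 | weight of SimGO in the convex combination |
| `beta` | 0.1 | weight of SimCOM |
| `normalize` | `TRUE` | per-task rescaling of each channel by its maximum (below) |
| `log_base` | e | base of the SimGO logarithm; a monotone rescaling absorbed by `alpha` |
| `min_articles` | 30 | article-count threshold for trusting a literature co-occurrence pair |
| `decoys` | 99 | decoys per validation trial (100-gene candidate sets) |
| `restart` | 0.8 | restart probability of the RWR baseline |
| `min_genes` | 5 | minimum known genes in the network for a disease to be evaluated |

The defaults for `t`, `alpha`, `beta`, `min_articles`, `decoys`, `restart`
and `min_genes` are the standard operating point for this family of methods
on curated human interactomes.

**Channel normalization.** The three channels live on incommensurate scales:
DN/LRW values are small probabilities-times-ratios, SimGO is a log
information content (order 1–10), SimCOM a sum of scores in $[0,1]$. A
convex combination of raw channels would let whichever channel happens to
have the largest numeric range dominate regardless of `alpha` and `beta`.
By default each channel is therefore divided by its maximum over all
(seed, candidate) pairs of the current ranking task before the weights are
applied. This is a genuine design choice, and it is the principal
reproducibility caveat for anyone comparing numbers across implementations
of this scheme: `normalize = FALSE` gives the raw combination, under which
scores are exactly additive over disjoint seed sets (a property the test
suite checks).

**Ties and zero scores.** Ranks are pessimistic: a candidate's rank is the
number of candidates scoring at least as high, so every member of a tie
group takes the group's worst rank. This makes success\@k estimates
conservative. A zero-scoring candidate is ranked at the full candidate-set
size; with pessimistic ties this is automatic ($score \ge 0$ for all
candidates), so the stated rule and the tie rule agree by construction.

**Other numerical choices.** Walk profiles are computed lazily per source as
sparse matrix–vector products ($O(t\,|E|)$ each) and memoised per source
within a ranking or evaluation run; nothing is precomputed all-pairs. The
RWR baseline iterates to an L1 change below $10^{-10}$ and raises an error
with diagnostics rather than returning an unconverged vector. Duplicate
edges keep the maximum weight (deterministic and conservative); zero-weight
edges are dropped at construction so that every strength is positive and
every transition row well-defined. Floating-point assertions in the test
suite use absolute tolerances of $10^{-10}$ to $10^{-12}$; scores are
reported at full double precision.

## The evaluation protocol

Leave-one-out with decoys: for each disease and each known gene, the gene is
held out, the remaining known genes seed the ranking, and the target is
mixed with 99 decoys drawn uniformly *without* replacement from the network
genes excluding **all** of the disease's known genes — excluding only the
target would let fellow seeds appear as decoys and leak labels. Decoys are
redrawn independently per trial, seeded by `seed + trial_index`, so a report
is exactly reproducible and trials are independent. Diseases with fewer
than `min_genes` known genes in the network are skipped with a log message.

The LRW-only comparator scores *every* pair by the walk, adjacent or not,
isolating the contribution of the DN component. The RWR baseline scores
candidates by their stationary visiting probability under restart to the
seed distribution. Externally computed rank lists can be compared with
`compare_rankings()`, a thin two-tailed t-test wrapper over per-trial ranks.
Other published comparators are out of scope and can be brought in as rank
files.

## The synthetic benchmark

`generate_fixtures()` emulates the structural assumptions the method
exploits, with known ground truth:

* a 500-gene background grown by preferential attachment (2 edges per gene),
  giving the heavy-tailed degree distribution of real interactomes — which
  matters here because the DN hub penalty and the LRW strength weighting are
  only exercised on skewed degrees;
* 20 planted disease modules of 6 genes, wired within-module with
  probability 0.8 and to each background gene with probability 0.005, so
  modules are far denser than the background (density ≈ 0.008) but not
  isolated; any module gene left unwired is attached to a random module
  partner so every planted gene enters the network;
* 2 module-specific GO terms annotating exactly each module's genes, against
  a pool of 30 broad terms (3 per background gene, 1 per module gene), so
  the specific shared term is always the information-carrying minimum and
  $S_{max}$ is set by the broad pool;
* 80% of each module wrapped as a complex, plus 5 random background
  complexes as noise;
* each module registered as one disease.

Module sizes and counts were chosen so the full benchmark (620 genes, ~1500
interactions, 120 validation trials) runs in seconds; probabilities were
chosen to make the planted signal unambiguous.

What passing this benchmark shows: the pipeline recovers planted modules
essentially perfectly, the biological channels do not destroy the
topological signal, and every component behaves per its contract. What it
does **not** show: performance on real interactomes. Real disease modules
are sparser, overlap each other, and are observed through a noisy,
biased interactome; real GO terms are hierarchically redundant rather than
cleanly module-specific; real complexes only partially align with disease
modules. Success rates on this benchmark are therefore near ceiling by
construction and must not be read as estimates of performance on curated
disease data.

## Interfaces

All inputs are plain text: edge lists (`gene gene [weight]`), two-column
gene–term TSV or GAF 2.x for annotations, `id<TAB>gene;gene;...` for
complexes and diseases, `gene gene count` for literature co-occurrence.
Genes are opaque case-sensitive strings; identifier mapping between symbol
namespaces is dataset plumbing that belongs upstream of this package. The
`inst/scripts/dignifi` executable is a thin command-line veneer over the
exported functions for shell pipelines; the functions themselves are the
interface.

## Known limitations

* The per-task channel normalization makes combined scores task-relative:
  scores are comparable within one ranking, not across diseases.
* SimGO ignores the GO hierarchy; two genes annotated to sibling terms with
  no shared assignment score zero.
* Complex reliability depends on the network: a real complex invisible to
  the interactome scores zero even though its co-membership is biologically
  meaningful.
* The decoy protocol measures retrieval among random genes, which is easier
  than distinguishing a causal gene from its functional neighbours;
  reported success rates are optimistic in that specific sense, equally for
  all methods compared.
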