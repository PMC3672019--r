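---
title: "Global network alignment with diffusion scoring and auction matching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global network alignment with diffusion scoring and auction matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netalignr)
```

## The problem

Two protein–protein interaction (PPI) networks from different species
encode partially conserved machinery. A *global* alignment maps each
protein of one network to at most one protein of the other so that both
sequence-level resemblance and interaction patterns are preserved; the
induced edge mapping then exposes conserved complexes and supports
transferring functional annotation across species. `netalignr` implements
the classical two-stage pipeline — diffusion-based node-pair scoring
followed by weighted bipartite matching — with matching heuristics fast
enough that alignments of typical PPI networks take minutes rather than
hours, plus the assessment machinery needed to verify that the heuristics
do not degrade alignment quality.

## Similarity model

Let $A$ and $B$ be the symmetric adjacency matrices of the undirected
networks $G_A$ ($n_A$ nodes) and $G_B$ ($n_B$ nodes), and let
$\tilde A, \tilde B$ be their column-stochastic normalizations: column $j$
divided by the degree of node $j$, all-zero for isolated nodes
(`normalize_adjacency()`). Given a non-negative *elemental* similarity
matrix $H$ (sequence similarity, or any topology-independent prior), the
diffused similarity $X \in \mathbb{R}^{n_A \times n_B}$ is iterated as

$$X \leftarrow \alpha\, \tilde A X \tilde B^\top + (1 - \alpha) H',$$

where $H'$ is $H$ scaled to unit 1-norm. The recursion expresses that two
nodes are similar when their neighbours are similar, anchored by the
elemental prior with weight $1 - \alpha$. Stacking columns with
$\mathrm{vec}$ turns the update into
$x \leftarrow \alpha (\tilde B \otimes \tilde A) x + (1 - \alpha) h$, a
personalized-PageRank-style linear system; `kronecker_oracle()` implements
this stacked form with the explicit Kronecker operator and the two
implementations agree entrywise to $10^{-10}$ in the test suite, which
locks the orientation convention (rows of $X$ index $G_A$).

Numerical choices, made once and tested:

* **Norm.** "Normalized to unity" is implemented as the 1-norm, applied to
  $h$ once at setup and to $x$ after every iteration, so entries remain a
  probability distribution over node pairs. The invariant
  $\sum_{ij} X_{ij} = 1 \pm 10^{-12}$ is recorded per iteration and
  asserted in the tests.
* **Initialization.** $X_0 = H'$. Any start converges for $\alpha < 1$;
  this one makes $\alpha = 0$ exactly stationary from the first iteration.
* **Stopping.** A fixed iteration count (default 20) with $\alpha = 0.8$,
  the setting used for all built-in experiments; an optional 1-norm
  early-stop tolerance exists but is off by default.
* **Degenerate mass.** With $\alpha = 1$ and isolated nodes, one update can
  annihilate all score mass (a 1×1 edgeless pair is the minimal case);
  the iteration then retains the previous normalized iterate rather than
  dividing by zero, which also keeps the 1×1 result at the normalized
  value 1 for every $\alpha$.
* **Storage.** $\tilde A, \tilde B$ are sparse; $X$ is dense, as diffusion
  fills it in.

## Matching extraction

$X$ defines a complete weighted bipartite graph between the two node sets.
Three extractors return an injective set of pairs:

* **Greedy ½-approximation** (`greedy_match()`): select the largest entry,
  zero its row and column, repeat while a positive entry remains. Ties go
  to the smallest row, then column index, making the output deterministic.
  The weight is provably at least half the optimum; the fuzzed test suite
  checks the bound against an exhaustive oracle, and the 2×2 example
  `[[1.0, 0.9], [0.9, 0]]` (greedy 1.0 vs optimal 1.8) shows the bound is
  nearly tight.
* **Auction** (`auction_match()`): objects (columns) carry prices, and each
  unassigned buyer (row) with a positive-profit object bids
  $u_i - v_i + \varepsilon$ — best profit minus second-best plus an
  increment — on its best object, which switches owner and rises in price.
  Scores are integerized as $\mathrm{round}(x_{ij} \cdot \text{scale})$
  (scale $10^6$ by default) because the optimality theory is stated for
  integer weights: with fixed $\varepsilon < 1/\min(n_A, n_B)$ the final
  assignment is exactly optimal for the scaled problem, a property the
  tests exercise on random integer matrices. Buyers whose rows are all
  zero never bid; zero-profit pairs are left to the completion step.
* **Adaptive ε-scaling auction** (`adaptive_auction_match()`, the
  default): starts at $\varepsilon_0 = 1/(\min(n)+1)$ on the scaled
  problem and multiplies $\varepsilon$ by `growth` (default 4) after any
  inner round that yields fewer than $\delta$ *net* new assignments
  (default $\max(1, \lceil 0.01 \min(n) \rceil)$), trading exactness for
  speed. Progress is counted as objects going from unowned to owned:
  with sequential (Gauss–Seidel) bidding every bid momentarily assigns its
  bidder, so counting bid events would never trigger escalation and the
  auction would crawl at the initial increment. Prices are retained across
  ε phases, and price monotonicity is asserted in the tests. Afterwards,
  `complete_matching()` pairs leftover rows with the first free columns,
  ascending, so the cardinality is always $\min(n_A, n_B)$ — added pairs
  may contribute zero weight but never reduce it.

When $n_A > n_B$ the matchers transpose internally and map results back.
`brute_force_optimal()` — exhaustive enumeration over all
maximum-cardinality injections, guarded to $\min(n) \le 9$ — serves as the
exact reference in every quality test; no library matching routine is used
on either side of those comparisons.

## Assessing an alignment

The *alignment graph* (`build_alignment_graph()`) has one node per matched
pair $(i, j)$ and an edge between $(i_1, j_1)$ and $(i_2, j_2)$ exactly
when $i_1 i_2 \in E_A$ and $j_1 j_2 \in E_B$. Its edge count (conserved
edges) and connected-component sizes are the topological quality measures:
more conserved edges mean more interaction structure survives the mapping,
and large components are candidate conserved modules, whereas a profusion
of singletons signals a fragmented alignment.

Biological coherence is scored per species (`enrich_components()`): each
component is projected onto one species' nodes, the projection is
intersected with that species' annotation background, and each term
annotating a projected node receives the exact hypergeometric upper-tail
probability of drawing at least $k$ term-annotated nodes in a draw of the
projection's size from the background. A term is enriched at
$p \le 0.05$ (raw by default; a per-component Bonferroni option exists).
Two summaries follow: **TNR**, the percentage of components (singletons
included — they dilute specificity by design) with at least one enriched
term, and **TPR**, the number of *distinct* enriched terms across all
components. Terms are flat labels: no ontology-graph ancestry is
propagated, so numerical parity with DAG-aware enrichment tools is not
claimed. One consequence worth knowing: if an alignment collapses into a
single giant component, its projection approaches the whole background and
no term can be enriched — the statistic deliberately penalizes
over-merged components.

## What the synthetic generator emulates

`generate_pair(n, edge_prob, rewire_frac, extra_nodes, seed)` draws $G_A$
as Erdős–Rényi $G(n, p)$, relabels a shuffled copy as $G_B$, deletes
$\lceil \text{rewire\_frac} \cdot |E_A| \rceil$ mapped edges and inserts
as many uniformly among non-edges (evolutionary gain/loss of
interactions), and appends `extra_nodes` nodes without counterparts
(proteins lacking orthologs). `generate_elemental()` scores every planted
pair `true_score` and, optionally, random off-truth pairs with
$\mathrm{Uniform}(0, \text{noise\_score\_max})$ (spurious sequence hits).
`generate_annotations()` plants each term on a connected module of $G_A$
grown by random neighbour expansion, mirrored through the truth map onto
$G_B$, with all nodes forming the background.

Defaults are fixed at `edge_prob = 0.1` (mean degree ~5 at the package's
50-node experiment size, the sparse regime typical of PPI data),
`extra_nodes = 5`, `true_score = 1`, noise off. Two features of real data
are deliberately *not* imitated: heavy-tailed PPI degree distributions and
the magnitude distribution of BLAST scores; both affect absolute
performance numbers but not the correctness properties the tests assert.
Note that with a noiseless elemental prior the truth is recoverable from
$H$ alone at any rewiring level — informative degradation curves require
elemental noise (the package's built-in experiment uses 500 noise pairs
with noise ceiling equal to `true_score`), and passing tests on these
instances demonstrate correctness of the machinery, not performance on
real proteomes.

The annotation file format is two columns (node, term), so a round trip
through disk restricts the background to annotated nodes; in-memory
annotation sets generated for the planted instances use every network node
as background.

## Problem sizes and reproducibility

The built-in experiments use networks of up to 10 nodes where an explicit
Kronecker operator or exhaustive matching enumeration serves as reference,
and 50-node planted instances (20 seeds per condition, rewiring
$\in \{0, 0.1, 0.3, 0.6\}$) for end-to-end recovery — sizes at which exact
references are computable while leaving the asymptotic regime to the
algorithmic guarantees. All randomness flows through explicit integer
seeds; two runs with the same configuration and inputs produce
byte-identical matching files, which the test suite asserts at file level.

## Limitations

* The adaptive auction is a heuristic: validity, full cardinality on
  positive matrices, and empirical near-optimality are tested, but no
  optimality is claimed for the escalated-ε regime.
* Integerization bounds auction optimality claims to the scaled problem;
  score differences below $1/\text{scale}$ are invisible to the bidding.
* Enrichment treats annotation terms as independent flat labels.
* The edge-list reader accepts only the package's TSV formats; converters
  from BLAST output or interaction-database XML are user-side.
* Node labels may not contain `|`, which names matched pairs.
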