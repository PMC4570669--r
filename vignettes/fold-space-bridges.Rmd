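---
title: "Calibrated structural-bridge networks across protein fold space"
author: "foldbridges"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrated structural-bridge networks across protein fold space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldbridges)
```

## The problem

Protein domains are conventionally classified into discrete SCOP folds, yet
structural alignment programs routinely report significant similarities
*between* domains of different folds. Each such inter-fold similarity is a
"structural bridge", and the set of bridges defines a network over folds — a
map of fold space. Two obstacles make such maps treacherous. First, every
alignment method scores similarity on its own scale (Z-scores, p-values,
TM-scores, elastic distances), so "significant" means something different for
each. Second, a large share of bridges are artefacts of the particular
aligner: maps built from single methods disagree substantially, and only
their consensus deserves much confidence.

`foldbridges` addresses both. It calibrates each method's scores onto a
common probabilistic scale — the posterior probability that two domains share
a fold — then collapses domain-level similarities into fold-level networks at
a ladder of probability thresholds, intersects the per-method networks into
consensus networks, and analyses the resulting landscapes: weighted
centralities, community structure, and the relationship between a fold's
network position and its evolutionary age.

## Score calibration

For one alignment method, consider the similarity $S$ of a random domain
pair and the indicator $F$ that the pair shares a fold. For a candidate
threshold $\bar s$ the posterior probability of fold co-membership is

$$
P(F{=}1 \mid S > \bar s) \;=\;
\frac{P(S > \bar s \mid F{=}1)\,P(F{=}1)}
     {P(S > \bar s \mid F{=}1)\,P(F{=}1) + P(S > \bar s \mid F{=}0)\,P(F{=}0)}.
$$

All five ingredients are estimated empirically, with no smoothing: the priors
are the observed proportions of sibling and unrelated pairs, and the
conditionals are the proportions of each population scoring strictly above
$\bar s$. Distance-oriented scores (e.g. an elastic metric, where smaller
means more similar) are sign-flipped internally so that "greater = more
similar" holds throughout; their reported cutoffs are mapped back to the
original scale and marked as upper limits.

Comparisons involving an all-α domain behave differently from the rest (α
helices superpose promiscuously), so calibration is run separately for the
*alpha-involved* and *other* partitions, each with its own priors and
survival curves. The priors are computed within each partition, which keeps
the two calibrations fully self-contained.

When a method reports several candidate scores, `select_score_by_auc()`
keeps the column that best discriminates fold siblings from unrelated pairs
(largest AUROC, computed by the rank-sum identity; constant columns score
0.5 with a warning; ties resolve by column order).

Three numerical choices matter:

* **Strict survivals.** $P(S > \bar s \mid F)$ uses a strict inequality, so
  the posterior at an *alignment's own score* would be 0/0 at the maximum.
  `posterior_of_alignment()` therefore evaluates the curve at the largest
  observed candidate threshold strictly below the alignment's score, which
  makes the alignment count itself in the conditional; a perfectly
  separating top score maps to posterior 1. Scores below the observed
  support evaluate at the leftmost estimable point and are flagged.
* **Suffix-rule inversion.** The empirical posterior-versus-score curve can
  be non-monotone where data are sparse. `threshold_for_posterior(model, p)`
  returns the smallest observed score such that *every* observed score at or
  above it has posterior at least `p`. This is well defined regardless of
  local dips, reduces to the naive crossing point when the curve is
  monotone, and is non-decreasing in `p` by construction. Levels above the
  attainable maximum return an explicit "unattainable" sentinel.
* **Bridge contamination bounds the posterior.** Genuine inter-fold bridges
  score in the sibling range while being labelled $F{=}0$, so the
  top-of-scale posterior plateaus near
  $n_{\text{sib}} / (n_{\text{sib}} + n_{\text{bridge}})$ rather than 1.
  Two practical consequences. If bridges were *not* rare relative to
  sibling pairs, no score would ever reach posterior 0.5 — the calibration
  would (correctly) conclude that a high score carries little information
  about fold co-membership. And in small samples a handful of
  high-scoring bridges can dip the empirical curve below `p` near the top,
  in which case the suffix rule reports a conservative (higher) cutoff; the
  per-pair posteriors used for network construction are unaffected.

A worked micro-example: sibling scores $\{5,7,9\}$ and unrelated scores
$\{1,2,6,8\}$ give priors $3/7$ and $4/7$; at $\bar s = 4$ the conditionals
are $1$ and $0.5$, so the posterior is
$(3/7)/(3/7 + 0.5\cdot 4/7) = 0.6$.

```{r worked}
cs <- fit_calibration(c(5, 7, 9, 1, 2, 6, 8),
                      c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
posterior_at(cs$models$all, 4)
```

## Network construction

**Collapse.** Domain-pair posteriors are collapsed to a chosen hierarchy
level (family, superfamily or fold): entry $(A, B)$ of the group-level
array keeps the single cross-group alignment with the highest posterior,
together with its provenance (the representative domain pair and raw
score). Ties resolve towards the higher raw score. Because the collapse is
a maximum, collapsing to families and then to folds equals collapsing to
folds directly — a property the tests exploit.

**Edge weights.** Each method weights its edges with a quantity on a
structural (not statistical) scale, "greater = more similar":

* TM-score-reporting methods use the TM-score itself;
* methods reporting an optimal RMSD but no TM-score (FATCAT-like) use an
  approximate TM-score
  $\mathrm{TM} \approx (L_{\mathrm{aln}}/\bar L)\,/\,
  \bigl(1 + (\mathrm{rmsd}/d_0(\bar L))^2\bigr)$ with the canonical
  $d_0(L) = 1.24\,(L-15)^{1/3} - 1.8$ and $\bar L$ the mean domain length —
  the TM functional with every aligned deviation set to the reported RMSD,
  using exactly the fields such methods emit. It is flagged as approximate
  in provenance, and a zero RMSD over the full length gives 1;
* elastic-metric methods use the reciprocal of the distance, which is the
  simplest order-reversing positive transform (a zero or negative distance
  is an error, not a silent cap).

**Static and dynamic networks.** Static networks keep edges with posterior
at least the threshold (a closed comparison, matching the "probability
≥ 0.5" convention) at the default ladder 0.5–0.9. The node universe always
retains unconnected folds; renderers may hide them but every analysis keeps
them. The dynamic sweep annotates each collapsed pair with its *birth
threshold* — the highest grid value its posterior reaches as the threshold
relaxes from 1 towards 0.5 — and exports the sequence as GraphML for
animation tooling; the final frame equals the static network at 0.5.

**Consensus.** At each threshold the consensus network keeps exactly the
fold pairs present in all contributing methods' networks. Weights are made
comparable by dividing each method's weights by that method's mean edge
weight *over its own network at the same threshold and level* (the
averaging population is a design choice; the alternative — a global mean
over all thresholds — would let sparse high-threshold networks inherit
scale from dense ones), then averaging the normalised weights per edge. A
single shared edge therefore gets consensus weight exactly 1. With four
methods and five thresholds the sweep emits 25 static networks.

**Edge multiplicity.** Every fold pair of the universe is assigned the
number of methods (0–4) displaying it at a threshold; the histogram over
1–4 totals the union of the edge sets, and multiplicity 0 defines the
unconnected background used by the age analysis.

## Network analysis

Path lengths follow the reciprocal-weight metric
$d(i,j) = \min \sum_{e \in \text{path}} 1/w_e$ (strong bridges are short),
computed by Dijkstra's algorithm; distances across components are infinite.
Centralities are the weighted-network measures:

$$
C_D(i) = \sum_j w_{ij}, \qquad
C_C(i) = \sum_{j \ne i} \frac{1}{d(i,j)}, \qquad
C_B(i) = \sum_{j,k \ne i} \frac{\sigma_{jk}(i)}{\sigma_{jk}},
$$

with closeness summed over the nodes of $i$'s own component (so it is a
harmonic closeness, finite in disconnected networks) and betweenness
counted over unordered pairs under the same metric — both therefore
per-component, as the definitions require. Uniform weight rescaling scales
$C_D$ and $C_C$ linearly and leaves $C_B$ invariant, a property the tests
check along with agreement against exhaustive path enumeration on small
graphs. Near-equal path sums are treated as equal within a relative
tolerance of 1e-9 in the test oracle; the production path counts come from
igraph's weighted Dijkstra.

**Central and peripheral sets.** Central folds are the top 30% per measure,
with all nodes tying the boundary value included (deterministic and
order-independent). Peripheral folds are measure-specific: bottom 30% by
closeness; at most one neighbour, by degree; exactly zero betweenness, by
betweenness — the latter two because degree and betweenness are heavily
right-skewed, so a quantile rule would be dominated by ties at the bottom.
Degree ranks over all nodes; closeness and betweenness rank on
per-component values pooled across components. A node qualifying as both
central and peripheral (possible only in tiny networks) stays central. On
small dense networks the degree periphery can shrink to a couple of nodes,
too few for any rank test to reach conventional significance — the
closeness rule's fixed 30% sets are the dependable comparison there.
Pivotal folds are those central under *every* measure in *every* network,
including the consensus networks.

**Communities.** Louvain modularity maximisation runs on the weighted graph
restricted to connected nodes, with a fixed seed and (default) 10
random-vertex-order restarts keeping the maximum-modularity partition —
Louvain is order-sensitive and the restarts make the reported partition
reproducible and near-optimal on the scales used here. Exhaustive
modularity maximisation over all set partitions of two-clique graphs backs
the implementation in the tests.

**Statistics panel.** Per network: connected-node and edge counts, edges
unique to the network among its siblings at the same threshold, density
over connected nodes, mean neighbour count, mean shortest path within the
largest connected component, the global clustering coefficient (closed
connected triplets over all connected triplets), and component counts
(more than one node; at least 20 nodes).

## Fold ages

Ages are normalised to $[0,1]$: 1 marks a fold whose structural ancestor is
placed at the last universal common ancestor, 0 a recent ancestor. Two
analyses are built in:

* **Edge age differences by multiplicity.** The absolute age difference of
  every fold pair, binned by how many methods display the pair as an edge
  at the analysis threshold; bin 0 — pairs unconnected in *all* per-method
  networks at that threshold — is enumerated exhaustively (no sampling; at
  631 folds this is under 200k pairs). Folds without an age are excluded
  and counted.
* **Central versus peripheral ages.** For every network and measure, a
  two-sided Mann–Whitney U test compares the central and peripheral age
  samples (`wilcox.test`: exact for small tie-free samples, normal
  approximation with tie correction otherwise; completely tied samples
  return p = 1 with a warning). The `central_older` flag requires both
  significance at the configured level (default 0.01) and the central mean
  exceeding the peripheral mean — a two-sided test with a directional
  flag, so the null firing rate is about half the nominal level.

## The synthetic universe

Real inputs for this analysis are an all-against-all alignment of ~4,100
domains with four external programs — unavailable at desk scale. The
`synthetic_data` module therefore generates a universe with every property
the downstream stages consume, planted and therefore checkable:

* **Hierarchy.** Classes `a`–`d` (all-α, all-β, α/β, α+β), a configurable
  number of folds per class (default 10), domains per fold (default 3),
  with families and superfamilies nested inside folds so the intermediate
  collapse levels are non-trivial.
* **Scores.** Each pseudo-method draws sibling scores from a truncated
  normal on $[0,1]$ with mean 0.6, sd 0.1 and unrelated scores from mean
  0.25, sd 0.08 — the TM-score range in which real fold siblings and
  unrelated pairs land. One method is distance-oriented with mirrored
  parameters (sibling 0.4, unrelated 0.75) to exercise the sign-flip and
  reciprocal-weight paths everywhere. Every method also emits an
  uninformative `aux` column for the AUROC selector to reject.
* **Bridges.** A fraction of inter-fold pairs (default 0.05) is planted as
  bridges; each planted bridge draws, per method independently with
  probability `method_agreement` (default 0.8), its representative domain
  pair's score from the sibling distribution ("visible" to that method).
  Nine of ten bridges are allocated to fold pairs inside the same planted
  community, the rest across communities, which creates the five-block
  structure (all-α, α/β, α+β, β-sandwich, β-barrel — the β class split in
  half) that community detection is expected to recover. The default
  bridge rate keeps bridges rare relative to sibling pairs for two
  reasons: the real networks have the same property (tens of thousands of
  bridges against 8.4 million pairs), and the calibration mathematically
  requires it — planting bridges at a rate above the sibling prior caps
  the attainable posterior below 0.5 and empties every network, which is a
  property of the model, not a bug of the generator.
* **Ages.** Fold ages are uniform on $[0,1]$ subject to the planted
  constraint that bridge endpoints differ by at most `age_assortativity`
  (default 0.05). With chained bridges this is a joint constraint, realised
  by a breadth-first pass over each component of the bridge graph (each
  fold drawn uniformly on its tree parent's ±δ window — for a single pair,
  exactly the law of resampling until the gap is small enough) plus repair
  sweeps that redraw a violating endpoint only inside the intersection of
  all its partners' windows, so satisfied constraints are never broken.
  δ = 0 makes constrained groups share one draw; δ ≥ 1 is vacuous, so ages
  are exactly uniform. Because the constraint propagates along connected
  bridge components, the default bridge rate is also chosen to keep those
  components small: with many cross-community bridges the whole fold
  universe would be pulled into one narrow age window and the unconnected
  background would no longer resemble independent uniforms.
* **Coordinates.** Minimal synthetic poly-alanine PDB traces with 3.8 Å
  consecutive C-alpha spacing, an optional planted gap above the 4.3 Å
  chain-break threshold, and an optional C-alpha-only reduction, for the
  QC stage. These are labelled synthetic stand-ins; they have no realistic
  3D structure by design.

One master seed derives independent child seeds for the hierarchy, bridge,
score and age stages, so any stage can be regenerated alone and every
output is bit-for-bit reproducible.

**What the generator does not emulate** — and hence what green tests do not
certify about real data: heavy-tailed or multimodal score distributions,
correlations between methods beyond shared visibility of planted bridges,
alignment-length artefacts, the discreteness of real age estimates (many
real folds sit exactly at age 1), and the 631-fold scale. The tests certify
the *machinery* — calibration, collapse, consensus semantics, centrality
arithmetic, recovery of planted effects — not any biological claim.

## Problem sizes and study conditions

The shipped analyses run on sizes chosen to keep the full suite quick on a
single CPU while leaving every statistic well away from degeneracy: a
40-fold / 120-domain default universe (7,140 pairs per method) for the
pipeline and age analyses; a 48-fold / 288-domain universe with a denser
bridge plant (bridge fraction 0.2, agreement 0.98) for community-recovery
studies, where the posterior plateau works out to roughly 0.77 and the
consensus network carries the five planted blocks essentially noise-free;
and 100,000 pairs for the calibration-convergence study, where the
empirical posterior-0.5 cutoff lands within 0.02 score units of the
closed-form truncated-normal cutoff.

## Limitations

* The calibration is purely empirical; in sparse score regions the
  suffix-rule cutoffs are conservative, and a partition with very few
  sibling pairs yields noisy posteriors (the all-α partition of a small
  universe is the worst case).
* The consensus requires an edge in *all* methods; with unreliable methods
  this is stringent, and no majority-vote variant is provided.
* Louvain has a resolution limit: planted communities much smaller than
  $\sqrt{2m}$ internal edges may merge regardless of seed or restarts.
* Ages are inputs; the package neither estimates them nor models their
  uncertainty, and the age analyses are rank-based comparisons only.
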