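# foldbridges

Consensus networks of structural bridges across protein fold space.

Structural alignment programs regularly find significant similarities
between domains assigned to *different* SCOP folds. Each such inter-fold
similarity is a "structural bridge", and the bridges form a network over
folds — a map of fold space. `foldbridges` builds and analyses these maps
for researchers in structural bioinformatics who want to compare fold-space
organisation across alignment methods rather than trust any single one.

The package implements, end to end:

1. **Score calibration.** For each alignment method, the posterior
   probability that a domain pair shares a fold given its score exceeds a
   threshold s̄:

   P(F=1 | S>s̄) = P(S>s̄|F=1)·P(F=1) / [ P(S>s̄|F=1)·P(F=1) + P(S>s̄|F=0)·P(F=0) ]

   with priors and survival functions estimated empirically (no smoothing),
   separately for comparisons involving all-α domains, and inverted into
   per-method score cutoffs at any posterior level (upper limits for
   distance-oriented scores such as an elastic metric).
2. **Network construction.** Collapse of the domain-pair posterior array to
   family / superfamily / fold level (each fold pair keeps its
   maximum-posterior alignment with provenance), structural edge weights
   (TM-score, approximate TM from RMSD and lengths, inverse elastic
   metric), static networks at thresholds 0.5–0.9, a dynamic
   birth-threshold sweep from 1.0 down to 0.5, and consensus networks
   holding the edges found by *all* methods with mean-normalised averaged
   weights — 25 static networks per run.
3. **Network analysis.** Dijkstra shortest paths under the
   reciprocal-weight metric, weighted degree / closeness / betweenness
   (per connected component), central and peripheral fold sets (top 30%
   versus rule-based peripheries), Louvain communities with seeded
   restarts, a per-network statistics panel, and pivotal folds (central by
   every measure in every network).
4. **Fold-age analysis.** Absolute edge age differences binned by edge
   multiplicity (0–4 methods) against the unconnected background, and
   central-versus-peripheral age comparisons with two-sided Mann–Whitney U
   tests.
5. **Synthetic data.** A generator that plants a SCOP-like hierarchy,
   per-method score distributions, inter-fold bridges with a five-block
   community structure, bridge-age assortativity and coordinate fixtures,
   so the whole pipeline is testable without external databases.

## Worked example

Simulate a planted universe and run the full pipeline:

```r
library(foldbridges)

spec <- synthetic_spec(seed = 20)          # 4 classes x 10 folds x 3 domains
cfg  <- simulate_inputs(spec, "demo")      # writes TSV inputs + truth tables
res  <- run_pipeline(cfg)                  # calibrate, build, analyse

res$networks[["consensus@0.5"]]
#> fold_network: consensus @ fold level, threshold 0.5: 40 nodes (20 connected), 15 edges

subset(res$statistics, method == "simA",
       select = c(threshold, n_connected_nodes, n_edges, avg_shortest_path_lcc))
#>    threshold n_connected_nodes n_edges avg_shortest_path_lcc
#> 1        0.5                40     104              4.829493
#> 6        0.6                38      64              6.014252
#> 11       0.7                31      30              8.061597
#> 16       0.8                11       6              2.539642
#> 21       0.9                 2       1              1.865812

res$age_bins$summary
#>   multiplicity   n     median          q1         q3
#> 1            0 592 0.36197568 0.054495895 0.66370016
#> 2            1 138 0.20739631 0.037502791 0.66889660
#> 3            2  20 0.04977235 0.027872196 0.62924368
#> 4            3  18 0.03131626 0.029346019 0.03886716
#> 5            4  12 0.01387801 0.009873865 0.03547159
```

Reading the output: the method networks thin out and fragment as the
posterior threshold rises (104 edges over all 40 folds at 0.5, a single
edge at 0.9), exactly the static-sweep behaviour the thresholds ladder is
for. The age table shows the planted signal: fold pairs bridged by all
four pseudo-methods differ in age by a median of 0.014 — below the planted
assortativity of 0.05 — while the unconnected background sits at 0.36,
near the independent-uniform value. The artifact directory
(`cfg$output_dir`) holds the 25 static networks as GraphML and TSV edge
lists, per-method dynamic sequences, the score-cutoff table, centrality
and community tables, the statistics panel and a JSON run manifest.

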