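# netprox

Batch-aware differential expression and network-proximity analysis of
case/control bulk RNA-seq studies.

## The problem

Integrating tumor/normal RNA-seq datasets collected by different labs
requires removing between-study (batch) variation before testing for
differential expression, and a list of significant genes is rarely the end
point: co-expression structure and protein–protein interaction (PPI)
topology are what connect statistical hits to candidate biomarkers.
`netprox` implements that full path as one tested pipeline:

1. **Preprocess** — median-of-ratios size factors (computed within each
   batch), `log2(count/factor + 1)` transform, and a parametric
   empirical-Bayes location/scale batch adjustment (ComBat-style) with the
   condition protected as a covariate.
2. **DGE** — moderated two-group *t* statistics with variance shrinkage
   `s²̃ = (d₀s₀² + d s²)/(d₀ + d)` (prior estimated by method of moments on
   log s²), Benjamini–Hochberg step-up control, and the
   `padj < 0.05, |log2FC| ≥ 1` filter.
3. **WGCN** — co-expression network on the DEGs with edges `|r| ≥ r_min`
   and soft-power weights `|r|^β`, giant-component extraction, node weights
   as weighted degree, and the unsigned topological overlap measure
   `TOM_ij = (Σ_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij)`.
4. **Core proximity** — all-pairs Dijkstra shortest paths on
   similarity-derived edge lengths and, for each node *j* against a
   designated core gene set *c*,

   ```
   D_j = ( Σ_{i∉c} SP_ij / NC  −  Σ_{i∈c} SP_ij / C ) / ( Σ_i SP_ij / (NC+C) )
   ```

   so `D_j > 0` means *j* is closer to the core than to the network
   background; the positive-D subnetwork is extracted.
5. **PPIN** — STRING-dialect edge lists (combined score ≥ 400 by default),
   per-node degree *K*, betweenness *BC* (unnormalized, unordered pairs),
   closeness *CC* = (n−1)/Σd, hub classification (*K* > 13 and
   *BC* > 63.94), nonhub classification (neighbors of hubs with *K* ≤ 3 and
   *BC* < 9, or distance-2 neighbors with *K* ≤ 3 and *BC* = 0),
   whole-network metrics, and greedy (CNM-style) modularity clustering.
6. **Association** — pairwise Pearson correlations with t-based tests among
   hub / nonhub / focal gene groups, BH-adjusted, summarized per group pair
   by sign and significance.

A synthetic-data module generates negative-binomial counts with planted DE
genes, batch effects, a co-expressed core module, an anti-correlated focal
gene, and interaction graphs with known hubs/nonhubs, so the whole pipeline
runs and is validated without any downloads.

## Worked example

```r
library(netprox)
fx  <- write_fixtures(simulation_config(seed = 1), "demo_fx")
man <- run_pipeline(fx$config)
```

prints a manifest whose stage counts on this fixture are:

```
preprocess : genes_kept=1969 samples=40 batches=2
dge        : n_tested=1969 n_significant=106 n_up=50 n_down=49
wgcn       : n_candidate_genes=99 n_nodes_giant=99 n_edges_giant=2428
coreprox   : n_core=30 n_neighbors=1 n_subnetwork=31
ppin       : n_nodes=56 n_edges=56 n_hubs=3 n_nonhubs=49 n_clusters=3
association: n_pairs=1326 n_groups=3
```

The generator planted 100 DE genes (5% of 2000) at |log2FC| = 2 — the DGE
stage recovers 99 of them after low-expression filtering, with no false
positives.  The three planted interaction hubs are classified `hub`, and
the correlation summary recovers the planted focal-gene pattern — the
focal gene is significantly *negatively* correlated with all 3 hubs
(`focal/hub: negative_significant = 3, total = 3`) while hubs correlate
positively with each other, the pattern that flags a gene behaving against
its module.  Per-gene D-scores are in `demo_fx/out/d_scores.tsv`; core
module members score highest (D ≈ 0.9), meaning their mean shortest path
to the core (≈ 0.17) is far below their mean path to the background
(≈ 0.59).

The same run is available from the command line:

```sh
Rscript -e 'netprox::netprox_cli()' simulate --out-dir demo_fx --seed 1
Rscript -e 'netprox::netprox_cli()' run-all --config demo_fx/config.json
```

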