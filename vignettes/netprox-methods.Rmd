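---
title: "netprox: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{netprox: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netprox)
```

`netprox` integrates multi-batch tumor/normal RNA-seq count data into a
differential-expression call set, a weighted co-expression network, a
shortest-path core-proximity ranking, and PPI-network topology statistics.
This vignette documents the statistical models, every tunable parameter
that matters, the synthetic world the generator emulates, and the design
choices made where the methods literature leaves the design open.

## 1. Normalization and batch adjustment

**Size factors.** Median-of-ratios: for sample *s*,
`f_s = median_g (count_gs / gm_g)` over genes whose geometric mean `gm_g`
across samples is positive (equivalently: genes with no zero count).  The
pipeline computes factors *within each batch* rather than globally, then
batch-adjusts; per-batch normalization followed by adjustment is the
protocol that gives the cleanest post-adjustment mixing in our synthetic
experiments, and size factors estimated within a batch are not distorted
by between-batch composition shifts.

**Log transform.** `log2(count / f_s + 1)`, base 2 and pseudocount 1
throughout; all fold changes downstream are differences of these values.

**Low-expression filter.** Genes with count ≥ 10 in ≥ 25% of samples are
kept (both knobs configurable: `min_count`, `min_fraction`).  No single
accepted threshold exists; this is the conventional "clearly detected in a
quarter of the libraries" default.

**Batch adjustment.** Parametric empirical-Bayes location/scale
adjustment of the log-normalized matrix:

1. fit per-gene batch means and a protected condition effect by least
   squares; standardize residual variation by the pooled per-gene variance;
2. estimate per-gene-per-batch location `γ̂_gb` (batch mean of the
   standardized data) and scale `δ̂²_gb` (batch variance);
3. shrink toward batch-level hyperpriors estimated by method of moments — a
   normal prior for γ and an inverse-gamma prior for δ² — via the standard
   fixed-point iteration (tolerance `conv = 1e-6`);
4. subtract/divide the shrunken effects and restore the condition effect
   and pooled scale.

Only the parametric prior family is implemented; a non-parametric variant
adds cost without changing behaviour on data this model generates.  A
single batch is an identity transform (with a warning); a batch confounded
with condition triggers a warning because its location effect cannot be
separated from biology.

*Numerical note.* EB shrinkage leaves a residual between-batch mean gap of
order `1/sqrt(n_per_batch)` on each gene (the prior pulls per-gene batch
means toward the batch average).  This is inherent to the estimator, not a
convergence artifact: the shift-removal tests use 400 samples per batch,
where the residual is comfortably below the 0.05 tolerance.

## 2. Differential expression

Per gene, the tumor-minus-normal difference of log2 means is tested with a
pooled-variance t statistic whose variance is moderated:
`s²̃_g = (d₀ s₀² + d s²_g)/(d₀ + d)` with `d = n₁ + n₂ − 2`.  The prior
`(d₀, s₀²)` is estimated by method of moments on `log s²_g`, using the
digamma/trigamma moments of the log of a scaled F-distributed variance;
the trigamma inverse is solved by Newton iteration.  When the observed
spread of log-variances does not exceed its sampling component, `d₀ = ∞`
and every gene is tested at the common variance.  `prior_df = 0` recovers
the ordinary two-sample pooled t test exactly (verified against
`t.test(var.equal = TRUE)`), which pins the estimator's limiting behaviour.

BH adjustment is the step-up rule `padj_(i) = min_{k ≥ i} m p_(k)/k`
capped at 1.  Significance uses a *strict* `padj < α` and an *inclusive*
`|log2FC| ≥ fc_min` (defaults α = 0.05, fc_min = 1): a gene at exactly
padj = 0.05 is not significant, a gene at exactly log2FC = 1 passes the
fold-change filter.  Batch is handled entirely upstream by the adjustment
stage; the test itself has no covariates beyond condition, mirroring the
adjust-then-test order of the pipeline.

Calibration: on null negative-binomial simulations (10 seeds × 2000 genes,
n = 10/10) the empirical type-I error at p < 0.05 is within 0.05 ± 0.015,
and with planted |log2FC| = 2 at n = 20/20 and dispersion 0.1 the filter
recovers ≥ 90% of planted genes at empirical FDR ≤ 0.10.  These are
computed by the test suite, not quoted from anywhere.

## 3. Co-expression network and TOM

Edges join DEGs with `|Pearson r| ≥ r_min` and carry weight `|r|^β`
(defaults `r_min = 0.7`, `β = 1`).  Unsigned correlation is used because
up- and down-regulated genes are deliberately mixed in one network — an
anti-correlated gene should sit *near* its module, not be disconnected
from it.  Thresholding is on r itself rather than on the p-value of r:
with the sample sizes involved, p-thresholds admit correlations too weak
to be meaningful co-expression.  Constant-expression genes are excluded
with a warning (their correlation is undefined).

The giant component is extracted (ties broken toward the component
containing the lexicographically smallest node id, for determinism), node
weights are the sum of incident edge weights (strength), and the unsigned
topological overlap is

TOM_ij = (Σ_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij),  TOM_ii = 1,

computed after an explicit symmetrization guard `(A + Aᵀ)/2`.  On valid
adjacencies (entries in [0, 1], guaranteed by the `|r|^β` construction)
TOM is symmetric and bounded in [0, 1], and increases with shared-neighbor
weight at fixed connectivity — both property-tested.

## 4. Core proximity

Similarities become lengths by `1 − TOM` (floored at ε = 1e−6, so exact
duplicates keep a positive length) — the default, since TOM ∈ [0, 1] makes
its complement a natural dissimilarity — or by `1/similarity`
(`length_mode = "reciprocal"`).  Shortest paths run on the TOM-derived
graph by default; the raw `|r|^β` graph is accepted as an alternative
input, since either reading is defensible.  All-pairs Dijkstra (verified
against Floyd–Warshall exhaustively on small graphs) yields SP, and each
node *j* is scored against the core set *c*:

D_j = (Σ_{i∉c} SP_ij / NC − Σ_{i∈c} SP_ij / C) / (Σ_i SP_ij / (NC + C)).

Conventions: sums exclude `i = j` (including the zero self-distance would
deflate the averages asymmetrically); `C` and `NC` are recomputed per node
after that exclusion, so the score is defined for core members too;
unreachable nodes are excluded from the sums (the pipeline restricts to
the giant component first, making this moot in practice); a node whose
core or noncore reachable set is empty is flagged `defined = FALSE` rather
than scored.  D is invariant to rescaling all edge lengths and positive
exactly when the mean path to the core is shorter than to the background —
both property-tested.  The positive-D subnetwork is the induced subgraph
on the core plus all noncore nodes with D > 0.

The core list is user-supplied (one gene id per line); how such seed lists
are chosen is study-specific and outside this package's scope.  When no
list is given the pipeline falls back to the top-k DEGs by |log2FC|
(`top_k_core`, default 10) — an explicit, reproducible default, not a
claim about what any particular study did.

## 5. PPI network

STRING-dialect TSVs are parsed with a combined-score cutoff (default 400,
the usual medium-confidence value; the evidence-channel requirement is a
configurable column list because no universal channel subset exists),
duplicate orientations merged keeping the maximum score, weight =
combined_score/1000.

Topology statistics run on the unweighted skeleton: degree K; betweenness
BC by Brandes' algorithm with each unordered pair counted once and *no*
normalization (raw pair counts — the scale on which published hub
thresholds like 63.94 live); closeness CC = (n_comp − 1)/Σd per connected
component, so CC · mean_distance = 1 on a component.  All four equal
brute-force enumeration oracles (matrix-power path counting) on hundreds
of random graphs in the test suite.

Classification: hub iff K > 13 and BC > 63.94 (strict, configurable).
Nonhub: a non-hub that is a direct neighbor of a hub with K ≤ 3 and
BC < 9, or at distance exactly two from a hub with K ≤ 3 and BC = 0.  The
degree bound is *inclusive* (≤ 3): published tables of this analysis style
label degree-3 nodes nonhubs even where the prose says "less than three",
and the inclusive reading reproduces those tables; the bound is a
parameter for anyone preferring the strict reading.  With `graph = NULL`
the classifier applies the (K, BC) bounds alone — the mode used to
re-score printed tables, where adjacency is unavailable.

Clustering is agglomerative greedy modularity maximization: merge the
edge-connected community pair with the largest ΔQ until no positive gain
remains, ties broken by the lexicographically smallest pair of community
labels (a community is labeled by its smallest member id), making the
result deterministic.  On an 8-node two-clique benchmark the result equals
the exhaustive-enumeration modularity optimum over all 4140 partitions.

## 6. Association stage

Pairwise Pearson correlations among all grouped genes (hub / nonhub /
focal), two-sided p from `t = r√((n−2)/(1−r²))` with n − 2 df, BH
adjustment across the report by default (`adjust = "none"` available —
correlation reports in the literature are often unadjusted, so both
conventions are exposed).  The summary counts positive-significant /
negative-significant / non-significant pairs per group pair; effect sign
and significance are reported separately rather than collapsed, because a
"negative but not significant" pattern is itself informative for a
focal-gene analysis.  Correlations are computed on the batch-adjusted
matrix, the same values used for DE and the networks.

## 7. The synthetic world

`simulate_counts()` draws NB counts with variance `μ + μ²·φ` (dispersion
φ = 0.1, a typical bulk RNA-seq value), per-gene baseline log2 means
U(3, 9), library-size factors U(0.5, 2), and a two-condition design of
20 + 20 samples in 2 batches (round-robin within condition, so batch is
never confounded with condition).  Batch effects follow the location/scale
model the adjustment stage estimates: additive per-gene-per-batch shifts
N(0, 1²) on the log2 scale — strong enough to dominate PC1, as in real
multi-study merges — and lognormal(0, 0.2²) factors on the biological
noise (sd 0.3).  5% of genes are DE at |log2FC| = 2, half up, half down.
A 30-gene core module (drawn from the up-regulated DE genes when they
suffice, so the module survives DEG filtering) shares one latent N(0, 1)
factor with loading 0.8 — the simplest controllable correlation structure,
giving within-module |r| ≈ 0.7 against background ≈ 0.  One DE-down
"focal" gene loads −0.8 on the same factor, emulating a gene
anti-correlated with its module.  Graph models: `planted_hub` (hub clique,
15 leaves per hub, designated degree-≤3 nonhubs attached at distance 1 or
2), `erdos_renyi`, and `barabasi_albert`.

What a green test does **not** establish: the generator's genes are
independent given the factor (no correlated gene families beyond the one
module), counts have no outlier samples or GC/length biases, batch effects
are exactly the model the adjuster assumes (so adjustment quality on real
data, where the model is misspecified, will be worse), and effect sizes
are homogeneous.  Recovery rates measured here are upper bounds on
real-data behaviour.

## 8. Degenerate inputs and numerical conventions

- All-zero count matrices, empty graphs, cores that span the whole
  network, and single-condition designs raise errors naming the problem;
  single-batch adjustment and single-sample size factors degrade to
  identities with warnings.
- Constant genes: excluded from correlation networks (warning), guarded by
  a variance floor (1e−12) in the batch adjuster, flagged undefined in
  correlation reports.
- Determinism: every stochastic routine takes its seed from the
  configuration; equal configs give bit-identical matrices, graphs, files
  and manifests (timestamps live only in the log).
- The run config is JSON (`jsonlite`); CLI flags override file values.

## 9. Known limitations

- The moderated test assumes approximate normality of log counts; at very
  low means its calibration degrades (the default filter removes most such
  genes).
- Betweenness/closeness are unweighted; weighted centralities on the
  combined-score graph are a possible extension, but published hub
  thresholds are unweighted-scale.
- The greedy modularity maximizer has the usual resolution limit and can
  miss the global optimum on adversarial graphs; it is exact on the
  benchmark used here.
- No identifier mapping (gene symbol ↔ protein id) is performed; inputs
  must share a namespace.
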