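---
title: "Differential miRNA-target regulatory networks: methods and design"
author: "mgdrn package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential miRNA-target regulatory networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgdrn)
```

# The problem

MicroRNAs (miRNAs) repress their target mRNAs, so across a set of samples a
functional miRNA-target pair tends to show a *negative* expression
correlation. In cancer this repression is often rewired: a coupling that is
strong in normal tissue can be attenuated (or strengthened) in tumors. The
miRNA-gene differential regulatory network (MGDRN) makes this rewiring the
object of study. An edge is a candidate miRNA-target pair whose
per-condition Pearson correlation changes materially between the tumor and
normal sample groups; the network of such edges can then be mined for key
regulators (by centrality) and for groups of miRNAs that jointly dysregulate
the same pathways.

This package implements the full procedure — consensus target catalog,
fold-change differential expression, per-condition negative-correlation
networks, the differential network with dysregulation directions,
centrality-based key-regulator ranking, hypergeometric pathway
over-representation and bicluster-based synergy modules — together with a
synthetic-data generator that plants each of these structures so the whole
chain is testable at desk scale.

# The procedure, stage by stage

## Consensus target catalog

Sequence-based target prediction is noisy, and different databases disagree;
the conventional remedy is to keep only pairs predicted by several
independent sources. `buildCatalog()` keeps a (miRNA, gene) pair when it
appears in at least `minSources` *distinct* prediction tables (a pair listed
twice inside one table counts once). The default is `minSources = 2`:
requiring agreement between at least two of the seven canonical sources
(TargetScan, miRanda, PicTar and the like) retains sensitivity, while a
cutoff of three already shrinks such catalogs drastically. The parameter is
exposed because the right trade-off is data-dependent.

Identifiers are normalized by lower-casing and whitespace-stripping only.
Prediction tables mix precursor (`hsa-mir-152`) and mature
(`hsa-mir-152-3p`) namespaces; expression profiles are mature.
`mapToMature()` expands precursor ids to their mature arms from a
two-column mapping table. Unmapped precursor-style ids pass through with a
warning rather than an error, so partial maps remain usable; silently
dropping them would bias the catalog, and failing hard would make every
miRBase version mismatch fatal.

## Differential expression by fold change

`computeLog2FoldChange()` uses arithmetic means per condition and

$$\log_2\mathrm{FC} = \log_2\frac{\bar{x}_\mathrm{tumor} + c}
{\bar{x}_\mathrm{normal} + c},$$

with pseudocount $c = 0.01$ (RPKM scale) so zero-expression entities stay
finite; for any entity expressed above noise the pseudocount is negligible,
and the tests verify convergence to the plain mean ratio as $c \to 0$.
Selection keeps entities with $|\log_2\mathrm{FC}|$ *strictly* greater than
1, i.e. fold change above 2 or below 0.5 — the strict inequality mirrors
that rule exactly. By default only genes are filtered; the miRNAs entering
the network are those that regulate a selected gene. A `filterMirnasByFC`
flag additionally requires miRNAs to pass the same filter, since practice
varies on whether regulator nodes must themselves be differentially
expressed.

## Per-condition networks and the differential network

For every catalog pair whose gene was selected, the Pearson correlation is
computed separately over the normal and the tumor samples (at least three
samples per condition; pairs with zero variance are dropped, not imputed).
Within a condition, an edge is kept only when the correlation is strictly
negative — the sign consistent with repression.

`buildMGDRN()` then compares the two networks. A pair is *eligible* when it
carries a negative edge in at least one condition; the other condition's
raw, sign-unfiltered correlation is used for the comparison. Requiring
negativity in *both* conditions would discard exactly the strongest
rewiring events (negative in normal, positive in tumor), which are the
phenomenon of interest. The edge is kept when

$$|\Delta| = |r_\mathrm{tumor} - r_\mathrm{normal}| > 0.2$$

strictly, and labelled `up` when $\Delta > 0$ (repression weakened in
tumor) or `down` otherwise. The difference is taken on *signed*
correlations: that is the only reading under which the up/down direction
labels are well defined, and it matches the interpretation of a weakened
negative regulation as "up-dysregulated". A `deltaMode = "absolute"` option
gates on $||r_\mathrm{tumor}| - |r_\mathrm{normal}||$ instead, for
comparison. Up- and down-counts always partition the edge set, and every
gene node passes the DE filter — both are asserted as invariants in the
test suite.

## Topology and key regulators

The MGDRN is treated as an undirected, unweighted bipartite graph. Three
standard centralities are reported per node:

* **degree** — incident edge count;
* **betweenness** — $\sum_{s \ne v \ne t} \sigma_{st}(v)/\sigma_{st}$ over
  unordered pairs, endpoints excluded, unreachable pairs contributing 0;
  normalized by $(N-1)(N-2)/2$;
* **closeness** — the raw form $1/\sum_u d(u,v)$, and (default) the
  Wasserman–Faust normalization
  $\frac{r-1}{\sum d}\cdot\frac{r-1}{N-1}$ with $r$ the node's component
  size. The raw reciprocal-of-total-distance form is bounded by
  $1/(N-1)$ in any connected network, i.e. of order $10^{-3}$ for a
  thousand-node network, whereas reported closeness values in this kind of
  analysis are typically of order 0.2 — the magnitude the normalized form
  produces. Both modes are kept; `normalized` is the default.

Shortest-path machinery is delegated to igraph; the test suite checks
degree, betweenness and closeness against an independent all-pairs BFS
path-counting oracle (one hundred random bipartite graphs of up to 30
nodes, tolerance $10^{-9}$), including disconnected graphs.

`topK()` ranks miRNA nodes per centrality (ties broken lexicographically
for determinism; an option returns all nodes tied at the k-th value) and
`keyRegulators()` intersects the three top-10 lists. Arm suffixes
(`-3p`/`-5p`) are stripped before intersecting so the two arms of one
precursor count as one regulator.

## Pathway synergy

For each miRNA, its MGDRN target set is tested for over-representation in
every pathway with the exact upper-tail hypergeometric probability
$P(X \ge k)$ — the standard model for gene-set over-representation under
sampling without replacement. This is a deliberate, documented replacement
for web-service annotation tools; an `ease` option implements the more
conservative EASE variant ($k-1$), and Benjamini–Hochberg correction is
available by flag but off by default, matching the common raw
$p < 0.05$ screening convention. The background universe defaults to the
catalog genes that are also measured, and is configurable because
enrichment results are sensitive to it.

The significance matrix holds $-\log_{10}p$ where $p < \alpha$ and 0
elsewhere; all-zero rows and columns are dropped. Synergy modules are
extracted by bi-directional hierarchical clustering (Euclidean distance,
complete linkage by default): rather than scanning single cut heights, the
candidate blocks are all pairs of row-dendrogram and column-dendrogram
*subtrees* meeting the size minima (2 x 2 by default) — the union of the
clusters produced by every possible cut, which is deterministic and cannot
miss a block that any single cut would find. A block is a module when its
fraction of significant cells is at least `minDensity = 0.8` (module
boundaries in published heatmaps are drawn by eye; a high density threshold
is the reproducible surrogate). Overlapping candidates are resolved by
density, then size, and accepted modules never overlap in both dimensions
at once.

# The synthetic generator

`simulateDataset()` emulates the statistical structure the analysis
assumes, not RNA-seq reads:

* log-normal expression with log-scale standard deviation 0.4 for both
  entity kinds — a typical dispersion for RPKM-like data — and log-means
  uniform on $[\log 5, \log 500]$;
* each *true edge* couples one target gene to one miRNA through a shared
  standardized log-score. The log-scale correlation is found by bisection
  so that the *raw-scale* (exponentiated) correlation matches the target,
  using the closed-form lognormal correlation
  $(e^{\rho s^2}-1)/(e^{s^2}-1)$. At $s = 0.4$ the reachable negative
  range extends to about $-0.85$, covering the defaults (-0.7 in normal;
  -0.1 in tumor for dysregulated edges, so the planted $|\Delta|$ is 0.6);
* coupled genes receive a tumor mean shift of $\pm 2$ on the log2 scale,
  making them (and only them, up to sampling noise) differentially
  expressed;
* every true edge is placed in at least two prediction sources (in the
  precursor namespace, exercising the mature-id conversion); 200 decoy
  pairs are placed in exactly one source, except a 10% multi-source
  fraction that survives the consensus filter and must be rejected by the
  correlation filters instead;
* pathway gene sets are built so that each planted module miRNA (six
  dysregulated targets each) has most of its targets inside each of its
  module pathways; the default plants a 3 miRNA x 12 pathway and a
  4 miRNA x 4 pathway block. Non-module pathways are random gene samples.

The default fixture is 200 genes, 50 miRNAs and 60 + 60 samples — large
enough that sample correlations concentrate (the standard error of a
correlation at $n = 60$ is about 0.13 for independent pairs), small enough
that a full pipeline run takes a couple of seconds. The acceptance checks
run 20 seeds of this fixture and take medians.

What the generator deliberately omits: count-model (negative binomial)
noise, library-size and batch effects, many-to-many regulation (each
coupled gene has exactly one regulator), correlated decoys, and any
pathway-annotation redundancy. Passing tests therefore demonstrate that the
pipeline recovers the structure it is designed to detect under its own
model assumptions — not that the thresholds are optimal for any particular
real dataset.

# Numerical and degenerate-input choices

* All thresholds are strict inequalities (`> 1`, `< 0`, `> 0.2`,
  `< 0.05`).
* Correlations need at least 3 samples per condition and finite variance;
  undefined correlations drop the pair with a logged count.
* An empty condition network is a warning, not an error; a differential
  comparison where the out-of-network side is undefined skips the pair.
* Graphs with fewer than 3 nodes have zero betweenness; isolated nodes
  have zero closeness.
* Ranking ties are lexicographic; clustering uses `hclust`'s deterministic
  agglomeration, so identical inputs give byte-identical outputs (asserted
  in the suite).
* The generator restores the caller's RNG state and fixes the generator
  algorithms (Mersenne-Twister, inversion, rejection sampling) explicitly.

# Known limitations

* Correlation thresholds carry no significance assessment: with few
  samples per condition, a |delta| > 0.2 rule admits many chance edges
  (the multi-source decoys in the generator quantify this at the default
  sample size).
* The DE filter's pseudocount and the fold-change rule assume RPKM-like,
  pre-normalized input; no normalization is performed.
* Module extraction reports only dense blocks; diffuse synergy (many
  miRNAs weakly sharing pathways) is out of reach by design.
* The hypergeometric test treats genes as exchangeable; pathway size and
  expression-level biases are not modelled.

# Reproducing the analysis

```{r, eval = FALSE}
run <- runSyntheticPipeline(syntheticConfig(seed = 1))
run$edgeScore      # precision / recall of planted dysregulated edges
run$moduleScore    # per-planted-module Jaccard recovery
```

`scripts/acceptance.R` (repository root) repeats this over 20 seeds and
writes the summary quantities as JSON.
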