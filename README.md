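# mgdrn

Construction and analysis of **miRNA-target gene differential regulatory
networks (MGDRN)** from paired tumor/normal expression data.

miRNAs repress their target mRNAs, so a working miRNA-target pair shows a
negative expression correlation across samples. In tumors this repression
is often rewired. `mgdrn` finds the rewired pairs and what they imply:

1. **Consensus catalog** — keep (miRNA, gene) pairs predicted by at least
   `minSources` (default 2) independent prediction databases, after
   converting precursor miRNA ids to mature arms.
2. **Differential expression** — fold-change filter on genes,
   `|log2 FC| > 1` (fold change > 2 or < 0.5), with a pseudocount for
   zeros.
3. **Condition networks** — per condition (normal, tumor), keep catalog
   pairs with strictly negative Pearson correlation *r* over that
   condition's samples.
4. **Differential network** — keep pairs with
   `|r_tumor − r_normal| > 0.2`; label them `up` (repression weakened in
   tumor) or `down`. This bipartite graph is the MGDRN.
5. **Key regulators** — degree, betweenness and closeness centrality
   (Wasserman–Faust normalization by default); intersect the three top-10
   miRNA lists.
6. **Pathway synergy** — per-miRNA exact hypergeometric
   over-representation of MGDRN targets in pathway gene sets (GMT);
   bi-directional hierarchical clustering of the `−log10 p` significance
   matrix into dense miRNA × pathway synergy modules.

A synthetic-data generator plants every one of these structures (negative
couplings attenuated in tumor, fold-change shifts, multi-source prediction
tables with decoys, miRNA × pathway synergy blocks) with known ground
truth, so the whole chain is verifiable at desk scale. See the methods
vignette (`vignettes/mgdrn-methods.Rmd`) for the model, parameter and
design details.

## Worked example

Simulate the default fixture (200 genes, 50 miRNAs, 60 + 60 samples, 100
planted dysregulated edges with correlation −0.7 in normal attenuated to
−0.1 in tumor, two planted synergy blocks), run the full pipeline on the
written files, and score against the planted truth:

```r
library(mgdrn)
run <- runSyntheticPipeline(syntheticConfig(seed = 1), dir = "example")

run$result$catalog
#> InteractionCatalog: 170 consensus pairs (minSources = 2)
#>   48 miRNAs, 154 genes

run$result$mgdrn
#> MGDRN: 103 differential edges (103 up, 0 down) between 39 miRNAs and
#> 101 genes; |delta| > 0.2

run$edgeScore
#> precision    recall
#> 0.9708738 1.0000000

run$moduleScore
#> [1] 1 1

run$result$modules[[1]]
#> SynergyModule: 3 miRNAs x 12 pathways, density 1
```

Reading the numbers: of the 933 raw predicted pairs across seven sources,
170 survive the two-source consensus (the planted 150 true edges plus the
multi-source decoys). The MGDRN recovers 103 edges — all 100 planted
dysregulated couplings (recall 1.0) plus 3 chance edges (precision 0.97);
all are `up` because the planted rewiring weakens repression in tumor.
Both planted synergy modules (3 × 12 and 4 × 4) are recovered exactly
(Jaccard 1). Every artifact (catalog, DE tables, condition networks, MGDRN
TSV + GraphML, centrality report, key-regulator JSON, enrichment table,
significance matrix, module JSON, heatmap, run log) is written under
`example/output/`; `run$result$manifest` lists the paths.

Real data enter through the same file dialects via `pipelineConfig()` /
`loadPipelineConfig()` (YAML) and `runPipeline()`: expression TSVs plus a
sample-condition map, one two-column TSV per prediction source, an
optional precursor-to-mature map, and a GMT file. A thin command-line
wrapper is provided at `inst/scripts/run_pipeline.R`.

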