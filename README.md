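# scCommNet

Ligand–receptor communication networks and spatially autocorrelated gene
discovery for single-nuclei RNA-seq.

## What it is for

Comparing a diseased tissue against matched controls with snRNA-seq
raises two recurring questions, and this package answers both from one
`SingleCellExperiment`:

1. **Which cell populations can talk to which, and how does disease
   rewire that map?** Given a curated list of directed (ligand, receptor)
   gene pairs, a gene is *expressed* in a cell group when it has a count
   above zero in at least 20% of the group's cells (threshold
   configurable, boundary inclusive). A directed edge `b → r` exists for
   pair (L, R) exactly when L is expressed in broadcaster group `b` and R
   in receiver group `r`; the weight of an ordered group pair is its
   number of distinct expressed pairs. Per-condition networks are then
   compared by edge-set algebra: gained, lost and persisted pairs, zeroed
   ligands (expressed in control, silenced in disease) and fold changes.

2. **Which genes are expressed unevenly over the embedding, per cell
   type, and how does that differ between conditions?** Each gene is
   scored by Moran's I over a symmetrized kNN graph on the 2-D embedding,

   I = (n/W) · Σᵢⱼ wᵢⱼ (xᵢ − x̄)(xⱼ − x̄) / Σᵢ (xᵢ − x̄)²,

   with a seeded one-sided permutation test, BH adjustment per cell type
   × condition, a stage-1 call (I > 0, adjusted p ≤ 0.05, detected in
   ≥ 1% of cells) and a conservative second stage (single-condition genes
   need I > 0.1; both-condition genes need |I_N − I_D| > 0.1).

A hurdle-model simulator (`presetConfig()` / `generateDataset()`) plants
communication edges and spatial-gradient genes with machine-readable
ground truth, so the full pipeline is testable end to end without any
external data.

## Worked example

Plant a communication gain — lymphocytes acquiring the ITGB1 receptor for
ten fibroblast matrix ligands, fibroblasts acquiring COL1A1/COL1A2 for
the lymphocyte CD36 receptor — then recover it:

```r
library(scCommNet)

sim  <- generateDataset(presetConfig("fib_to_lymph_gain", seed = 7))
prof <- expressedFraction(sim$sce)                 # detection fractions
calls <- callsByCondition(prof, threshold = 0.20)  # 20% rule, inclusive
netN <- buildNetwork(calls$Normal,  sim$pairs, "Normal")
netD <- buildNetwork(calls$Disease, sim$pairs, "Disease")
(d <- diffNetworks(netN, netD))
#> DiffCommReport: Normal vs Disease
#>   total expressed pairs: 1 (Normal) / 13 (Disease)
#>   gained: 12  lost: 0  persisted: 1
#>   zeroed ligands: 0

as.data.frame(byPairCounts(d))[2, ]
#>   broadcaster   receiver n_normal n_disease n_gained n_lost n_persisted fold_change
#> 2  Fibroblast Lymphocyte        1        13       12      0           1          13

head(as.data.frame(gainedEdges(d)), 4)
#>   broadcaster   receiver ligand receptor
#> 1  Fibroblast Lymphocyte COL1A1     CD36
#> 2  Fibroblast Lymphocyte COL1A1    ITGB1
#> 3  Fibroblast Lymphocyte COL1A2     CD36
#> 4  Fibroblast Lymphocyte COL1A2    ITGB1
```

The planted single Normal pair, the 13 Disease pairs and the 12 gains are
recovered exactly: at 200 cells per group with detection probabilities
0.5 against a 0.05 background, a miscalled group-level detection has
probability below 10⁻⁶.

The spatial arm works the same way from the same container:

```r
sim  <- generateDataset(presetConfig("spatial_sarcomere", seed = 11))
tabN <- spatialDETable(sim$sce, "Cardiomyocyte", "Normal",  seed = 101)
tabD <- spatialDETable(sim$sce, "Cardiomyocyte", "Disease", seed = 101)
cf   <- conservativeFilter(tabN, tabD)
as.character(cf$gene[cf$pass])
#> [1] "ACTA1" "ACTC1" "MYH7"  "MYL2"  "TNNI3"
```

All five planted sarcomere-gradient genes pass the two-stage filter; the
40 i.i.d. null genes do not. `runPipeline()` chains QC → profiles →
networks → differential report → spatial discovery and writes every
artifact (sorted, byte-stable) plus a provenance record to a directory.

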