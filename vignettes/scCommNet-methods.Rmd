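---
title: "Quantifying intercellular communication and spatially autocorrelated expression in snRNA-seq"
author: "scCommNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intercellular communication and spatially autocorrelated expression in snRNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scCommNet)
```

## The problem

Single-nuclei RNA-seq of a diseased tissue against matched controls gives
per-nucleus UMI counts for tens of thousands of genes across many cell
types. Two questions recur in such designs. First: which cell populations
can, in principle, talk to which others — and how does disease rewire that
map? Second: within a cell type, which genes are expressed unevenly across
the transcriptional landscape (a 2-D embedding such as UMAP), and how does
that spatial pattern differ between conditions? scCommNet implements both
analyses over a common `SingleCellExperiment` container, together with a
seeded simulator that plants known answers so every stage is testable
without any external download.

## Ligand–receptor communication networks

### Model

The communication model is deliberately minimal and auditable. Given a
curated list of directed (ligand, receptor) gene pairs, a gene is
*expressed* in a cell group (a cell type or cluster, within one condition)
when it has a count above zero in at least a threshold fraction of that
group's cells — 20% by default. A directed edge from broadcaster group $b$
to receiver group $r$ exists for pair $(L, R)$ exactly when $L$ is
expressed in $b$ and $R$ is expressed in $r$. Edges are enumerated
exhaustively over ordered group pairs (self-loops are autocrine
signalling), and the weight of an ordered group pair is its number of
distinct expressed pairs, $C[b, r]$.

Three modelling commitments are worth making explicit:

* **Detection, not abundance.** The 20% rule uses raw count > 0
  indicators. No normalization enters it, so the call is invariant to
  depth-scaling choices and exactly reproducible.
* **Potential, not physical, communication.** Co-expression of cognate
  genes across two groups licenses an edge; no spatial proximity, protein
  abundance or secretion modelling is attempted.
* **Directed multigraph semantics.** A ligand participating in several
  pairs contributes several edges; "number of uniquely expressed pairs"
  always means distinct (ligand, receptor) tuples on an ordered group
  pair.

Between two conditions sharing node set and pair list, the differential
report partitions each ordered pair's edges into *gained* (disease only),
*lost* (control only) and *persisted*, with the identities
gained + persisted = n_disease and lost + persisted = n_normal holding by
construction. *Zeroed ligands* are ligand genes whose broadcaster-side
call was true in control and false in disease — the most interpretable
single cause of lost communication. Fold changes are only reported when
both counts are positive; categorical gains from zero are visible in the
gained table instead, which avoids dividing by zero while keeping the
events discoverable.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `threshold` | 0.20 | detection fraction making a gene "expressed" in a group (inclusive) |
| `minCells` | 3 | QC: a gene must be detected in at least this many nuclei |
| `minGenes` / `maxGenes` | 200 / 2000 | QC: detected-gene bounds per nucleus, both inclusive; the lower bound removes ambient-only droplets, the upper likely doublets |

All bounds are inclusive: a fraction of exactly 0.20, a nucleus with
exactly 200 or exactly 2000 detected genes, and a gene in exactly 3 nuclei
all pass. Because 0.2 is not representable in binary floating point, the
call is computed on the integer detection counts
(`nExpr >= threshold * nCells`) with a $10^{-9} \cdot n$ guard, which
reproduces the exact rational rule for any realistic group size.

QC applies the gene filter first and then the nucleus filter, so
per-nucleus detected-gene counts are taken on the gene-filtered matrix;
the order is configurable and recorded in the QC report, since the
opposite order is equally defensible and the two differ on edge cases.

## Moran's I spatial autocorrelation

### Statistic and graph

For a cell group in one condition, each gene's expression vector $x$ over
cells is scored by Moran's I on a spatial weight graph $w$:

$$I = \frac{n}{W} \cdot \frac{\sum_{ij} w_{ij} (x_i - \bar x)(x_j - \bar x)}{\sum_i (x_i - \bar x)^2}$$

$I$ runs from about $-1$ (perfect dispersion) through the null expectation
$-1/(n-1)$ (no autocorrelation) to $+1$ (expression concentrated in a
focal region of the embedding). It is invariant to affine transforms of
$x$ and to scalar rescaling of $w$.

The weight graph is a union-symmetrized k-nearest-neighbour graph (binary
weights, $k = 15$ by default) built by Euclidean distance on the supplied
2-D embedding, with ties broken deterministically by (distance, cell
index). Trajectory-learning tools compute this statistic over a learned
principal graph instead; graph learning is a separate, heavyweight
inference problem, so this package decouples from it and treats the
embedding as an input, preserving the statistic and every downstream
filtering rule. Consequences of that choice: results depend on the
embedding actually supplied (the package never fits one), and $k$ trades
locality against noise — 15 neighbours on groups of a few hundred to a
few thousand cells matches common single-cell practice.

### Testing and the two-stage filter

Significance is assessed one-sidedly for positive autocorrelation by label
permutation: $p = (1 + \#\{I_{perm} \ge I_{obs}\})/(1 + n_{perm})$ with
999 permutations by default, seeded and exactly reproducible. An analytic
normal approximation under the randomization assumption is available
behind a flag; it agrees with the permutation test on well-behaved inputs
and is cross-checked against an independent implementation in the test
suite. Note the permutation count bounds the smallest achievable p-value
at $1/(1+n_{perm})$; with BH adjustment across hundreds of genes,
fewer than ~500 permutations can leave even a perfect gradient short of
an adjusted 0.05, so `nPerm` should not be lowered casually.

Per cell type and condition, genes detected in at least 1% of cells are
tested; p-values are BH-adjusted within that cell type × condition family
(the adjustment method and family are explicit choices; "adjusted p"
alone does not pin them down). The stage-1 call is $I > 0$, adjusted
$p \le 0.05$, detection $\ge 1\%$. The conservative second stage compares
conditions: a gene available in a single condition passes with $I > 0.1$;
a gene available in both passes with $|I_N - I_D| > 0.1$ (both strict).
"Available" is interpreted as *stage-1 significant* rather than merely
tested — the stricter and, we judge, intended reading — but
`presence = "tested"` switches to the weaker one, and the rule applied is
recorded in the result's metadata.

Expression values feeding the statistic are library-size-normalized log1p
counts by default (each cell scaled to the median library size). The
detection-threshold stage never sees these values; they matter only for
Moran's I, where magnitude carries real signal. Raw counts are available
via `transform = "counts"`. Genes with zero variance after transformation
are skipped: the statistic is undefined for them.

## What the simulator emulates

The generator is a hurdle model: gene $g$ is detected in a cell of group
$c$, condition $d$ with probability $p_{gcd}$, and detected cells draw a
count $1 + \mathrm{Poisson}(\lambda)$ with $\lambda = 1$ by default. This
models exactly the structure the pipeline consumes — detection indicators
for the communication arm, detection plus mild magnitude for the spatial
arm — and nothing more. Planted "expressed" probabilities must clear the
calling threshold by a margin (default 0.05; the presets use 0.5 against
a 0.05 background, so at 200 cells per group the probability of any
miscalled group-level detection is below $10^{-6}$ by binomial tail
bounds, and planted edge sets are recovered exactly in effectively every
seed). Embeddings are generated, not learned: each group is a Gaussian
blob stretched along an axis, and each cell carries a latent coordinate
$t \sim U(0,1)$ mapping it onto that axis, which sidesteps UMAP
nondeterminism entirely.

Spatially regulated genes vary along $t$ in both detection probability
(`baseline + amplitude * t`) and detected-count mean
(`countMean + countAmplitude * t`). Real spatially regulated genes shift
both how often and how strongly they are detected; with detection-only
gradients the between-region variance share caps Moran's I near 0.2 even
for a maximal gradient, so the presets plant both (detection 0.1→0.9,
count mean 1→5), which yields $I \approx 0.2\text{–}0.3$ — comfortably
clear of the 0.1 filter while remaining far from a caricature. Null
spatial genes are i.i.d. across cells, equivalent to permuted labels.

The presets encode the study-condition motifs the package is exercised
on, at 200 cells per group per condition (300 for the spatial preset):

* `fib_to_lymph_gain` — exactly 1 fibroblast→lymphocyte pair in control
  and 13 in disease: the lymphocytes gain ITGB1, opening communication
  with 10 cognate matrix ligands the fibroblasts express constitutively,
  and the fibroblasts gain COL1A1/COL1A2, opening the constitutive CD36
  receptor. The single persisted pair (FN1→SDC4) is a synthetic choice.
* `global_loss` — ten cell types and 13 synthetic pairs whose
  broadcaster/receiver sets are sized so edge contributions sum exactly to
  1138 (control) and 546 (disease); the decomposition into per-pair
  contributions is this package's own construction, only the totals being
  externally meaningful.
* `itgb1_gain` — each fibroblast-cluster→cardiomyocyte-cluster path
  carries 5 persisted pairs, plus 11 cognate-ligand pairs gained in
  disease through an ITGB1 gain in the receiving clusters: a 3.2-fold
  increase by construction.
* `spatial_sarcomere` — five sarcomere genes with a disease-only spatial
  gradient against 40 i.i.d. nulls in one cardiomyocyte group.

What passing on these data does **not** show: robustness to ambient RNA,
doublets, batch effects, or the sensitivity of the 20% rule near its
boundary on real, shallowly sequenced nuclei — none of which the
generator models. The planted-recovery results certify the *logic* of the
pipeline, not the biology of any particular dataset.

## Numerical and degenerate-input choices

* kNN ties broken by (distance, cell index); duplicate coordinates
  allowed; $n < 2$ or $k \ge n$ are errors.
* Constant expression vectors are an error in `moransI` and silently
  skipped (per gene) in the table builder.
* An all-cells-removed QC outcome is a warning plus an empty matrix, not
  an error, so pipelines fail downstream with context rather than
  opaquely.
* Duplicate gene symbols on load collapse by summation with a warning;
  duplicate barcodes are an error.
* All written reports are fully sorted on their key columns; reruns are
  byte-identical.

## Problem sizes

The test suite and the acceptance script run the presets at their default
sizes (400–4000 cells, 25–130 genes), 100 random Moran oracle instances
at $n \le 50$, 200 random network-algebra instances at ≤ 5 groups, 50
seeded replicates of the fibroblast→lymphocyte recovery, and 499–999
permutations per Moran test. These sizes were chosen so the planted
signals sit in the same regime as the analyses they emulate while the
whole suite completes in about a minute.

## Limitations

* Communication edges are potential, binary and threshold-dependent; no
  statistical significance is attached to an individual edge (a
  permutation scheme in the style of receptor–ligand tools that shuffle
  group labels is a natural extension point).
* The spatial arm scores autocorrelation over a supplied embedding; it
  neither learns trajectories nor assigns pseudotime, and a distorted
  embedding distorts $I$.
* Gene identity is by case-sensitive symbol; curated lists using aliases
  must be harmonized upstream.
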