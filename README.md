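# scRiskNet

Genome-wide association studies of complex diseases — the motivating case
is non-syndromic cleft lip with/without cleft palate (nsCL/P) — deliver
risk loci and gene-level association statistics, but not the *cell types*
in which that risk acts or the *effector genes* at each locus. scRiskNet
combines a gene-based GWAS table (per-gene z-scores and p-values) with a
single-cell RNA-seq count matrix of the relevant tissue to answer both
questions, and ships a synthetic-data generator with planted ground truth
so every stage is validated end to end.

It is intended for statistical geneticists and single-cell analysts who
want a self-contained, fully seeded R implementation of this
integration workflow.

## What it computes

**Per-cell disease-relevance scores.** For a weighted disease gene set
*G*, each cell's raw score is the weighted mean of log-normalized
expression, S<sub>c</sub> = Σ w<sub>g</sub> x̃<sub>cg</sub> / Σ
w<sub>g</sub>. Scores are normalized against B Monte Carlo control gene
sets matched on mean × variance expression bins (control genes inherit
the disease genes' weights), and per-cell empirical p-values pool all
B·n<sub>cells</sub> normalized control scores.

**Cell-type association and heterogeneity.** A group's association
statistic is its mean normalized score, tested one-sided against the
control sets; within-group heterogeneity uses Geary's C on a
k-nearest-neighbor graph of the PCA embedding,

C = (n−1) Σ a<sub>ij</sub>(z<sub>i</sub>−z<sub>j</sub>)² / (2 W Σ
(z<sub>i</sub>−z̄)²),

reported as 1−C with a Monte Carlo reference — a uniformly elevated group
stays null, a score-coherent subpopulation does not.

**Subclustering and DEGs.** The target cluster is split at score p ≤ 0.01
(associated) vs p ≥ 0.1 (non-associated); rank-sum DEGs between the
subclusters are intersected with a TAD/risk-locus annotation.

**Co-expression modules.** Counts are aggregated into metacells (k = 25
nearest neighbors, bounded pairwise overlap), a signed weighted network
a<sub>ij</sub> = ((1+r<sub>ij</sub>)/2)<sup>β</sup> is built at a
scale-free-selected soft power, and modules come from average-linkage
clustering of the topological overlap matrix with eigengene merging and
kME-based cleanup. Modules are ranked by their percentage of risk-locus
genes; the top 3 feed downstream testing.

**GWAS integration.** A competitive gene-set test (OLS of z on module
membership plus covariates; one-sided t) asks whether a module is
enriched for association; BH-corrected gene-based p-values over the
selected modules' genes, filtered to genes outside every locus, give new
candidates. Four prioritization approaches are assembled into one
candidate table: `DEG`, `scDRS-TAD-gene`, `scDRS-gene` and
`hdWGCNA+GWAS`.

## Worked example

Simulate the fast-test dataset (1,500 cells × 1,200 genes, five cell
types, an 87-gene disease set over-expressed 1.5× in 20% of the
epithelium), score it, and test cell types:

```r
library(scRiskNet)

cfg  <- runConfig(seed = 3)
sim  <- simulateCounts(cfg$sim)
sce  <- normalizeLog1p(sim$sce)
set  <- WeightedGeneSet(sim$truth$genes$gene[sim$truth$genes$disease],
                        name = "disease_set")
bins <- computeGeneBins(sce)
ctrl <- sampleControlSets(bins, set, B = 200, seed = 23)
scores <- scoreCells(sce, set, ctrl)
scores
#> CellScores for 1500 cells, 200 control sets
#>   normalized score range: [-3.2, 4.19]
#>   30 cells at FDR < 0.1

groupAssociation(scores, sim$truth$cells$cell_type)
#>        group n_cells mean_score       p reliable
#>        blood     150    -0.1499 0.78109     TRUE
#>  endothelium     225    -0.0585 0.64179     TRUE
#>   epithelium     450     0.2791 0.00995     TRUE
#>   mesenchyme     375    -0.0294 0.57711     TRUE
#>      neurons     300    -0.2241 0.95025     TRUE

# cell-state embedding for the heterogeneity graph: scored genes left out
hvgs <- setdiff(selectHVGs(sce, n = 800), geneIds(set))
sce <- embedPCA(sce, hvgs, nPcs = 20)
groupHeterogeneity(scores, SingleCellExperiment::reducedDim(sce, "PCA"),
                   sim$truth$cells$cell_type)
#>        group n_cells one_minus_C       p
#>   epithelium     450     0.37144 0.00498   # (other rows null)

qcDepthCorrelation(scores, sce)$r
#> [1] 0.128
```

The epithelium — the type carrying the planted effect — is the only
significantly associated group (p = 0.00995) and the only one with
significant within-type score heterogeneity (p = 0.00498), reflecting the
planted 20% affected subpopulation; the score is only weakly correlated
with sequencing depth. `runPipeline(runConfig(seed = 3), "outdir")` runs
the same analysis plus subclustering, DEG overlap, module detection,
competitive tests and candidate assembly, writing one TSV per stage and a
run manifest; re-running with the same seed reproduces every output byte
for byte.

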