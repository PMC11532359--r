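---
title: "Methods: disease-relevance scoring and co-expression prioritization"
author: "scRiskNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disease-relevance scoring and co-expression prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

scRiskNet integrates two data modalities to locate the cell types and genes
through which common genetic risk for a disease is likely to act:

1. a **gene-based GWAS summary** — one association z-score (and p-value)
   per gene, of the kind produced by gene-level aggregation tools from SNP
   summary statistics; and
2. a **single-cell RNA-seq count matrix** of the relevant tissue, here
   embryonic craniofacial tissue in the motivating application
   (non-syndromic cleft lip/palate, nsCL/P).

The pipeline proceeds through per-cell disease-relevance scoring against
matched Monte Carlo control gene sets, cell-type association and
within-type heterogeneity testing, score-driven subclustering with
differential expression, metacell-based weighted co-expression module
detection, competitive gene-set association, and the assembly of four
candidate-prioritization approaches. Everything is exercised end to end on
synthetic data with planted ground truth; the real-data inputs the design
mirrors (an embryonic head cell atlas and an nsCL/P GWAS gene table) are
not shipped.

# Per-cell disease-relevance scoring

## Model

For a disease gene set $G$ with per-gene weights $w_g$ (all 1 in the
unweighted setting; gene-based GWAS z-scores in the weighted setting), the
raw score of cell $c$ is the weighted mean of log-normalized expression

$$S_c = \frac{\sum_{g \in G} w_g \tilde{x}_{cg}}{\sum_{g \in G} w_g},
\qquad \tilde{x}_{cg} = \ln\!\big(1 + x_{cg}\,/\,N_c \times 10^4\big).$$

Raw scores confound disease relevance with cell state and depth, so each
cell is compared with $B$ **matched control gene sets**: detected genes are
binned on a 10 × 10 grid of quantiles of mean and (within mean bin)
variance of normalized expression, and each control set replaces every
disease gene by a random same-bin gene, inheriting its weight.
Normalization is two-step. First, every score vector — the observed one
and each control set's — is centered across cells: bin matching is only
moment-based, so a control set whose genes are systematically hotter than
their bin-mates would otherwise shift all cells at once, and such
set-level offsets belong to the null, not to any cell. Then the
normalized score is

$$z_c = \frac{\tilde S_c - \mathrm{mean}_b\, \tilde S^{(b)}_c}
             {\mathrm{sd}_b\, \tilde S^{(b)}_c},$$

with the (centered) control scores themselves normalized by
leave-self-out mean and sd so that observed and control normalized scores
are comparable. Omitting the centering step leaves a few-percent
cross-cell correlation within each control set that inflates the null
spread of the group-level association statistic — measurably halving its
power at the study scale. The
empirical p-value pools all $B \times n_\mathrm{cells}$ normalized control
scores:

$$p_c = \frac{1 + \#\{\text{pooled controls} \ge z_c\}}{1 + B\,n_\mathrm{cells}},$$

followed by Benjamini–Hochberg correction across cells. Pooling gives a
much finer p-value granularity than a per-cell comparison at the same
$B$. An optional inverse-standard-deviation gene weighting
(`varianceWeighting`) is implemented but off by default; only the
unweighted and z-score-weighted settings are the documented analysis
modes. Scoring operates on the log-normalized (not scaled/clipped) layer.

Defaults: $B = 1000$ for analyses, $B = 100$–$200$ in the fast test
configurations; 10 × 10 bins (matching on variance as well as mean guards
against inflation driven by highly variable genes). These are package
design choices; published work using this family of scores defers the
exact settings to supplementary material.

## Group-level tests

*Association.* The statistic for a cell group (cluster or annotated type)
is the mean normalized score; its one-sided Monte Carlo p-value compares
it to the mean of each control set's normalized scores over the same
cells, $p = (1 + \#\{b : \bar z^{(b)} \ge \bar z\}) / (1 + B)$. Groups
below 20 cells are reported but flagged unreliable.

*Heterogeneity.* To ask whether high-scoring cells form a subpopulation
rather than a uniform shift, Geary's $C$ is computed on a k-nearest-neighbor
graph (k = 15, union-symmetrized) built on the PCA embedding restricted to
the group:

$$C = \frac{(n-1)\sum_{ij} a_{ij}(z_i - z_j)^2}
           {2 \sum_{ij} a_{ij} \sum_i (z_i - \bar z)^2},$$

reported as $1 - C$ (positive = spatially structured scores). The Monte
Carlo reference recomputes the statistic on each control set's normalized
scores. A uniformly elevated group shifts every cell equally and $C$ is
shift-invariant, so the test correctly stays null there; the graph and k
are package choices (the source analyses name neither). One circularity
deserves care: if the embedding that defines the neighbor graph is built
on a gene universe containing the scored set, the score correlates with
graph position through the shared genes and even a uniform shift acquires
apparent spatial structure. The validation studies therefore build the
heterogeneity embedding on HVGs excluding the scored genes; at full
transcriptome scale (a ~100-gene set among ~2,000 HVGs of 20k genes) the
effect is small, but the exclusion is the cleaner design.

*Subcluster split.* Within a target cluster, cells at $p \le 0.01$ form
the associated subcluster and cells at $p \ge 0.1$ the non-associated one
(thresholds and strict/inclusive comparison configurable); rank-sum DEGs
between the two subclusters, intersected with the risk-locus annotation,
yield the DEG prioritization approach.

# Preprocessing

Depth normalization is $\ln(1 + \mathrm{count}/\mathrm{total} \times 10^4)$.
Highly variable genes use the variance-stabilizing flavor: a loess fit
(span 0.3, degree 2; a global linear trend below 30 expressed genes) of
log10 variance on log10 mean of raw counts predicts each gene's expected
sd, counts are standardized with it and clipped at $\sqrt{n}$, and genes
are ranked by the variance of the clipped standardized counts. PCA runs
on per-gene centered/unit-scaled HVGs clipped at ±10, with a deterministic
sign convention (largest-magnitude loading positive). Clustering builds
the shared-nearest-neighbor graph (k = 20, Jaccard edge weights over
self-inclusive neighbor sets, pruned below 1/15) and applies seeded
Louvain modularity optimization — the original Louvain algorithm, not
Leiden, matching the toolchain the design follows. Note that modularity
resolution interacts with dataset size: on a few hundred cells the default
resolution 1.0 subdivides homogeneous populations (into pure
sub-clusters); coarse structure corresponds to resolution ≈ 0.5 at that
scale.

Rank-sum differential expression uses exact enumeration over
$\binom{n_A+n_B}{n_A}$ assignments when both groups have ≤ 8 cells
(exact under ties) and a tie-corrected normal approximation with
continuity correction otherwise; log2 fold changes are computed on
depth-normalized means with a $10^{-9}$ pseudocount. The up-DEG threshold
defaults to adjusted p < 0.05 and log2FC > 0 (the fold-change-above-1
reading; the stricter 0.1 cutoff that appears in some presentations is a
parameter).

# Co-expression modules

Correlations between genes are weak and noisy at single-cell resolution,
so expression is first aggregated into **metacells**: within one cell
group, each candidate is a cell plus its k − 1 = 24 nearest embedding
neighbors; candidates are accepted in seeded random order while sharing at
most 10 cells with every accepted metacell, up to 250 metacells; member
counts are summed and re-normalized (log1p, scale 10⁴).

The network is **signed**: $a_{ij} = ((1 + r_{ij})/2)^\beta$, so modules
are groups of positively correlated genes. The soft power $\beta$ is the
smallest candidate in 1…20 whose connectivity distribution reaches a
sign-corrected scale-free fit $R^2 \ge 0.8$ over 10 connectivity bins
(fallback 9). Topological overlap is

$$\mathrm{TOM}_{ij} = \frac{\sum_u a_{iu}a_{uj} + a_{ij}}
                           {\min(k_i, k_j) + 1 - a_{ij}},$$

clustered by average linkage on $1 - \mathrm{TOM}$. The static cut is
applied at 0.99 **of the maximum merge height**: an absolute cut height on
$1-\mathrm{TOM}$ proved brittle because the overall height scale shifts
with $\beta$; the relative convention (as in dynamic tree cutting) is
stable across powers. Branches below 30 genes are unassigned, modules
whose eigengenes correlate above 0.8 are merged iteratively, and two
quality steps mirror standard network practice:

* **kME pruning** — genes whose correlation with their own module
  eigengene falls below 0.3 are released (loose average-linkage branches
  otherwise absorb uncorrelated genes);
* **coherence floor** — a module whose mean own-gene kME falls below 0.5
  is dissolved. A module is, by definition here, a set of substantially
  inter-correlated genes; diffuse clusters held together only by weak
  shared variation (at small transcriptome sizes, depth normalization
  induces a few-percent mutual correlation among all background genes
  because planted module factors are a large fraction of the library)
  are not modules.

The module eigengene is the first principal component of the module's
standardized gene × metacell submatrix, unit-norm and sign-aligned with
the module mean profile; kME is each gene's Pearson correlation with an
eigengene, and the top 10 own-module kME genes are reported as hub genes.
Modules are ranked by their percentage of risk-locus ("TAD") genes and the
top 3 are selected for downstream testing, ties broken by absolute
TAD-gene count then label.

# GWAS integration and candidate approaches

The **competitive gene-set test** regresses the gene-based z-score on a
module-membership indicator (plus optional covariates such as a log
gene-length proxy) over a background universe, with a one-sided t-test for
a positive membership coefficient; with no covariates it reduces exactly
to a pooled-variance two-sample t-test. Genes are treated as independent:
the reference implementation of such tests models inter-gene LD from
genotype data, which is out of scope here, and the synthetic z-scores are
generated independently, so the simplification is exact in-test — users
applying this to real data should be aware the p-values ignore LD.

Four candidate lists are assembled (a gene may appear under several):

| Approach | Rule |
|---|---|
| DEG | up-DEGs of the associated subcluster ∩ TAD genes, minus the disease set |
| scDRS-TAD-gene | score–expression correlation r > 0.01, inside loci, not in the disease set |
| scDRS-gene | r > 0.01, outside every locus |
| hdWGCNA+GWAS | selected-module genes significant after BH (α = 0.05) on gene-based p, outside every locus |

The BH universe for the module-gene FDR defaults to the union of the
selected modules' genes with GWAS entries (a per-module option exists; the
source wording is ambiguous between the two). Over-representation analysis
of module gene lists against a term→gene map uses the upper-tail
hypergeometric test with BH correction, with the expression matrix's gene
universe as background (the universe every other stage uses, not the
genome); ontology-aware redundancy removal is out of scope, and an
optional Jaccard-overlap collapse (> 0.8 shared genes keeps the smallest
p) is provided as a clearly labeled approximation.

# The synthetic-data generator

The generator plants known structure so that every stage can be validated
against ground truth:

* **Counts** are negative binomial with mean *baseline × type-marker fold
  × module factor × disease fold × library size* and gene-level dispersion
  (size 2). Baselines are log-normal (meanlog = log 0.3, sdlog = 1.2, a
  typical droplet-data expression profile at a few hundred counts per
  cell); library sizes log-normal (sdlog 0.3). Five cell types carry 100
  marker genes each at 3×.
* **The disease set** (87 genes at full scale, mirroring the motivating
  study's set size and its 404-locus-gene / 51-undetected arithmetic) is
  drawn from genes above the median baseline — candidate genes are,
  definitionally, detected in the relevant tissue — and multiplied by the
  disease fold (default 1.5×) in the affected fraction (default 20%) of
  one cell type.
* **The affected subpopulation is a cell state**, not just a set of
  gene-set over-expressors: it carries its own marker program (60
  specifically expressed genes, drawn from the below-median stratum and
  strongly induced — 5×, the keratin-class pattern of state markers — in
  affected cells) and the co-regulated bystander locus genes share that
  state program. This is what makes the subpopulation coherent
  in embedding space — the premise of the heterogeneity test — and
  mirrors how associated subclusters present in real data (many DEGs, not
  only the scored set). Under the null (fold 1.0) no state exists and the
  affected flag is distributionally inert.
* **Modules** share per-cell Gaussian latent factors entering the mean
  log-additively (`exp(loading·z − loading²/2)`, mean-preserving; default
  loading 0.8), active only in configured cell types. Locus genes are
  planted preferentially into the first modules so TAD-fraction ranking
  has a decisive planted signal, and outside-locus GWAS hits are placed in
  the two most locus-enriched modules.
* **GWAS z-scores** are N(0,1) for null genes, shifted (+4) for disease
  genes and planted outside-locus hits; p is the one-sided upper tail.
  Risk loci are random genomic intervals; locus-flagged genes (including
  identifiers deliberately absent from the matrix) map to them.

What the generator does **not** emulate: batch effects, doublets, ambient
RNA, cell-cycle structure, LD between gene-level statistics, and the
compositional scale of a real 20k-gene transcriptome. Passing tests
demonstrate internal correctness and statistical calibration/power under
these conditions, not performance on real tissue atlases.

# Validation studies and problem sizes

The package ships its validation as functions (`studyNullCalibration`,
`studyScoringPower`, `studyDegRecovery`, `studyModuleRecovery`,
`studyCompetitiveTest`, `studyPipelineEndToEnd`), which the test suite and
`scripts/acceptance.R` run at these sizes:

* Null calibration: 20 simulations of 2,000 cells × 1,000 genes, B = 200;
  pooled p-value uniformity (KS) and group type-I error over 400 random
  groups.
* Power: 20 seeds × two scenarios (20% of a 300-cell type affected;
  a whole type uniformly elevated), 2,000 cells × 2,000 genes, the 87-gene
  set, B = 200, all (≤ 2,000) HVGs for the embedding. The two scenarios
  are simulated separately: a fully elevated type inflates the disease
  genes' global means and would otherwise distort every other cell's
  matched controls. The transcriptome size matters: at 1,000 genes the
  10 × 10 matching grid holds only ~10 genes per bin for an 87-gene set,
  and the residual type-specificity of the coarsely matched control sets
  dominates the null spread of the group statistic.
* DEG recovery: 5 seeds, 500 vs 500 cells, 100 planted 1.5× genes. With
  the committed baseline-expression profile the measured sensitivity sits
  near the 0.8 design bound (misses concentrate at the detection margin,
  where a 1.5× fold is intrinsically hard for a rank test); specificity
  is comfortably above 0.95.
* Module recovery: 5 seeds, five 50-gene modules + 250 noise genes, 250
  metacells from 2,000 cells.
* Competitive test: 1,000 null replicates; 20 power replicates at a +0.5
  shift on 50 of 2,000 genes.
* End to end: the fast-test configuration (1,500 cells × 1,200 genes,
  B = 100) run twice for byte-identical outputs and across 5 seeds for
  planted-candidate recovery.

# Determinism

Every stochastic step takes an explicit seed; the pipeline derives stage
seeds from one global seed (simulate: `seed`; clustering: `seed + 10`;
control sampling: `seed + 20`; metacells: `seed + 30`) so partial re-runs
reproduce full-run outputs, and re-running a configuration yields
byte-identical TSVs. Degenerate inputs are handled explicitly: all-zero
cells stay zero (warning), zero-variance genes are flagged rather than
propagating NaN, zero control-score spread yields normalized score 0 and
p = 1, constant score vectors never produce a significant heterogeneity
call, and quantile bins collapse when there are fewer distinct values
than bins.

# Known limitations

* The competitive test ignores LD between gene-level statistics.
* The per-cell empirical p-values are pooled across cells, which assumes
  exchangeability of control scores across cells; strong global structure
  in score variance would argue for per-cell reference distributions at
  much larger B.
* Module detection targets planted-partition-style structure; overlapping
  modules and nested co-expression hierarchies are not modeled.
* At desk scale (hundreds of genes), compositional effects of depth
  normalization are much larger than in a full transcriptome; the module
  coherence floor exists partly for that reason.
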