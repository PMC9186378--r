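---
title: "immunophen: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{immunophen: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind each stage of the pipeline, the
parameters that matter, the synthetic-data generator that stands in for
real cohorts, and the design decisions that were genuinely open. Nothing
here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Single-cell QC and differentiation signatures

`qcFilter()` applies the standard droplet-data rules in a fixed order:
genes detected (count > 0) in fewer than 3 cells are removed first, then
cells with fewer than 200 or more than 4,500 detected genes or more than
10% mitochondrial transcripts (genes with the `MT-` name prefix). The
order matters — a gene removed in step one can change a cell's detected
count — and all comparisons are strict, because that is how the thresholds
are conventionally stated; cells sitting exactly on a boundary survive.
Filtering is idempotent.

`wilcoxonDe()` tests each gene between two cell groups with the two-sided
Wilcoxon rank-sum test in its normal approximation with continuity and tie
correction (the default test behind Seurat's `FindMarkers`), on
log2(x + 1) data; the pseudocount is fixed at 1 throughout the package.
No min-pct or log-fold-change pre-filter is applied before thresholding:
pre-filters change the multiple-testing universe, and the thresholds below
are the stated selection rule. `splitSignatures()` then takes
log2FC > 1.3 & FDR < 0.05 as the *early* differentiation signature and
log2FC < −1.3 as the *late* one (Benjamini–Hochberg FDR);
`cohortDegs()` supports the cohort-specific variants (|log2FC| > 1 for
RNA-seq, > 0.2 for arrays) whose intersections across cohorts define
shared DEG sets.

## Deconvolution

`deconvolve()` estimates immune-cell fractions per bulk sample by
non-negative least squares on the genes shared with the reference basis,
followed by renormalization to the simplex. Instead of ν-SVR (the core of
CIBERSORT) we use NNLS: it is deterministic, dependency-light, and has the
same contract (non-negative weights on a signature basis). Both sides are
standardized per gene by the basis row standard deviation — but *not*
centred. Centring is the one place we deviate from a full z-score: with
centring, a noiseless mixture `y = B f` is no longer an exact solution of
the transformed system unless Σf is known, and a positive rescaling of a
sample changes its fitted direction. Pure variance-standardization keeps
the system exactly linear, so noiseless mixtures are recovered to machine
precision and fractions are exactly invariant to per-sample rescaling,
while still down-weighting high-variance genes. Relative (simplex) mode is
the only mode implemented; no per-sample permutation p-values.

## Consensus clustering and the two-step subtype classifier

`consensusCluster()` is Monti-style: in each of `reps` repetitions (1000
by default; recovery tests use 200) a fraction 0.8 of samples is drawn
without replacement and clustered by `hclust` with Euclidean distance and
`"ward.D"` linkage — Ward's criterion applied to unsquared distances. The
consensus between two samples is their co-clustering rate among
co-sampling repetitions; final labels cut the tree of 1 − consensus. The
PAC score (share of consensus entries strictly inside (0.1, 0.9)) is
exposed as a diagnostic. k is *not* selected automatically: the two-step
classifier fixes k = 2 (step one) and k = 3 (step two) as the reproduced
structure, and PAC lets a user judge whether that structure is present in
their data.

Step one clusters the immune-cell fraction columns and must decide which
cluster is the infiltrated subtype A. Because full fraction rows always
sum to 1, "total immune fraction" cannot discriminate; infiltration is
therefore measured as the summed fraction of designated *effector* types
(default: M1 macrophages, CD8 T cells, activated memory CD4 T cells — the
three cell types most tightly associated with the hot phenotype). Step two
z-scores the early-signature genes within the A samples and clusters them
into A1/A2/A3, named in decreasing order of mean effector fraction.
Clusters with fewer than 2 samples are merged into the nearest surviving
cluster with a warning. Identical-sample (zero-variance) input is an
error, not a silent degenerate split.

`logrank()` delegates the two-group statistic to `survival::survdiff`
(observed minus expected events over the pooled risk sets, χ² with 1 df)
and emits Kaplan–Meier step tables via `survival::survfit`; groups with
identical survival experience short-circuit to χ² = 0 exactly.

## ssGSEA, the hot/cold grade, fold changes, TMB

`ssgsea()` implements the rank-weighted running-sum statistic: per sample,
genes get average-tie ranks, are walked in decreasing rank order, and the
enrichment score is the summed difference between the in-set cumulative
weight (rank^α, α = 0.25) and the out-set cumulative count. With
`normalize = TRUE` (default) scores are rescaled by the global max − min.
Whether scores are normalized before the median split is exposed as this
flag; the split itself is rank-based and unaffected.

The hot/cold grade is the ssGSEA score of the single four-gene set
{CXCL9, CXCL10, CXCL11, CCL5}; `hotColdSplit()` labels scores strictly
above the cohort median *hot*, everything else *cold*. Ties at the exact
median go cold — a deterministic choice that is conservative toward "hot"
calls. `signatureFoldChange()` is the plain difference of hot and cold
group means, per signature and for the summed immune-related score.
`tmb()` is mutations per megabase.

## Network centralities and the hub screen

`centralities()` computes, from scratch: degree; shortest-path betweenness
by Brandes' algorithm (unnormalized, endpoint-excluding, each unordered
pair counted once, unreachable pairs skipped); eigenvector centrality by
power iteration on A + I — the shift breaks the ± eigenvalue symmetry of
bipartite graphs so the iteration converges, and leaves eigenvectors
unchanged (tolerance 1e-10, non-negative, unit Euclidean norm); and
eccentricity centrality 1/max dist to reachable nodes, with isolated
nodes at 0. `hubScreen()` takes the top 40 nodes by degree and intersects
the top 20 of them by eigenvector with the top 20 by betweenness;
eigenvector is the default secondary metric (eccentricity can be
substituted via `secondaryMetrics`). Boundary ties are broken by the
higher secondary value then lexicographic node id, and flagged in the
audit output, since "first 40/first 20" is undefined under ties.
`degreeFilter()` provides the strict degree > 30 variant; the two screens
coincide on some networks but not in general, so both are exposed.

## Windowed copy number

`inferCnvProfile()` averages reference-centred log2(x + 1) expression over
a sliding window of 2·50 + 1 = 101 genes ordered by genomic location. The
raw windowed mean of absolute expression cannot be a *relative* copy
number, so E is centred by the per-gene reference-cell mean (the standard
inferCNV convention) and clipped to ±3 (configurable) for outlier
robustness. Windows truncate at chromosome ends, dividing by the actual
member count, and never span chromosomes. Gain/loss calls use a symmetric
±0.2 threshold: the one-sided reading of the rule ("< 0.2 is loss") would
label near-zero values losses, so it is read as −0.2.

## Diffusion pseudotime

`diffusionMap()` builds a Gaussian kernel with local bandwidths (distance
to the ⌈k/2⌉-th neighbour, k = 15 by default) on the symmetrized kNN
graph, row-normalizes to a transition operator, and embeds cells with the
top non-trivial right eigenvectors. Components are weighted by
λ/(1 − λ) rather than λ: kernel eigenvalues on realistic data sit near 1,
where plain-λ weighting leaves higher harmonics undamped and the distance
from the root stops tracking the trajectory; λ/(1 − λ) is the aggregate
diffusion distance over all diffusion times and damps harmonics
geometrically. A disconnected kNN graph is an error (with the advice to
raise k). `pseudotime()` is the Euclidean distance from a user-chosen
root in that embedding, min-max rescaled to [0, 1]; the root is the
biological anchor (the monocyte end) and is deliberately user-supplied.
`expressionAlongPseudotime()` reports per-gene Spearman correlations with
BH-adjusted p-values; constant genes are flagged with ρ = 0.

## The response network

`buildFeatures()` assembles the seven predictors — single-gene ssGSEA
grades of CXCL9, CXCL10, CXCL11, CCL5 plus the M1, CD8 T and activated
memory CD4 T fractions — and z-scores each (constants are an error); the
scaling constants travel with the trained model. `trainMlp()` trains the
7–20–5–1 network with a logistic sigmoid at *every* layer (one activation
for the whole network), mean binary cross-entropy, and full-batch gradient
descent. The published description leaves the optimizer, learning rate,
epochs and dropout rate unstated; we declare lr = 0.01, 2000 epochs and
dropout 0.2 (inverted dropout, hidden layers, training only) as defaults
rather than inferring them, and chose plain gradient descent over
resilient backpropagation because it is reproducible and directly
checkable against finite differences. Weights start uniform(−0.5, 0.5)
under the seed; training is bit-deterministic given the seed.
`evaluateRoc()` computes the threshold-sweep ROC, trapezoid AUC (equal to
the tie-corrected Mann–Whitney statistic) and the 0.5-threshold confusion
matrix. Models serialize to JSON at 17-digit precision, so reloaded
models predict bit-identically.

## The synthetic-data generator

The generator defines the study conditions for every recovery test; its
defaults are fixed once and shared by tests and the acceptance script.

* **Single cells** (`genScCohort`): latent time t ~ U(0, 1); marker
  effects follow a logistic switch centred at t = 0.5. The default switch
  width 0.1 makes the early and late thirds of the axis differ by the full
  planted log2 fold change (the regime of the signature-threshold tests);
  width ≈ 0.5 yields a gradual gradient along the whole axis (the regime
  of the trajectory tests). Counts are negative-binomial (dispersion
  size = 10) around the log-mean structure with per-cell depth factors;
  ~3% shallow cells, ~8% high-mito cells and a handful of near-absent
  genes are planted so each QC rule fires (only under the `"nb"` count
  model — the `"mean"` model is an idealized noiseless gradient).
  CNV segments multiply expected expression in half the cells.
* **Bulk cohorts** (`genBulkCohort`): expression = basis × Dirichlet
  fractions, chemokine rows of hot samples shifted by 2^2 by default,
  additive Gaussian noise. With `plantSubtypes = TRUE` the hot samples are
  split A1/A2/A3 with graded effector Dirichlet weights (12/7/4.5 vs 1 for
  B) and subtype-specific blocks of early-signature genes; the gradations
  were chosen so that the planted structure is unambiguous to a
  practitioner's eye (adjacent subtypes separated by roughly two
  within-subtype standard deviations of effector fraction). Survival is
  exponential with a hot-vs-cold hazard ratio (default 0.4) and ~25%
  administrative censoring; response labels follow a logistic model on the
  seven generative features.
* **Graphs** (`genPpi`): Erdős–Rényi background with a planted dense
  module. Module-to-background edges are drawn at 3× the background rate
  (`moduleBackgroundMultiplier`): hub genes are globally central, and a
  clique wired to the background at the base rate has top degree and
  eigenvector but *bottom*-of-list betweenness (its internal paths are
  redundant), which no centrality screen should be expected to recover.

What the generator does **not** emulate: batch effects, doublets,
read-level sequencing noise, gene–gene correlation beyond the planted
structure, non-exponential survival, and cohort shift between training
and test sets. Passing recovery tests therefore demonstrates correctness
of the algorithms under their own assumptions, not robustness on real
cohorts; in particular the synthetic train/test AUCs say nothing about
transfer across real ICB cohorts.

## Numerical choices, degenerate inputs, problem sizes

Strict inequalities at every published threshold; log2(x + 1) wherever a
log scale is needed; BH for all multiplicity correction. Degenerate inputs
raise errors naming the offender (all-filtered matrices, all-zero samples,
zero-variance clustering input, single-class labels, disconnected kNN
graphs, all-identical scores at the median split). Consensus runs, MLP
training and all generators take explicit seeds and restore the caller's
RNG state.

Test and acceptance problem sizes — 500 cells × 1,000 genes for QC/DE,
n = 100–200 bulk samples, 200-node graphs, 300-cell trajectories,
reps = 200 consensus, 1,000 null simulations for log-rank calibration —
were chosen as the smallest sizes at which the planted effects are
comfortably identifiable, so the whole suite runs on one CPU in well under
a minute per stage.
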