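---
title: "From CNV profiles to drug ranking: the emtmet pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From CNV profiles to drug ranking: the emtmet pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emtmet)
```

`emtmet` chains six analysis stages that together take single-cell tumor
data to a ranked list of candidate anti-metastatic drugs. This vignette
explains the model behind each stage, the parameters that matter, what
the synthetic-data generators do and do not emulate, and the numerical
choices made where the design was genuinely open.

## 1. Malignancy calling from CNV scores

Inferred copy-number pipelines emit a cells × features score matrix
centred at the neutral value 1. The package summarizes each cell by its
*CNV Deviation*, the mean squared departure from neutrality
$\mathrm{dev}_j = \frac{1}{n}\sum_i (s_{ij}-1)^2$. The squared form
(no square root) is the default — the 0.002 calling threshold lives on
that scale — and `compute_cnv_deviation(sqrt = TRUE)` offers the RMS
variant for sensitivity analysis.

Deviation alone confuses diffuse noise with genuine aberration, so a
second axis asks whether a cell's *profile shape* matches the
consensus of the most aberrant cells: the reference curve is the
feature-wise mean over the top 5% of cells by deviation (`top_frac`,
ties broken by stable cell order), and each cell receives a Pearson
correlation to it. Correlating against a per-feature curve is the only
well-defined reading of "correlation to the top cells": a correlation
against a scalar summary does not exist.

The call is a strict two-threshold quadrant rule: deviation > 0.002 and
r > 0.1 is Malignant, both strictly below is NotMalignant, everything
else — including exact threshold equality and cells whose correlation is
undefined because their profile has zero variance — is Other. When a
cell-type annotation is supplied, only epithelial cells may receive the
Malignant label. Note that with feature noise σ the expected deviation of
a neutral cell is σ², so at σ = 0.05 even non-malignant cells sit above
0.002 and the correlation axis does the separating; this mirrors how the
two axes divide labor on real data.

## 2. Gene-set scoring and EMT stratification

Two scorers are provided. `control_binned_score()` is the classic
module score: genes are binned into 25 equal-frequency bins by mean log
expression, each set gene draws 100 controls from its bin (without
replacement when possible), and the score is mean(set) − mean(controls).
The control pool deliberately may include set genes themselves (the
standard construction); with small gene universes this self-contamination
shrinks the score toward zero, which is why defaults assume a few hundred
genes per bin. `ranking_auc_score()` is the ranking alternative: the
area under the set-recovery curve within the top 5% of each cell's
expression ranking, normalized so perfect packing scores 1.

Scores are min–max scaled to [0, 1] (a constant vector maps to 0), and
malignant cells are stratified at the 40% and 60% score quantiles into
lEMT/mEMT/hEMT. Quantiles use linear interpolation (R type 7) so the
boundaries are reproducible; cells exactly at a boundary are mEMT (the
source procedure is silent; the strict reading of "below"/"above" puts
boundary ties in the middle band). Stratification is per cancer type by
default — a global split would let one cancer's EMT range dominate the
others — and groups under 5 cells are skipped with a warning. Because
the rule depends only on ranks, any strictly increasing transform of the
scores leaves the labels unchanged.

## 3. Meta-program discovery

Each sample's highly-variable-gene submatrix is factorized by
multiplicative-update NMF at ranks 4–12 with 10 random restarts per
rank. The composite metric for rank choice is unreported in the source
procedure; the package uses the cophenetic correlation of the
repeat-consensus cell clustering (cells assigned to their argmax
factor), ties to the smaller rank. A caveat worth knowing: on
near-noiseless block data, coarse ranks can be trivially stable and win
the tie — at realistic noise the criterion behaves as intended. Each
factor of the winning fit contributes its top 50 genes (`top_n`; module
size is likewise unreported) as one module.

Cross-sample integration then proceeds: genes recurring in < 2 modules
are dropped (`min_recurrence`), modules with Jaccard similarity > 0.05
to at least 5 other modules are kept as robust, and a gene co-occurrence
network is built with edge weight = number of modules containing both
endpoints. Two pruning knobs implement the "high-connectivity genes"
filter: edges supported by a single module are removed
(`min_weight = 2`) — a pair seen once is not recurrence evidence, and
without this filter the graph is near-complete because the forced
minimum rank of 4 produces one mixed "leftover" factor per sample — and
nodes with weighted degree < 2 are dropped. Infomap (the two-level map
equation, via igraph) partitions the result; non-singleton communities
are the meta-programs, and `map_equation()` lets you verify that the
returned partition codes the random walk more compactly than singletons.
Programs with Jaccard > 0.25 merge by single linkage across
runs/cancers.

Modules are screened against program activities by Pearson correlation
with both thresholds strict (|r| > 0.2 *and* p < 0.05): at realistic
cell counts the |r| cutoff dominates, so the screen's null rate is far
below the nominal α.

## 4. Contrastive differential expression and trend genes

The hEMT-vs-lEMT contrast first removes the shared background: both
groups are embedded by joint PCA (30 components), mutual k-nearest
neighbors (k = 5) across groups form anchor pairs, and both members of
any pair with PC-coordinate correlation > 0.9 (`sim_thr`; unreported
upstream) are dropped. The full CCA-anchor machinery of integration
suites is deliberately simplified to joint-PCA MNN — the contract that
matters (bidirectional correspondence, removal of near-duplicates) is
preserved. Wilcoxon rank-sum on the log layer with the pseudocount fold
change `log2((mean(expm1 a)+1)/(mean(expm1 b)+1))` and thresholds
p < 0.05, |avg_log2FC| > 0.25 yields the directed DE batch. Raw p
thresholds are used as printed upstream; BH-adjusted values are reported
alongside for the record.

Trend genes come from smoothing each gene on pseudotime (natural cubic
spline, df = 3, 100 grid points) and applying the Mann–Kendall test to
the fitted grid: τ = S/(n(n−1)/2), exact enumeration of the permutation
distribution for tie-free n ≤ 10, otherwise the tie-corrected normal
approximation with continuity correction. The |τ| threshold is 0.7 by
default with 0.4 available as the permissive preset (the source reports
both in different places; the Methods value is the default). Because the
smoothed grid is strongly autocorrelated, the p-value alone would be
anti-conservative for noise genes — the |τ| cutoff is what controls the
screen.

Signature assembly takes genes in ≥ 2 of the 3 batches (strict triple
intersection is the obvious alternative; 2-of-3 is the declared
default), direction from the DE batch when present (the direct
phenotypic contrast), else the trend sign. Cross-cancer candidates need
a consistent direction in ≥ 3 cancers; genes qualifying in both
directions are excluded.

## 5. Bulk risk models and the MPS

Cohorts are split 80/20 stratified by label. Feature selection
intersects ≥ 2 of three selectors (L1-logistic path at the CV-optimal
penalty, random-forest impurity importance top 35, univariate rank-AUC
top 35). The ten learner families of the source workflow are reduced to
a pluggable registry with three built-ins (logistic GLM, ridge glmnet,
random forest): the learners are off-the-shelf; the contribution this
package implements fully is the selection and scoring layer around them.
Cross-validation is stratified 5-fold (fold count unreported upstream).

Candidates are ranked by Model Score = (CV+Test)/2 − 0.8·|CV−Test|,
which never exceeds max(CV, Test) and equals it only when the two AUCs
agree — a model that looks brilliant in CV and mediocre on the test set
ranks below an honest mid-range model. The MPS/GMPS is the logistic
linear predictor including the intercept (probabilities are a monotone
transform, so every rank-based quantity is identical); the event class
is explicit (`positive = "M"`) because alphabetical factor ordering
would silently flip the sign. Separation triggers a lightly penalized
ridge refit, recorded on the model object. Risk groups split at the
median with ties going Low.

## 6. Drug prioritization

Drug–target edges and PPI edges form one simple undirected graph;
isolated nodes are removed and the adjacency is column-normalized into
the transition operator. The restart walk
$P_{t+1} = \alpha A P_t + (1-\alpha)P_0$ runs from the normalized binary
seed vector (the signature genes) at α = 0.7 to an L1 tolerance of
1e-10; "PageRank initialization" in the source description is read as
exactly this personalized-PageRank iteration — the stated binary P₀
leaves no separate role for a PageRank pass. Probability mass is
conserved at every step and the iterate converges to
$(1-\alpha)(I-\alpha A)^{-1}P_0$, which the tests verify against a
direct linear solve.

Perturbation profiles are ranked by per-gene Welch t (drug vs control;
a single replicate falls back to fold change) — empirical-Bayes
moderation is available in principle but unnecessary here, since only
the ranking feeds enrichment. Pre-ranked GSEA uses the weighted
Kolmogorov–Smirnov running sum (hit weights |stat|, uniform miss
penalty) with a gene-label permutation null: NES = ES / mean(|null ES|
of matching sign), and the two-sided p is
(1 + #{|null ES| ≥ |ES|})/(n_perm+1) — defined on |ES| so it is exactly
discrete-uniform under the null. Gene-label permutation is used because
perturbation arms are far too small for phenotype permutation;
n_perm = 1000 by default.

The mapping from NES to a drug score is unreported upstream; the
package min–max normalizes −NES over the candidate set (strong
down-regulation of the up-signature scores 1) and likewise min–max
normalizes the RWR mass, so the weighted combination
Drug Score = 0.6·Score_RWR + 0.4·Score_GSEA operates on commensurate
[0, 1] scales. Candidates are the intersection of drugs covered by both
routes. Finally, `perturbation_mps_test()` applies a fitted MPS to both
arms and reports the median shift with a Wilcoxon rank-sum p.

## The synthetic world

All generators hang off one `sim_config()` whose defaults are the
reference conditions used throughout the tests: 1000 genes × 2000 cells
in 6 samples / 3 cancers; two CNV blocks of 100 features shifted ±0.3
against score noise σ = 0.05; a uniform latent EMT axis loading with
unit effect on a 50-gene set; three disjoint 50-gene programs, each cell
dominated by one; a 400-sample bulk cohort with
label ~ Bernoulli(sigmoid(β·Σ dir·x)), β = 2 per gene — the literal
additive model, whose symmetric centred predictor keeps classes near
1:1 at any effect size; and a 50-drug world with 5 planted inhibitors
(target overlap 0.8 with the signature, log-scale signature reversal of
magnitude 1, 20 replicates per arm, Erdős–Rényi PPI at density 0.05
over 200 genes, which is connected with high probability). Expression is
Gaussian on the log1p scale with σ = 0.4 — a deliberate extra knob
(`expr_noise_sd`) separate from the CNV noise, since one σ cannot be
both a realistic expression scatter and the CNV noise level; counts are
`round(expm1(log))`. One master seed feeds deterministic per-generator
substreams, so any module can be tested in isolation and identical
configs are bit-identical.

What the generators do *not* emulate: negative-binomial count noise,
dropout, doublets, batch effects, ambient RNA, spatial structure, or
correlated PPI topology. Tests passing on this world demonstrate that
the algorithms recover the structure they assume when it is present —
they say nothing about robustness to the failure modes real data adds.

Problem sizes in the test-suite and acceptance runs are scaled-down
versions of the same conditions (e.g. the NMF chain runs on
300 genes × 600 cells with 150 HVGs and 150 iterations per fit); the
statistical structure, thresholds, and all planted effect sizes are
unchanged.

## Degenerate inputs and numerical conventions

Zero-variance cells get an undefined correlation and are treated as
below any positive threshold; constant score vectors scale to 0 and
stratify as mEMT; an all-tied series has τ = 0, p = 1; NMF updates are
floored at 1e-9 to avoid division by zero; ties in rankings break by
stable gene/cell order everywhere, so every result is reproducible from
a seed. Model-ranking ties break by higher test AUC, then model id.

## Known limitations

The anchor step is O(n²) in cells per group and intended for the
few-hundred-cell contrasts it is used on here. The cophenetic rank
criterion computes an N × N consensus per rank and is likewise meant for
per-sample cell counts in the hundreds. `screen_modules_by_program()`
uses mean scaled expression as the module score — a simplified eigengene,
not the full weighted-network construction. GSEA's gene-label
permutation tests a different null than phenotype permutation (gene
exchangeability, ignoring inter-gene correlation); with handfuls of
replicates per arm it is the only defensible choice, but its p-values
should be read accordingly.
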