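# emtmet

Pan-cancer single-cell studies of metastasis keep reusing the same
bespoke computational moves: call malignant cells from inferred
copy-number profiles, stratify them along an epithelial–mesenchymal
transition (EMT) axis, distill recurrent transcriptional meta-programs,
derive directed metastasis gene signatures, turn those signatures into a
bulk-cohort risk score, and finally ask which drugs might push the
signature back down. `emtmet` implements that whole chain as one tested,
reusable R package, together with a synthetic-data module that generates
every input with planted ground truth — so the pipeline can be exercised
and validated end to end without any downloads.

It is aimed at computational biologists who want either the individual
statistics (each is an exported, documented function) or the full
workflow on their own matrices.

## The methods in brief

**Malignancy calling.** From a cells × features CNV score matrix
(neutral = 1), each cell's *CNV Deviation* is the mean squared deviation
from neutrality,

    CNVDeviation_j = (1/n) Σ_i (CNVScore_ij − 1)²,

a reference curve is the feature-wise mean over the top 5% of cells by
deviation, and each cell's Pearson correlation *r* to that curve is
computed. Cells with deviation > 0.002 **and** r > 0.1 are Malignant;
cells below both thresholds are NotMalignant; everything else is Other.

**EMT stratification.** Cells are scored against a gene set either by a
control-binned module score (set mean minus expression-matched control
mean) or a ranking recovery-AUC score, min–max scaled to [0, 1], and
malignant cells are split at the 40%/60% score quantiles into
lEMT / mEMT / hEMT.

**Meta-programs.** Per-sample NMF (multiplicative updates, ranks 4–12,
10 restarts, rank chosen by cophenetic stability) yields gene modules;
modules with Jaccard > 0.05 to ≥ 5 partners are robust; a gene
co-occurrence network (edge weight = number of shared modules) is
partitioned with the Infomap map equation; near-duplicate programs merge
by single linkage.

**Signatures.** Three batches — module↔program correlation screening
(|r| > 0.2, p < 0.05), mapping-based contrastive DE between hEMT and
lEMT cells (mutual-nearest-neighbor anchors, removal of highly similar
pairs, Wilcoxon rank-sum, p < 0.05 and |avg_log2FC| > 0.25), and
Mann–Kendall pseudotime trends on spline-smoothed curves (p < 0.05,
|τ| > 0.7) — combined by ≥ 2-of-3 membership with direction from the DE
contrast, then shared across ≥ 3 cancers.

**Risk models.** Stratified 80/20 split; feature selection as the
intersection of ≥ 2 selectors (L1 logistic path, random-forest
importance, univariate AUC); candidate learners ranked by the

    Model Score = (CV + Test)/2 − λ·|CV − Test|,  λ = 0.8,

which penalizes the overfitting gap; the metastasis prediction score
(MPS/GMPS) is the logistic linear predictor β₀ + Σ βᵢxᵢ, with a median
High/Low risk split.

**Drug prioritization.** On a drug–target + PPI network seeded with the
signature, a random walk with restart
P(t+1) = αAP(t) + (1−α)P₀ (α = 0.7, A column-stochastic) scores drugs by
stationary mass; per-drug perturbation-vs-control rankings feed
pre-ranked permutation GSEA, whose NES sign labels a drug as
inhibiting/promoting the signature; both scores are min–max normalized
and combined as Drug Score = 0.6·Score_RWR + 0.4·Score_GSEA. A fitted
MPS applied to drug and control profiles (Wilcoxon) validates top hits.

## Worked example

```r
library(emtmet)

cfg   <- sim_config(seed = 42)          # 1000 genes x 2000 cells, 2 CNV blocks
sc    <- gen_single_cell(cfg)
cnv   <- gen_cnv_matrix(sc$truth, cfg)
calls <- call_malignancy(cnv)           # thresholds 0.002 / 0.1
table(calls$label)
#>    Malignant  Other
#>         1032    968

emt   <- control_binned_score(sc$matrix, sc$truth$emt_genes, seed = 1)
cor(emt$raw, sc$truth$emt_latent, method = "spearman")
#> [1] 0.972
strat <- stratify_emt(setNames(emt$scaled, emt$cell), group_by = sc$meta$cancer)
table(strat$subtype)
#> hEMT lEMT mEMT
#>  800  800  400
```

The malignancy call recovers the planted malignant population almost
perfectly (1032 called vs 1031 planted; F1 ≈ 0.9995), the module score
tracks the latent EMT gradient (Spearman ρ ≈ 0.97), and the 40/60
quantile split yields the expected 40/20/40 subtype proportions per
cancer. The same pattern continues downstream: `discover_meta_programs()`
returns the planted co-expression programs, `evaluate_models()` picks a
bulk model with test AUC ≈ 0.95, and `prioritize_drugs()` places all
five planted inhibitors at the top of the Drug Score ranking.

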