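Package: emtmet
Title: EMT-Driven Metastasis Signatures, Risk Models and Drug Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A pan-cancer single-cell workflow for studying
    epithelial-mesenchymal transition (EMT) driven metastasis. Identifies
    malignant cells from inferred copy-number profiles via a CNV-deviation
    statistic and a top-cell reference curve; scores cells against gene sets
    and stratifies malignant cells into low/medium/high EMT subtypes by
    quantiles; discovers robust cross-sample gene meta-programs with
    non-negative matrix factorization, Jaccard filtering, gene co-occurrence
    networks and map-equation community detection; derives metastasis
    signature gene sets by mapping-based contrastive differential expression
    and Mann-Kendall pseudotime trend screening; selects and scores bulk
    metastasis prediction models with a cross-validation/test concordance
    Model Score and computes per-sample metastasis prediction scores
    (MPS/GMPS); and prioritizes candidate anti-metastatic compounds by
    combining random walk with restart on drug-target networks with
    pre-ranked permutation GSEA of perturbation profiles. A synthetic-data
    module generates every input with planted ground truth so the whole
    pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    glmnet,
    ranger,
    splines,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    fgsea,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
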