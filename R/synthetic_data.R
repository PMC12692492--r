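#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators. The defaults define
#' the reference study conditions used throughout the package's tests: 2,000
#' cells with copy-number blocks shifted by +/-0.3 against noise sd 0.05, a
#' unit-strength latent EMT gradient over a 50-gene set, three planted
#' 50-gene co-expression programs, a 400-sample bulk cohort whose metastasis
#' label follows a logistic model with effect size 2, and a 50-drug world
#' with 5 planted inhibitors (target overlap 0.8, perturbation shift 1.0,
#' 20 replicates per arm).
#'
#' @param seed Master RNG seed; every generator derives its own substream
#'   from it, so modules are reproducible in isolation.
#' @param n_genes,n_cells,n_samples,n_cancers Dimensions of the single-cell
#'   world.
#' @param cnv_blocks List of planted CNV segments, each
#'   `list(features = <integer indices>, shift = <mean shift>)`.
#' @param n_cnv_features Number of genomic features in the CNV score matrix.
#' @param malignant_frac Fraction of cells carrying the CNV blocks.
#' @param emt_set_size Number of genes in the planted EMT set.
#' @param emt_gradient_sd Effect size of the latent EMT axis on EMT-set genes
#'   (log scale).
#' @param n_programs,program_size,program_effect Planted co-expression
#'   program parameters.
#' @param bulk_n,bulk_beta Bulk cohort size and logistic effect size.
#' @param n_drugs,n_planted_drugs Drug-world size and number of planted
#'   anti-metastatic drugs.
#' @param target_size Targets per drug.
#' @param target_overlap Fraction of a planted drug's targets drawn from the
#'   signature.
#' @param perturb_delta Log-scale down-shift planted drugs apply to
#'   up-signature genes.
#' @param perturb_reps Replicates per perturbation arm.
#' @param ppi_genes,ppi_density Size and edge density of the simulated
#'   protein-protein interaction layer.
#' @param noise_sd CNV score noise sd around the neutral value 1.
#' @param expr_noise_sd Log-scale expression noise sd.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 1000L, n_cells = 2000L,
                       n_samples = 6L, n_cancers = 3L,
                       cnv_blocks = list(list(features = 101:200, shift = 0.3),
                                         list(features = 501:600, shift = -0.3)),
                       n_cnv_features = 1000L,
                       malignant_frac = 0.5,
                       emt_set_size = 50L, emt_gradient_sd = 1,
                       n_programs = 3L, program_size = 50L, program_effect = 1,
                       bulk_n = 400L, bulk_beta = 2,
                       n_drugs = 50L, n_planted_drugs = 5L,
                       target_size = 8L, target_overlap = 0.8,
                       perturb_delta = 1, perturb_reps = 20L,
                       ppi_genes = 200L, ppi_density = 0.05,
                       noise_sd = 0.05, expr_noise_sd = 0.4) {
  cfg <- list(seed = seed, n_genes = n_genes, n_cells = n_cells,
              n_samples = n_samples, n_cancers = n_cancers,
              cnv_blocks = cnv_blocks, n_cnv_features = n_cnv_features,
              malignant_frac = malignant_frac,
              emt_set_size = emt_set_size, emt_gradient_sd = emt_gradient_sd,
              n_programs = n_programs, program_size = program_size,
              program_effect = program_effect,
              bulk_n = bulk_n, bulk_beta = bulk_beta,
              n_drugs = n_drugs, n_planted_drugs = n_planted_drugs,
              target_size = target_size, target_overlap = target_overlap,
              perturb_delta = perturb_delta, perturb_reps = perturb_reps,
              ppi_genes = ppi_genes, ppi_density = ppi_density,
              noise_sd = noise_sd, expr_noise_sd = expr_noise_sd)
  counts <- c("n_genes", "n_cells", "n_samples", "n_cancers", "n_cnv_features",
              "emt_set_size", "n_programs", "program_size", "bulk_n",
              "n_drugs", "n_planted_drugs", "target_size", "perturb_reps",
              "ppi_genes")
  for (f in counts) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 1 || v != round(v))
      stop_cfg(f, "must be a count >= 1")
  }
  effects <- c("emt_gradient_sd", "program_effect", "bulk_beta",
               "perturb_delta", "noise_sd", "expr_noise_sd")
  for (f in effects) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0)
      stop_cfg(f, "must be a non-negative real")
  }
  for (f in c("malignant_frac", "target_overlap", "ppi_density")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      stop_cfg(f, "must lie in [0, 1]")
  }
  if (cfg$n_planted_drugs > cfg$n_drugs)
    stop_cfg("n_planted_drugs", "cannot exceed n_drugs")
  if (!is.list(cfg$cnv_blocks) ||
      !all(vapply(cfg$cnv_blocks, function(b)
        is.list(b) && all(c("features", "shift") %in% names(b)), TRUE)))
    stop_cfg("cnv_blocks", "must be a list of list(features=, shift=)")
  for (b in cfg$cnv_blocks)
    if (any(b$features < 1) || any(b$features > cfg$n_cnv_features))
      stop_cfg("cnv_blocks", "feature indices outside 1..n_cnv_features")
  if ((cfg$emt_set_size + cfg$n_programs * cfg$program_size) > cfg$n_genes)
    stop_cfg("n_genes", "too small for EMT set plus planted programs")
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic single-cell world
#'
#' Draws a genes-by-cells expression matrix with the latent structure every
#' downstream module assumes: a latent EMT axis in \[0, 1\] loading linearly
#' (effect `emt_gradient_sd`) on the planted EMT gene set, disjoint
#' co-expression programs (each cell is dominated by one program), and a
#' malignant mask that later receives CNV blocks. Expression is Gaussian on
#' the log1p scale; the counts layer is `round(expm1(log))`.
#'
#' @param config A [sim_config()].
#' @return List with elements `matrix` (a [cell_matrix()]), `meta`
#'   (data.frame: cell, sample, cancer, stage, met_state, cell_type) and
#'   `truth` (list: malignant, emt_latent, pseudotime, program_membership,
#'   emt_genes, signature).
#' @export
gen_single_cell <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(substream(config$seed, 1L), {
    G <- config$n_genes; N <- config$n_cells
    genes <- sprintf("g%04d", seq_len(G))
    cells <- sprintf("cell%05d", seq_len(N))
    sample_id <- sprintf("S%02d", 1 + (seq_len(N) - 1) %% config$n_samples)
    cancer_of_sample <- sprintf("CA%02d",
      1 + (seq_len(config$n_samples) - 1) %% config$n_cancers)
    cancer <- cancer_of_sample[as.integer(sub("S", "", sample_id))]

    emt_genes <- genes[seq_len(config$emt_set_size)]
    program_membership <- rep(NA_character_, G)
    names(program_membership) <- genes
    prog_names <- sprintf("P%d", seq_len(config$n_programs))
    for (p in seq_len(config$n_programs)) {
      idx <- config$emt_set_size + (p - 1) * config$program_size +
        seq_len(config$program_size)
      program_membership[idx] <- prog_names[p]
    }

    malignant <- stats::runif(N) < config$malignant_frac
    emt_latent <- stats::runif(N)
    pseudotime <- emt_latent   # the hEMT -> myCAF axis the trend screen reads

    mu <- stats::runif(G, 0.5, 2)              # baseline log1p expression
    L <- matrix(stats::rnorm(G * N, sd = config$expr_noise_sd), G, N) + mu
    emt_load <- stats::runif(config$emt_set_size, 0.5, 1.5)
    L[seq_len(config$emt_set_size), ] <- L[seq_len(config$emt_set_size), ] +
      config$emt_gradient_sd * outer(emt_load, emt_latent)
    primary_prog <- sample.int(config$n_programs, N, replace = TRUE)
    activity <- stats::runif(N, 0.5, 1.5) * config$program_effect
    for (p in seq_len(config$n_programs)) {
      rows <- which(program_membership == prog_names[p])
      on <- primary_prog == p
      gl <- stats::runif(length(rows), 0.5, 1.5)
      L[rows, on] <- L[rows, on] + outer(gl, activity[on])
    }
    L <- pmax(L, 0)
    counts <- round(expm1(L))

    mat <- cell_matrix(counts = counts, logcounts = L,
                       gene_ids = genes, cell_ids = cells)
    meta <- data.frame(cell = cells, sample = sample_id, cancer = cancer,
                       stage = sample(c("I", "II", "III", "IV"), N, TRUE),
                       met_state = sample(c("NM", "RM", "DM", "UM"), N, TRUE),
                       cell_type = "Epithelial",
                       stringsAsFactors = FALSE)
    names(malignant) <- names(emt_latent) <- names(pseudotime) <- cells
    truth <- list(malignant = malignant, emt_latent = emt_latent,
                  pseudotime = pseudotime,
                  program_membership = program_membership,
                  emt_genes = emt_genes,
                  signature = data.frame(gene = emt_genes, direction = "up",
                                         stringsAsFactors = FALSE))
    list(matrix = mat, meta = meta, truth = truth)
  })
}

#' Generate an inferred-CNV style score matrix
#'
#' Cells-by-features scores centred at the neutral value 1. Non-malignant
#' cells are pure noise around 1; malignant cells additionally carry the
#' configured amplification/deletion block shifts.
#'
#' @param truth Ground truth from [gen_single_cell()] (needs `malignant`).
#' @param config A [sim_config()].
#' @return A [cnv_profile()].
#' @export
gen_cnv_matrix <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"), is.logical(truth$malignant))
  with_seed(substream(config$seed, 2L), {
    N <- length(truth$malignant)
    Fn <- config$n_cnv_features
    scores <- 1 + matrix(stats::rnorm(N * Fn, sd = config$noise_sd), N, Fn)
    mal <- which(truth$malignant)
    for (b in config$cnv_blocks)
      scores[mal, b$features] <- scores[mal, b$features] + b$shift
    scores <- pmax(scores, 1e-6)
    rownames(scores) <- names(truth$malignant)
    colnames(scores) <- sprintf("feat%04d", seq_len(Fn))
    cnv_profile(scores)
  })
}

#' Generate a bulk cohort with logistic metastasis labels
#'
#' Gene expression is standard normal on the log scale; the metastasis label
#' is Bernoulli with success probability
#' `sigmoid(bulk_beta * sum(dir_g * x_g))` over the signature genes. The
#' symmetric, centred predictor keeps the class balance near 1:1 at any
#' effect size.
#'
#' @param config A [sim_config()].
#' @param signature Data.frame with columns `gene` and `direction`
#'   (`"up"`/`"down"`), or a character vector (all taken as up).
#' @return List with `expr` (genes x samples), `labels` (data.frame: sample,
#'   label in NM/M) and `prob` (the generating probabilities).
#' @export
gen_bulk <- function(config, signature) {
  stopifnot(inherits(config, "sim_config"))
  signature <- as_signature(signature)
  if (nrow(signature) == 0) stop("signature must be non-empty")
  with_seed(substream(config$seed, 3L), {
    sig_genes <- signature$gene
    n_bg <- max(config$n_genes - length(sig_genes), 0)
    genes <- c(sig_genes, sprintf("bg%04d", seq_len(n_bg)))
    samples <- sprintf("bulk%04d", seq_len(config$bulk_n))
    X <- matrix(stats::rnorm(length(genes) * config$bulk_n),
                length(genes), config$bulk_n,
                dimnames = list(genes, samples))
    dir <- ifelse(signature$direction == "down", -1, 1)
    eta <- config$bulk_beta * colSums(dir * X[sig_genes, , drop = FALSE])
    prob <- stats::plogis(eta)
    lab <- ifelse(stats::rbinom(config$bulk_n, 1, prob) == 1, "M", "NM")
    list(expr = X,
         labels = data.frame(sample = samples, label = lab,
                             stringsAsFactors = FALSE),
         prob = prob)
  })
}

#' Generate a drug-target world with planted anti-metastatic drugs
#'
#' Builds a gene universe containing the signature, a random PPI layer over
#' it (Erdos-Renyi at `ppi_density`), drug-target edges in which planted
#' drugs draw a fraction `target_overlap` of their targets from the
#' signature, and perturbation profiles in which planted drugs down-shift
#' up-signature genes by `perturb_delta` (and up-shift down-signature genes
#' symmetrically) on the log scale; decoy drugs have null profiles.
#'
#' @param config A [sim_config()].
#' @param signature As in [gen_bulk()].
#' @return List with `drug_targets` (data.frame drug/gene), `ppi`
#'   (data.frame gene_a/gene_b), `profiles` (list: per-drug matrices and a
#'   shared `ctrl` matrix, genes x replicates), and `truth`
#'   (`planted_drugs`).
#' @export
gen_drug_world <- function(config, signature) {
  stopifnot(inherits(config, "sim_config"))
  signature <- as_signature(signature)
  if (nrow(signature) == 0) stop("signature must be non-empty")
  if (config$n_planted_drugs > config$n_drugs)
    stop_cfg("n_planted_drugs", "cannot exceed n_drugs")
  with_seed(substream(config$seed, 4L), {
    sig_genes <- signature$gene
    n_bg <- max(config$ppi_genes - length(sig_genes), 0)
    genes <- c(sig_genes, sprintf("net%04d", seq_len(n_bg)))
    drugs <- sprintf("drug%03d", seq_len(config$n_drugs))
    planted <- drugs[seq_len(config$n_planted_drugs)]

    n_sig_tgt <- round(config$target_overlap * config$target_size)
    targets <- lapply(seq_along(drugs), function(i) {
      if (drugs[i] %in% planted) {
        c(sample(sig_genes, min(n_sig_tgt, length(sig_genes))),
          sample(setdiff(genes, sig_genes),
                 config$target_size - min(n_sig_tgt, length(sig_genes))))
      } else sample(genes, config$target_size)
    })
    drug_targets <- data.frame(
      drug = rep(drugs, lengths(targets)),
      gene = unlist(targets), stringsAsFactors = FALSE)

    # Erdos-Renyi PPI layer; above ~log(n)/n density it is connected whp.
    pairs <- utils::combn(genes, 2)
    keep <- stats::runif(ncol(pairs)) < config$ppi_density
    ppi <- data.frame(gene_a = pairs[1, keep], gene_b = pairs[2, keep],
                      stringsAsFactors = FALSE)

    base <- stats::runif(length(genes), 4, 8)      # control log expression
    draw_arm <- function(shift) {
      m <- matrix(stats::rnorm(length(genes) * config$perturb_reps,
                               sd = config$expr_noise_sd),
                  length(genes), config$perturb_reps) + base + shift
      rownames(m) <- genes
      colnames(m) <- sprintf("rep%02d", seq_len(config$perturb_reps))
      m
    }
    dir <- ifelse(signature$direction == "down", -1, 1)
    planted_shift <- numeric(length(genes))
    names(planted_shift) <- genes
    planted_shift[sig_genes] <- -config$perturb_delta * dir
    profiles <- list(ctrl = draw_arm(0))
    for (d in drugs)
      profiles[[d]] <- draw_arm(if (d %in% planted) planted_shift else 0)

    list(drug_targets = drug_targets, ppi = ppi, profiles = profiles,
         truth = list(planted_drugs = planted))
  })
}

# Coerce a character vector or data.frame into the signature layout.
as_signature <- function(x) {
  if (is.character(x))
    return(data.frame(gene = x, direction = "up", stringsAsFactors = FALSE))
  stopifnot(is.data.frame(x), all(c("gene", "direction") %in% names(x)))
  x[, c("gene", "direction")]
}

#' Write every synthetic input to disk in standard formats
#'
#' Materializes one simulated world as the plain-text formats the pipeline
#' consumes: MTX + sidecars for the expression matrix, TSV for metadata,
#' pseudotime, CNV scores, bulk cohort, labels and edge lists, GMT for gene
#' sets.
#'
#' @param config A [sim_config()].
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_sim_inputs <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sc <- gen_single_cell(config)
  write_cell_matrix(sc$matrix, file.path(dir, "expression"))
  write_tsv(sc$meta, file.path(dir, "meta.tsv"))
  write_tsv(data.frame(cell = names(sc$truth$pseudotime),
                       pseudotime = sc$truth$pseudotime),
            file.path(dir, "pseudotime.tsv"))
  cnv <- gen_cnv_matrix(sc$truth, config)
  utils::write.table(cnv$scores, file.path(dir, "cnv_scores.tsv"),
                     sep = "\t", quote = FALSE)
  write_gmt(list(EMT = sc$truth$emt_genes), file.path(dir, "emt.gmt"))
  bulk <- gen_bulk(config, sc$truth$signature)
  utils::write.table(bulk$expr, file.path(dir, "bulk_expr.tsv"),
                     sep = "\t", quote = FALSE)
  write_tsv(bulk$labels, file.path(dir, "bulk_labels.tsv"))
  world <- gen_drug_world(config, sc$truth$signature)
  write_tsv(world$drug_targets, file.path(dir, "drug_targets.tsv"))
  write_tsv(world$ppi, file.path(dir, "ppi.tsv"))
  invisible(dir)
}
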