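#' Build a drug-target / PPI network with a seeded transition operator
#'
#' Merges drug-target edges and gene-gene (PPI) edges into one simple
#' undirected graph, removes isolated nodes, and column-normalizes the
#' adjacency matrix into the random-walk transition operator. Seed genes
#' (the metastasis signature) are intersected with the network; seeds
#' absent from it are dropped with a warning, an empty intersection is an
#' error.
#'
#' @param drug_target_edges Data.frame with columns `drug`, `gene`.
#' @param ppi_edges Data.frame with columns `gene_a`, `gene_b`.
#' @param seeds Character vector of seed gene ids.
#' @return Object of class `drug_network`: `graph`, `A` (sparse
#'   column-stochastic), `nodes`, `node_type` ("drug"/"gene"), `seeds`.
#' @export
build_network <- function(drug_target_edges, ppi_edges, seeds) {
  if (nrow(drug_target_edges) == 0 && nrow(ppi_edges) == 0)
    stop("edge lists are empty")
  edges <- rbind(
    data.frame(from = paste0("drug:", drug_target_edges$drug),
               to = drug_target_edges$gene, stringsAsFactors = FALSE),
    data.frame(from = ppi_edges$gene_a, to = ppi_edges$gene_b,
               stringsAsFactors = FALSE))
  g <- igraph::simplify(igraph::graph_from_data_frame(edges, directed = FALSE))
  g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  nodes <- igraph::V(g)$name
  node_type <- ifelse(startsWith(nodes, "drug:"), "drug", "gene")
  kept <- intersect(seeds, nodes[node_type == "gene"])
  if (length(kept) == 0) stop("no seed gene present in the network")
  if (length(kept) < length(seeds))
    warning(length(seeds) - length(kept),
            " seed gene(s) absent from the network; dropped")
  adj <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  deg <- Matrix::colSums(adj)
  deg[deg == 0] <- 1  # no dangling columns survive isolation removal
  A <- adj %*% Matrix::Diagonal(x = 1 / deg)
  dimnames(A) <- list(nodes, nodes)
  structure(list(graph = g, A = A, nodes = nodes, node_type = node_type,
                 seeds = kept),
            class = "drug_network")
}

#' Random walk with restart
#'
#' Iterates `P_{t+1} = alpha * A %*% P_t + (1 - alpha) * P_0` from the
#' normalized binary seed indicator `P_0` until the L1 change drops below
#' `tol`. The stationary vector sums to 1; its mass on drug nodes is the
#' network-propagation drug score.
#'
#' @param network A [build_network()] object.
#' @param alpha Diffusion parameter (default 0.7; `alpha = 0` returns
#'   `P_0`).
#' @param tol L1 convergence tolerance.
#' @param max_iter Iteration cap; exceeding it is an error reporting the
#'   residual.
#' @return Named stationary probability vector over all nodes.
#' @export
rwr <- function(network, alpha = 0.7, tol = 1e-10, max_iter = 10000) {
  stopifnot(inherits(network, "drug_network"))
  if (alpha < 0 || alpha >= 1) stop("alpha must lie in [0, 1)")
  p0 <- as.numeric(network$nodes %in% network$seeds)
  p0 <- p0 / sum(p0)
  p <- p0
  for (it in seq_len(max_iter)) {
    p_new <- as.numeric(alpha * (network$A %*% p)) + (1 - alpha) * p0
    res <- sum(abs(p_new - p))
    p <- p_new
    if (res < tol) return(stats::setNames(p, network$nodes))
  }
  stop(sprintf("RWR did not converge in %d iterations (residual %.3g)",
               max_iter, res))
}

#' Rank genes by a perturbation-vs-control statistic
#'
#' Per-gene Welch t statistic between drug-treated and control replicate
#' profiles, genes sorted by decreasing statistic (ties broken by gene id).
#' With a single replicate per arm the log2 fold change is used instead
#' (noted in `attr(, "method")`).
#'
#' @param drug_profiles,ctrl_profiles Genes x replicates matrices with
#'   rownames.
#' @return Data.frame: `gene`, `stat`, sorted descending.
#' @export
rank_perturbation <- function(drug_profiles, ctrl_profiles) {
  if (ncol(drug_profiles) == 0 || ncol(ctrl_profiles) == 0)
    stop("each arm needs at least one sample")
  shared <- intersect(rownames(drug_profiles), rownames(ctrl_profiles))
  if (length(shared) == 0) stop("no shared genes between arms")
  Xd <- drug_profiles[shared, , drop = FALSE]
  Xc <- ctrl_profiles[shared, , drop = FALSE]
  if (ncol(Xd) >= 2 && ncol(Xc) >= 2) {
    m <- rowMeans(Xd) - rowMeans(Xc)
    se <- sqrt(apply(Xd, 1, stats::var) / ncol(Xd) +
               apply(Xc, 1, stats::var) / ncol(Xc))
    stat <- ifelse(se == 0, 0, m / se)
    method <- "welch_t"
  } else {
    stat <- rowMeans(Xd) - rowMeans(Xc)  # log scale: log2FC up to a factor
    method <- "log_fc"
  }
  out <- data.frame(gene = shared, stat = unname(stat),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$stat, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "method") <- method
  out
}

# ES of a gene set at given hit positions in a ranking of length G,
# hit weights w (>= 0). Weighted KS running-sum extreme.
running_es <- function(pos, w, G) {
  k <- length(pos)
  o <- order(pos)
  pos <- pos[o]; w <- w[o]
  W <- sum(w)
  if (W == 0) w <- rep(1, k) else w <- w
  W <- sum(w)
  cw <- cumsum(w) / W
  miss <- 1 / (G - k)
  after <- cw - (pos - seq_len(k)) * miss        # just after each hit
  before <- c(0, cw[-k]) - (pos - seq_len(k)) * miss  # just before each hit
  vals <- c(after, before)
  vals[which.max(abs(vals))]
}

#' Pre-ranked GSEA with gene-label permutation
#'
#' Weighted Kolmogorov-Smirnov enrichment of a gene set in a signed
#' ranking: hits increment the running sum proportionally to
#' `|stat|^weight_exp`, misses decrement uniformly; ES is the extreme of
#' the running sum. The null distribution comes from `n_perm` random gene
#' sets of the same size; `NES = ES / mean(|null ES| of matching sign)` and
#' the two-sided p-value is `(1 + #{|null ES| >= |ES|}) / (n_perm + 1)`.
#'
#' @param ranking Data.frame from [rank_perturbation()] (`gene`, `stat`),
#'   or a named numeric vector of statistics.
#' @param gene_set Character vector; needs >= 3 genes in the ranking.
#' @param n_perm Permutations (default 1000).
#' @param seed RNG seed.
#' @param weight_exp Hit-weight exponent (default 1).
#' @return List: `es`, `nes`, `p`.
#' @export
gsea_preranked <- function(ranking, gene_set, n_perm = 1000, seed = 1L,
                           weight_exp = 1) {
  if (is.numeric(ranking))
    ranking <- data.frame(gene = names(ranking), stat = unname(ranking),
                          stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$stat, ranking$gene), , drop = FALSE]
  G <- nrow(ranking)
  hit <- ranking$gene %in% gene_set
  k <- sum(hit)
  if (k < 3) stop("fewer than 3 set genes overlap the ranking")
  if (k >= G) stop("gene set covers the whole ranking")
  wts <- abs(ranking$stat)^weight_exp
  pos <- which(hit)
  es <- running_es(pos, wts[pos], G)
  null_es <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      rp <- sample.int(G, k)
      running_es(rp, wts[rp], G)
    }, 0)
  })
  same <- null_es[sign(null_es) == sign(es)]
  denom <- if (length(same) > 0) mean(abs(same)) else mean(abs(null_es))
  nes <- if (denom > 0) es / denom else 0
  p <- (1 + sum(abs(null_es) >= abs(es))) / (n_perm + 1)
  list(es = es, nes = nes, p = p)
}

#' Map NES values to a \[0, 1\] enrichment drug score
#'
#' For an up-direction metastasis signature, a drug that down-regulates the
#' signature (negative NES) should score high: `score_gsea` is the min-max
#' normalization of `-NES` across the candidate drugs. The effect label is
#' `inhibits` for negative NES, `promotes` for positive.
#'
#' @param nes Named per-drug NES vector (>= 2 drugs).
#' @param signature_direction Direction of the scored signature
#'   (currently `"up"`).
#' @return Data.frame: drug, nes, score_gsea, effect.
#' @export
score_gsea <- function(nes, signature_direction = "up") {
  if (length(nes) < 2) stop("need at least 2 drugs")
  stopifnot(signature_direction == "up")
  data.frame(drug = names(nes) %||% as.character(seq_along(nes)),
             nes = unname(nes),
             score_gsea = minmax(-unname(nes)),
             effect = ifelse(nes < 0, "inhibits", "promotes"),
             stringsAsFactors = FALSE)
}

#' Weighted Drug Score
#'
#' `l1 * score_rwr + l2 * score_gsea` over the candidate drugs (both inputs
#' already min-max normalized over the same candidate set), ranked
#' descending.
#'
#' @param score_rwr,score_gsea Aligned named numeric vectors in \[0, 1\].
#' @param l1,l2 Weights (defaults 0.6 and 0.4; a sum away from 1 warns).
#' @return Data.frame: drug, score_rwr, score_gsea, drug_score, ranked.
#' @export
drug_score <- function(score_rwr, score_gsea, l1 = 0.6, l2 = 0.4) {
  stopifnot(length(score_rwr) == length(score_gsea))
  if (abs(l1 + l2 - 1) > 1e-8) warning("weights do not sum to 1")
  out <- data.frame(drug = names(score_rwr) %||%
                      as.character(seq_along(score_rwr)),
                    score_rwr = unname(score_rwr),
                    score_gsea = unname(score_gsea),
                    drug_score = l1 * unname(score_rwr) +
                      l2 * unname(score_gsea),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$drug_score, out$drug), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank candidate anti-metastatic drugs
#'
#' End-to-end prioritization: build the drug-target/PPI network seeded with
#' the signature, run the restart walk to get each drug's propagation
#' score, run perturbation-vs-control ranking plus pre-ranked GSEA of the
#' up-signature per drug, intersect the drugs covered by both routes,
#' min-max normalize both scores over that candidate set, and combine them
#' with the weighted Drug Score.
#'
#' @param drug_targets,ppi Edge lists as in [build_network()].
#' @param signature Data.frame (`gene`, `direction`) or character vector.
#' @param profiles List of genes x replicates matrices, one per drug, plus
#'   a `ctrl` element (as from [gen_drug_world()]).
#' @param alpha RWR diffusion (default 0.7).
#' @param l1,l2 Drug Score weights (defaults 0.6/0.4).
#' @param n_perm GSEA permutations per drug.
#' @param seed RNG seed.
#' @return Data.frame: drug, score_rwr (raw and normalized), es, nes,
#'   p_gsea, score_gsea, drug_score, effect; ranked by drug_score.
#' @export
prioritize_drugs <- function(drug_targets, ppi, signature, profiles,
                             alpha = 0.7, l1 = 0.6, l2 = 0.4,
                             n_perm = 1000, seed = 1L) {
  signature <- as_signature(signature)
  up_genes <- signature$gene[signature$direction != "down"]
  network <- build_network(drug_targets, ppi, seeds = up_genes)
  p_star <- rwr(network, alpha = alpha)
  drug_nodes <- network$nodes[network$node_type == "drug"]
  rwr_raw <- stats::setNames(p_star[drug_nodes],
                             sub("^drug:", "", drug_nodes))
  profile_drugs <- setdiff(names(profiles), "ctrl")
  cand <- intersect(names(rwr_raw), profile_drugs)
  if (length(cand) < 2) stop("fewer than 2 drugs covered by both routes")
  gsea <- lapply(cand, function(d) {
    rk <- rank_perturbation(profiles[[d]], profiles$ctrl)
    gsea_preranked(rk, up_genes, n_perm = n_perm,
                   seed = substream(seed, match(d, cand)))
  })
  nes <- stats::setNames(vapply(gsea, `[[`, 0, "nes"), cand)
  sg <- score_gsea(nes)
  ds <- drug_score(stats::setNames(minmax(rwr_raw[cand]), cand),
                   stats::setNames(sg$score_gsea, sg$drug)[cand],
                   l1 = l1, l2 = l2)
  info <- data.frame(drug = cand,
                     rwr_raw = unname(rwr_raw[cand]),
                     es = vapply(gsea, `[[`, 0, "es"),
                     nes = unname(nes),
                     p_gsea = vapply(gsea, `[[`, 0, "p"),
                     effect = sg$effect[match(cand, sg$drug)],
                     stringsAsFactors = FALSE)
  out <- merge(ds, info, by = "drug", sort = FALSE)
  out <- out[order(-out$drug_score, out$drug), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Perturbation MPS shift test
#'
#' Computes the metastasis prediction score per replicate in the
#' drug-treated and control arms and compares them: the effect size is the
#' median difference (drug minus control) and significance comes from the
#' two-sided Wilcoxon rank-sum test. A genuinely inhibitory drug yields a
#' negative shift.
#'
#' @param model A [fit_score_model()] object.
#' @param drug_profiles,ctrl_profiles Genes x replicates matrices.
#' @return List: `delta`, `p`, `mps_drug`, `mps_ctrl`.
#' @export
perturbation_mps_test <- function(model, drug_profiles, ctrl_profiles) {
  mps_d <- compute_score(model, drug_profiles)
  mps_c <- compute_score(model, ctrl_profiles)
  wt <- suppressWarnings(stats::wilcox.test(mps_d, mps_c))
  list(delta = stats::median(mps_d) - stats::median(mps_c),
       p = wt$p.value, mps_drug = mps_d, mps_ctrl = mps_c)
}
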