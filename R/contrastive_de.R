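#' Mutual-nearest-neighbor anchor pairs between two cell groups
#'
#' Embeds both groups jointly (PCA of the concatenated log layer, first
#' `n_pcs` components) and pairs cells that are mutual k-nearest neighbors
#' across groups. Pair similarity is the Pearson correlation of the two
#' cells' PC coordinate vectors. This establishes the bidirectional
#' correspondence used to strip shared background before contrastive
#' differential expression.
#'
#' @param a,b [cell_matrix()] objects sharing a gene space.
#' @param n_pcs Principal components used (default 30, capped by the data).
#' @param k Neighbors per direction (default 5).
#' @return Data.frame: `cell_a`, `cell_b`, `similarity`.
#' @export
anchor_map <- function(a, b, n_pcs = 30, k = 5) {
  stopifnot(inherits(a, "cell_matrix"), inherits(b, "cell_matrix"))
  shared <- intersect(a$gene_ids, b$gene_ids)
  if (length(shared) == 0) stop("gene spaces are disjoint")
  na <- length(a$cell_ids); nb <- length(b$cell_ids)
  if (na < k || nb < k) stop("each group needs at least k cells")
  X <- t(cbind(a$logcounts[shared, , drop = FALSE],
               b$logcounts[shared, , drop = FALSE]))
  n_pcs <- min(n_pcs, nrow(X) - 1, ncol(X))
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = n_pcs)$x
  pa <- pc[seq_len(na), , drop = FALSE]
  pb <- pc[na + seq_len(nb), , drop = FALSE]
  # cross-group squared distances
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * tcrossprod(pa, pb)
  knn_ab <- t(matrix(apply(d2, 1, function(r)
    order(r, seq_along(r))[seq_len(k)]), nrow = k))
  knn_ba <- t(matrix(apply(d2, 2, function(r)
    order(r, seq_along(r))[seq_len(k)]), nrow = k))
  out <- list()
  for (i in seq_len(na)) {
    for (j in knn_ab[i, ]) {
      if (i %in% knn_ba[j, ]) {
        out[[length(out) + 1L]] <- c(i, j)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(cell_a = character(), cell_b = character(),
                      similarity = numeric(), stringsAsFactors = FALSE))
  m <- do.call(rbind, out)
  sim <- vapply(seq_len(nrow(m)), function(r)
    stats::cor(pa[m[r, 1], ], pb[m[r, 2], ]), 0)
  data.frame(cell_a = a$cell_ids[m[, 1]], cell_b = b$cell_ids[m[, 2]],
             similarity = sim, stringsAsFactors = FALSE)
}

#' Remove highly similar anchored cells from both groups
#'
#' Both members of every anchor pair whose similarity exceeds `sim_thr` are
#' dropped; all other cells are retained. This removes the shared background
#' population that would dilute the hEMT-vs-lEMT contrast.
#'
#' @param a,b [cell_matrix()] objects the pairs refer to.
#' @param pairs Data.frame from [anchor_map()].
#' @param sim_thr Similarity threshold (default 0.9, strict).
#' @return List: `a_keep`, `b_keep` (retained cell ids).
#' @export
drop_similar <- function(a, b, pairs, sim_thr = 0.9) {
  hot <- pairs[pairs$similarity > sim_thr, , drop = FALSE]
  list(a_keep = setdiff(a$cell_ids, hot$cell_a),
       b_keep = setdiff(b$cell_ids, hot$cell_b))
}

#' Wilcoxon rank-sum differential expression
#'
#' Per gene, a two-sided Wilcoxon rank-sum test on the log layer between
#' groups A and B, with the pseudocount fold change
#' `avg_log2FC = log2((mean(expm1(a)) + 1) / (mean(expm1(b)) + 1))`.
#' Genes satisfying `p < p_max` and `|avg_log2FC| > lfc_min` are reported,
#' with BH-adjusted p-values alongside for the record; the full table is in
#' `attr(, "all")`.
#'
#' @param a,b [cell_matrix()] objects on a shared gene space (or plain
#'   genes x cells log matrices with rownames).
#' @param p_max,lfc_min Reporting thresholds (defaults 0.05 and 0.25).
#' @return Data.frame: gene, avg_log2FC, p, p_adj, direction (up = higher
#'   in A).
#' @export
wilcoxon_de <- function(a, b, p_max = 0.05, lfc_min = 0.25) {
  La <- if (inherits(a, "cell_matrix")) a$logcounts else as.matrix(a)
  Lb <- if (inherits(b, "cell_matrix")) b$logcounts else as.matrix(b)
  shared <- intersect(rownames(La), rownames(Lb))
  if (length(shared) == 0) stop("no shared genes")
  if (ncol(La) < 3 || ncol(Lb) < 3) stop("each group needs at least 3 cells")
  La <- La[shared, , drop = FALSE]; Lb <- Lb[shared, , drop = FALSE]
  p <- vapply(shared, function(g)
    suppressWarnings(stats::wilcox.test(La[g, ], Lb[g, ])$p.value), 0)
  lfc <- log2((rowMeans(expm1(La)) + 1) / (rowMeans(expm1(Lb)) + 1))
  all_tab <- data.frame(gene = shared, avg_log2FC = unname(lfc),
                        p = unname(p),
                        p_adj = stats::p.adjust(p, "BH"),
                        direction = ifelse(lfc >= 0, "up", "down"),
                        stringsAsFactors = FALSE, row.names = NULL)
  keep <- all_tab[all_tab$p < p_max & abs(all_tab$avg_log2FC) > lfc_min, ]
  rownames(keep) <- NULL
  attr(keep, "all") <- all_tab
  keep
}

#' Mapping-based contrastive differential expression
#'
#' The full contrast between two cell states: anchor the groups, drop
#' mutual pairs above the similarity threshold, then run [wilcoxon_de()] on
#' the remaining cells.
#'
#' @inheritParams anchor_map
#' @inheritParams drop_similar
#' @inheritParams wilcoxon_de
#' @return As [wilcoxon_de()].
#' @export
contrastive_de <- function(a, b, n_pcs = 30, k = 5, sim_thr = 0.9,
                           p_max = 0.05, lfc_min = 0.25) {
  pairs <- anchor_map(a, b, n_pcs = n_pcs, k = k)
  kept <- drop_similar(a, b, pairs, sim_thr = sim_thr)
  if (length(kept$a_keep) < 3 || length(kept$b_keep) < 3)
    stop("fewer than 3 cells left after similarity filtering")
  wilcoxon_de(subset_cells(a, match(kept$a_keep, a$cell_ids)),
              subset_cells(b, match(kept$b_keep, b$cell_ids)),
              p_max = p_max, lfc_min = lfc_min)
}

#' Smooth expression along pseudotime
#'
#' Natural cubic spline regression of one gene's expression on pseudotime,
#' evaluated on an even `n_points` grid across the observed pseudotime
#' range.
#'
#' @param expr Per-cell expression vector.
#' @param pseudotime Per-cell pseudotime, same length.
#' @param n_points Grid size (default 100).
#' @param df Spline degrees of freedom (default 3).
#' @return Data.frame: `pseudotime` (grid), `value` (fitted).
#' @export
smooth_curve <- function(expr, pseudotime, n_points = 100, df = 3) {
  ok <- is.finite(pseudotime) & is.finite(expr)
  if (sum(ok) < 10) stop("need at least 10 cells with finite pseudotime")
  pt <- pseudotime[ok]; y <- expr[ok]
  if (stats::sd(pt) == 0) stop("pseudotime is constant")
  grid <- seq(min(pt), max(pt), length.out = n_points)
  if (stats::sd(y) == 0)
    return(data.frame(pseudotime = grid, value = rep(y[1], n_points)))
  fit <- stats::lm(y ~ splines::ns(pt, df = df))
  data.frame(pseudotime = grid,
             value = unname(stats::predict(fit,
                                           newdata = data.frame(pt = grid))))
}

# Mahonian numbers: counts of permutations of n by inversion number.
mahonian <- function(n) {
  counts <- 1
  for (m in 2:n) {
    new <- numeric(length(counts) + m - 1)
    for (shift in 0:(m - 1))
      new[shift + seq_along(counts)] <- new[shift + seq_along(counts)] + counts
    counts <- new
  }
  counts
}

#' Mann-Kendall trend test
#'
#' Kendall's S statistic over all ordered pairs of the series, with
#' `tau = S / (n(n-1)/2)`. The p-value is two-sided: exact (enumeration of
#' the permutation distribution of S via inversion counts) for tie-free
#' series of length <= 10, otherwise the normal approximation with tie
#' correction and continuity correction. An all-tied series returns
#' `tau = 0, p = 1`.
#'
#' @param series Numeric vector, length >= 4.
#' @return List: `tau`, `p`, `S`.
#' @export
mann_kendall <- function(series) {
  n <- length(series)
  if (n < 4) stop("series must have length >= 4")
  d <- outer(series, series, "-")
  S <- sum(sign(d[lower.tri(d)]))  # lower triangle holds x_j - x_i for j > i
  n_pairs <- n * (n - 1) / 2
  tau <- S / n_pairs
  ties <- table(series)
  if (all(ties == n)) return(list(tau = 0, p = 1, S = 0))
  has_ties <- any(ties > 1)
  if (!has_ties && n <= 10) {
    counts <- mahonian(n)
    inv <- 0:(length(counts) - 1)
    s_vals <- n_pairs - 2 * inv
    p <- sum(counts[abs(s_vals) >= abs(S)]) / sum(counts)
  } else {
    t_corr <- sum(ties * (ties - 1) * (2 * ties + 5))
    var_s <- (n * (n - 1) * (2 * n + 5) - t_corr) / 18
    z <- if (S > 0) (S - 1) / sqrt(var_s)
         else if (S < 0) (S + 1) / sqrt(var_s) else 0
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(tau = tau, p = min(p, 1), S = S)
}

#' Screen genes for monotone pseudotime trends
#'
#' Per gene: smooth expression along pseudotime with [smooth_curve()], then
#' apply [mann_kendall()] to the fitted grid values. Genes with
#' `p < p_max` and `|tau| > tau_min` are reported, direction from the sign
#' of tau. (The default `tau_min = 0.7` is the stringent preset; 0.4 is the
#' permissive alternative.)
#'
#' @param matrix A [cell_matrix()] or genes x cells log matrix.
#' @param pseudotime Per-cell pseudotime aligned with the columns.
#' @param p_max,tau_min Thresholds (defaults 0.05 and 0.7).
#' @param n_points Smoothing grid size.
#' @return Data.frame: gene, tau, p, direction.
#' @export
trend_genes <- function(matrix, pseudotime, p_max = 0.05, tau_min = 0.7,
                        n_points = 100) {
  L <- if (inherits(matrix, "cell_matrix")) matrix$logcounts else as.matrix(matrix)
  stopifnot(length(pseudotime) == ncol(L))
  res <- lapply(rownames(L), function(g) {
    sm <- smooth_curve(L[g, ], pseudotime, n_points = n_points)
    mk <- mann_kendall(sm$value)
    data.frame(gene = g, tau = mk$tau, p = mk$p, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  keep <- tab[tab$p < p_max & abs(tab$tau) > tau_min, , drop = FALSE]
  keep$direction <- ifelse(keep$tau > 0, "up", "down")
  rownames(keep) <- NULL
  keep
}

#' Combine the three gene-set batches into a directed signature
#'
#' A gene enters the signature when it appears in at least `min_membership`
#' of the three batches (module screen, contrastive DE, pseudotime trends).
#' Direction comes from the DE batch when available (the direct
#' hEMT-vs-lEMT phenotypic contrast), else from the trend batch's tau sign,
#' else from the first batch's annotation; provenance is recorded.
#'
#' @param gs1 Character vector, or data.frame with `gene` (+ optional
#'   `direction`): the module-screen batch.
#' @param gs2 Data.frame with `gene`, `direction`: the DE batch.
#' @param gs3 Data.frame with `gene`, `direction`: the trend batch.
#' @param min_membership Minimum batches a gene must appear in (default 2).
#' @return Data.frame: gene, direction, provenance (comma-separated tags).
#' @export
intersect_signatures <- function(gs1, gs2, gs3, min_membership = 2) {
  norm <- function(x, tag) {
    if (is.null(x) || (is.data.frame(x) && nrow(x) == 0) || length(x) == 0)
      return(data.frame(gene = character(), direction = character(),
                        tag = character(), stringsAsFactors = FALSE))
    if (is.character(x))
      x <- data.frame(gene = x, direction = NA_character_,
                      stringsAsFactors = FALSE)
    if (!"direction" %in% names(x)) x$direction <- NA_character_
    data.frame(gene = x$gene, direction = x$direction, tag = tag,
               stringsAsFactors = FALSE)
  }
  tabs <- list(norm(gs1, "GeneSet1"), norm(gs2, "GeneSet2"),
               norm(gs3, "GeneSet3"))
  long <- do.call(rbind, tabs)
  if (nrow(long) == 0) stop("all gene sets are empty")
  out <- lapply(unique(long$gene), function(g) {
    rows <- long[long$gene == g, ]
    if (length(unique(rows$tag)) < min_membership) return(NULL)
    dir <- if (any(rows$tag == "GeneSet2")) rows$direction[rows$tag == "GeneSet2"][1]
           else if (any(rows$tag == "GeneSet3")) rows$direction[rows$tag == "GeneSet3"][1]
           else rows$direction[1]
    data.frame(gene = g, direction = dir,
               provenance = paste(sort(unique(rows$tag)), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(gene = character(), direction = character(),
                      provenance = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Genes shared across cancers with a consistent direction
#'
#' A gene becomes a global candidate with direction d when it carries
#' direction d in at least `min_cancers` of the per-cancer signatures;
#' genes qualifying in both directions are excluded as conflicting.
#'
#' @param signatures Named list of per-cancer signature data.frames
#'   (`gene`, `direction`).
#' @param min_cancers Minimum supporting cancers (default 3).
#' @return Data.frame: gene, direction, n_cancers.
#' @export
cross_cancer_shared <- function(signatures, min_cancers = 3) {
  if (length(signatures) < min_cancers)
    stop("need at least min_cancers signature sets")
  long <- do.call(rbind, lapply(signatures, function(s)
    s[, c("gene", "direction")]))
  tally <- stats::aggregate(list(n = rep(1, nrow(long))),
                            by = long[, c("gene", "direction")], FUN = sum)
  hits <- tally[tally$n >= min_cancers, , drop = FALSE]
  conflicted <- hits$gene[duplicated(hits$gene)]
  hits <- hits[!hits$gene %in% conflicted, , drop = FALSE]
  data.frame(gene = hits$gene, direction = hits$direction,
             n_cancers = hits$n, row.names = NULL, stringsAsFactors = FALSE)
}
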