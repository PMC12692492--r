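#' Control-binned gene-set score
#'
#' Per-cell mean log expression of the set genes minus the mean of
#' expression-matched control genes, the module-score construction used for
#' EMT and cancer stem cell scoring in single-cell work. Genes are binned by
#' their mean log expression into `n_bins` equal-frequency bins; each set
#' gene contributes `n_ctrl` control genes drawn from its bin (without
#' replacement when the bin is large enough, with replacement otherwise).
#'
#' @param matrix A [cell_matrix()].
#' @param gene_set Character vector of gene ids; absent genes are dropped
#'   with a warning.
#' @param n_bins Number of expression bins (default 25).
#' @param n_ctrl Control genes per set gene (default 100).
#' @param seed RNG seed for the control draw.
#' @return Data.frame: cell, raw (the score), scaled (min-max to \[0, 1\]).
#' @export
control_binned_score <- function(matrix, gene_set, n_bins = 25,
                                 n_ctrl = 100, seed = 1L) {
  stopifnot(inherits(matrix, "cell_matrix"))
  present <- intersect(gene_set, matrix$gene_ids)
  if (length(present) == 0) stop("no gene of the set is present in the matrix")
  if (length(present) < length(gene_set))
    warning(length(gene_set) - length(present),
            " set gene(s) absent from the matrix; dropped")
  L <- matrix$logcounts
  gmeans <- rowMeans(L)
  # Equal-frequency bins on the gene means (ranks avoid degenerate breaks).
  bin <- ceiling(rank(gmeans, ties.method = "first") /
                   (length(gmeans) / n_bins))
  bin <- pmin(pmax(bin, 1L), n_bins)
  names(bin) <- matrix$gene_ids
  ctrl <- with_seed(seed, {
    unlist(lapply(present, function(g) {
      pool <- matrix$gene_ids[bin == bin[g]]
      sample(pool, n_ctrl, replace = length(pool) < n_ctrl)
    }))
  })
  raw <- colMeans(L[present, , drop = FALSE]) -
    colMeans(L[ctrl, , drop = FALSE])
  data.frame(cell = matrix$cell_ids, raw = unname(raw),
             scaled = scale_01(unname(raw)), stringsAsFactors = FALSE)
}

#' Ranking-based recovery-AUC gene-set score
#'
#' AUCell-style activity: per cell, genes are ranked by expression
#' (descending, ties broken by stable gene order) and the score is the area
#' under the set-recovery curve within the top `top_frac` of the ranking,
#' normalized so that a set occupying the very top ranks scores 1 and a set
#' absent from the top fraction scores 0.
#'
#' @inheritParams control_binned_score
#' @param top_frac Fraction of the ranking considered (default 0.05).
#' @return Data.frame: cell, raw, scaled.
#' @export
ranking_auc_score <- function(matrix, gene_set, top_frac = 0.05) {
  stopifnot(inherits(matrix, "cell_matrix"))
  if (top_frac <= 0 || top_frac > 1) stop("top_frac must be in (0, 1]")
  present <- intersect(gene_set, matrix$gene_ids)
  if (length(present) == 0) stop("no gene of the set is present in the matrix")
  if (length(present) < length(gene_set))
    warning(length(gene_set) - length(present),
            " set gene(s) absent from the matrix; dropped")
  L <- matrix$logcounts
  G <- nrow(L)
  k <- ceiling(top_frac * G)
  is_set <- matrix$gene_ids %in% present
  s <- length(present)
  # Max attainable area: set genes packed into the top ranks.
  auc_max <- if (s >= k) k * (k + 1) / 2 else s * (s + 1) / 2 + (k - s) * s
  raw <- vapply(seq_len(ncol(L)), function(j) {
    ord <- order(-L[, j], seq_len(G))[seq_len(k)]
    sum(cumsum(is_set[ord]))
  }, 0) / auc_max
  data.frame(cell = matrix$cell_ids, raw = raw, scaled = scale_01(raw),
             stringsAsFactors = FALSE)
}

#' Min-max scale a score vector to \[0, 1\]
#'
#' `(x - min) / (max - min)`; a constant vector maps to all zeros. Invariant
#' under positive affine transforms of the input.
#'
#' @param scores Numeric vector.
#' @return Rescaled vector.
#' @export
scale_01 <- function(scores) {
  if (length(scores) == 0) stop("need at least one score")
  minmax(scores)
}

#' Stratify cells into lEMT / mEMT / hEMT by score quantiles
#'
#' Within each stratification group (typically cancer type), cells below the
#' 40% quantile of the EMT score are lEMT, cells above the 60% quantile are
#' hEMT, and the remainder (including cells exactly at either boundary) are
#' mEMT. Quantiles use linear interpolation (R type 7) so boundaries are
#' reproducible. Groups with fewer than 5 cells are skipped with a warning
#' (subtype NA).
#'
#' @param scores Named per-cell numeric vector (names = cell ids).
#' @param q_low,q_high Quantile thresholds (defaults 0.40 and 0.60).
#' @param group_by Optional per-cell grouping factor aligned with `scores`.
#' @return Data.frame: cell, group, score, subtype.
#' @export
stratify_emt <- function(scores, q_low = 0.40, q_high = 0.60,
                         group_by = NULL) {
  cells <- names(scores) %||% as.character(seq_along(scores))
  group <- if (is.null(group_by)) rep("all", length(scores))
           else as.character(group_by)
  stopifnot(length(group) == length(scores))
  subtype <- rep(NA_character_, length(scores))
  for (g in unique(group)) {
    idx <- which(group == g)
    if (length(idx) < 5) {
      warning("group '", g, "' has fewer than 5 cells; skipped")
      next
    }
    qs <- stats::quantile(scores[idx], c(q_low, q_high), type = 7,
                          names = FALSE)
    subtype[idx] <- ifelse(scores[idx] < qs[1], "lEMT",
                    ifelse(scores[idx] > qs[2], "hEMT", "mEMT"))
  }
  data.frame(cell = cells, group = group, score = unname(scores),
             subtype = subtype, stringsAsFactors = FALSE)
}
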