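#' CNV profile container
#'
#' Cells-by-features matrix of inferred copy-number scores with neutral
#' value 1 (the convention of inferCNV-style pipelines: amplification > 1,
#' deletion < 1). Features are assumed genomically ordered.
#'
#' @param scores Numeric cells x features matrix with finite, positive
#'   entries.
#' @return Object of class `cnv_profile` with `scores`, `cell_ids`,
#'   `feature_ids`.
#' @export
cnv_profile <- function(scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) == 0 || ncol(scores) == 0) stop("empty CNV profile")
  cell_ids <- rownames(scores) %||% sprintf("cell%05d", seq_len(nrow(scores)))
  feature_ids <- colnames(scores) %||% sprintf("feat%04d", seq_len(ncol(scores)))
  dimnames(scores) <- list(cell_ids, feature_ids)
  structure(list(scores = scores, cell_ids = cell_ids,
                 feature_ids = feature_ids),
            class = "cnv_profile")
}

#' Per-cell CNV Deviation
#'
#' Quantifies how far a cell's copy-number profile departs from the neutral
#' state: the mean squared deviation of its scores from 1,
#' `deviation_j = (1/n) * sum_i (score_ij - 1)^2` over the n features.
#' With `sqrt = TRUE` the root of that quantity (an RMS deviation) is
#' returned instead, for sensitivity analysis; the squared form is the
#' default and is the scale on which the 0.002 calling threshold lives.
#'
#' @param profile A [cnv_profile()].
#' @param sqrt Return the RMS instead of the mean square.
#' @return Named per-cell deviation vector (>= 0; 0 iff all scores are 1).
#' @export
compute_cnv_deviation <- function(profile, sqrt = FALSE) {
  stopifnot(inherits(profile, "cnv_profile"))
  bad <- !is.finite(profile$scores)
  if (any(bad)) {
    cells <- unique(profile$cell_ids[which(bad, arr.ind = TRUE)[, 1]])
    stop("non-finite CNV scores for cells: ",
         paste(utils::head(cells, 5), collapse = ", "),
         if (length(cells) > 5) sprintf(" (+%d more)", length(cells) - 5))
  }
  dev <- rowMeans((profile$scores - 1)^2)
  if (sqrt) dev <- base::sqrt(dev)
  dev
}

#' Reference CNV curve from the highest-deviation cells
#'
#' The feature-wise mean score over the top `top_frac` of cells by CNV
#' Deviation — the "most aberrant" consensus profile that genuinely
#' malignant cells should correlate with. Ties at the cutoff are broken by
#' stable cell order.
#'
#' @param profile A [cnv_profile()].
#' @param top_frac Fraction of cells defining the reference (default 0.05).
#' @param deviation Optional precomputed deviations (recomputed otherwise).
#' @return Named per-feature mean vector.
#' @export
build_reference_curve <- function(profile, top_frac = 0.05, deviation = NULL) {
  stopifnot(inherits(profile, "cnv_profile"))
  if (top_frac <= 0 || top_frac > 1) stop("top_frac must be in (0, 1]")
  dev <- deviation %||% compute_cnv_deviation(profile)
  n_top <- max(1L, ceiling(top_frac * nrow(profile$scores)))
  top <- order(-dev, seq_along(dev))[seq_len(n_top)]
  colMeans(profile$scores[top, , drop = FALSE])
}

#' Correlate each cell's CNV profile to the reference curve
#'
#' Pearson correlation between a cell's per-feature score vector and the
#' reference curve. Cells (or a curve) with zero variance have no defined
#' correlation and are returned as NA; downstream classification treats NA
#' as below any positive correlation threshold.
#'
#' @param profile A [cnv_profile()].
#' @param curve Per-feature reference vector from [build_reference_curve()].
#' @return Named per-cell correlation vector in \[-1, 1\] (or NA).
#' @export
correlate_to_reference <- function(profile, curve) {
  stopifnot(inherits(profile, "cnv_profile"))
  if (length(curve) != ncol(profile$scores))
    stop("curve length (", length(curve), ") != feature count (",
         ncol(profile$scores), ")")
  if (stats::sd(curve) == 0)
    return(stats::setNames(rep(NA_real_, nrow(profile$scores)),
                           profile$cell_ids))
  # zero-variance cells warn inside cor(); they are set to NA just below
  cc <- suppressWarnings(stats::cor(t(profile$scores), curve)[, 1])
  sds <- apply(profile$scores, 1, stats::sd)
  cc[sds == 0] <- NA_real_
  stats::setNames(cc, profile$cell_ids)
}

#' Two-threshold malignancy call
#'
#' Cells with deviation > `dev_thr` AND correlation > `cor_thr` are
#' Malignant; cells with deviation < `dev_thr` AND correlation < `cor_thr`
#' are NotMalignant; everything else (including exact threshold equality,
#' since the rule uses strict inequalities) is Other. Undefined correlations
#' count as below the threshold. When `cell_type` is given, only cells
#' annotated with `eligible_type` can be labelled Malignant; a
#' malignant-looking cell of another type falls to Other.
#'
#' @param deviation,correlation Aligned per-cell vectors.
#' @param dev_thr,cor_thr Calling thresholds (defaults 0.002 and 0.1).
#' @param cell_type Optional per-cell type annotation.
#' @param eligible_type Type eligible for the Malignant label.
#' @return Data.frame: cell, deviation, correlation, label.
#' @export
classify_malignancy <- function(deviation, correlation,
                                dev_thr = 0.002, cor_thr = 0.1,
                                cell_type = NULL,
                                eligible_type = "Epithelial") {
  if (length(deviation) != length(correlation))
    stop("deviation and correlation must be aligned")
  r <- ifelse(is.na(correlation), -Inf, correlation)
  label <- ifelse(deviation > dev_thr & r > cor_thr, "Malignant",
           ifelse(deviation < dev_thr & r < cor_thr, "NotMalignant", "Other"))
  if (!is.null(cell_type)) {
    stopifnot(length(cell_type) == length(deviation))
    label[label == "Malignant" & cell_type != eligible_type] <- "Other"
  }
  data.frame(cell = names(deviation) %||% seq_along(deviation),
             deviation = unname(deviation),
             correlation = unname(correlation),
             label = label, row.names = NULL, stringsAsFactors = FALSE)
}

#' Full malignancy-calling pipeline
#'
#' CNV Deviation, top-cell reference curve, per-cell correlation, and the
#' two-threshold call, in one step.
#'
#' @inheritParams classify_malignancy
#' @inheritParams build_reference_curve
#' @param profile A [cnv_profile()].
#' @return Data.frame as in [classify_malignancy()].
#' @export
call_malignancy <- function(profile, dev_thr = 0.002, cor_thr = 0.1,
                            top_frac = 0.05, cell_type = NULL,
                            eligible_type = "Epithelial") {
  dev <- compute_cnv_deviation(profile)
  curve <- build_reference_curve(profile, top_frac, deviation = dev)
  r <- correlate_to_reference(profile, curve)
  classify_malignancy(dev, r, dev_thr, cor_thr, cell_type, eligible_type)
}
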