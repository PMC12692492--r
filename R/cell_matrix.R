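#' Expression container with counts and log-normalized layers
#'
#' A light genes-by-cells container. When only counts are supplied the log
#' layer is derived as `log1p(counts / libsize * scale_factor)`, the standard
#' library-size normalization.
#'
#' @param counts Non-negative genes x cells matrix, or NULL.
#' @param logcounts Genes x cells matrix on log1p scale, or NULL.
#' @param gene_ids,cell_ids Row/column identifiers; taken from dimnames when
#'   omitted.
#' @param scale_factor Library-size scale used when deriving the log layer.
#' @return An object of class `cell_matrix` with fields `counts`,
#'   `logcounts`, `gene_ids`, `cell_ids`.
#' @export
cell_matrix <- function(counts = NULL, logcounts = NULL,
                        gene_ids = NULL, cell_ids = NULL,
                        scale_factor = 1e4) {
  ref <- if (!is.null(counts)) counts else logcounts
  if (is.null(ref)) stop("provide at least one of counts, logcounts")
  gene_ids <- gene_ids %||% rownames(ref) %||% sprintf("g%05d", seq_len(nrow(ref)))
  cell_ids <- cell_ids %||% colnames(ref) %||% sprintf("c%05d", seq_len(ncol(ref)))
  if (!is.null(counts)) {
    counts <- as.matrix(counts)
    if (any(counts < 0)) stop("counts layer must be non-negative")
    dimnames(counts) <- list(gene_ids, cell_ids)
  }
  if (is.null(logcounts)) {
    lib <- colSums(counts)
    lib[lib == 0] <- 1
    logcounts <- log1p(sweep(counts, 2, lib, "/") * scale_factor)
  } else {
    logcounts <- as.matrix(logcounts)
  }
  dimnames(logcounts) <- list(gene_ids, cell_ids)
  if (!is.null(counts) && !all(dim(counts) == dim(logcounts)))
    stop("counts and logcounts layers must share dimensions")
  structure(list(counts = counts, logcounts = logcounts,
                 gene_ids = gene_ids, cell_ids = cell_ids),
            class = "cell_matrix")
}

#' @method print cell_matrix
#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("cell_matrix: %d genes x %d cells (layers: %s)\n",
              length(x$gene_ids), length(x$cell_ids),
              paste(c("counts", "logcounts")[!c(is.null(x$counts), FALSE)],
                    collapse = ", ")))
  invisible(x)
}

#' @export
dim.cell_matrix <- function(x) c(length(x$gene_ids), length(x$cell_ids))

#' Subset a cell matrix by cell index
#'
#' Column subset keeping both layers and the cell ids aligned.
#'
#' @param x A [cell_matrix()].
#' @param idx Numeric or logical cell index.
#' @return A [cell_matrix()] restricted to the selected cells.
#' @export
subset_cells <- function(x, idx) {
  cell_matrix(counts = if (!is.null(x$counts)) x$counts[, idx, drop = FALSE],
              logcounts = x$logcounts[, idx, drop = FALSE],
              gene_ids = x$gene_ids,
              cell_ids = x$cell_ids[if (is.logical(idx)) which(idx) else idx])
}
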