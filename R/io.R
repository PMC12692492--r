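#' Read a GMT gene-set file
#'
#' GMT is the tab-delimited gene-set exchange format: one set per line,
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description column (recycled).
#' @export
write_gmt <- function(sets, path, description = "emtmet") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a cell matrix as Matrix Market plus sidecars
#'
#' Writes `matrix.mtx`, `genes.tsv` and `barcodes.tsv` (the conventional
#' sparse single-cell exchange layout) for the counts layer.
#'
#' @param x A [cell_matrix()].
#' @param dir Output directory (created if absent).
#' @export
write_cell_matrix <- function(x, dir) {
  stopifnot(inherits(x, "cell_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::Matrix(x$counts, sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(x$gene_ids, file.path(dir, "genes.tsv"))
  writeLines(x$cell_ids, file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a cell matrix written by [write_cell_matrix()]
#'
#' @param dir Directory holding `matrix.mtx`, `genes.tsv`, `barcodes.tsv`.
#' @return A [cell_matrix()] whose log layer is recomputed from counts.
#' @export
read_cell_matrix <- function(dir) {
  counts <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  genes <- readLines(file.path(dir, "genes.tsv"))
  cells <- readLines(file.path(dir, "barcodes.tsv"))
  dimnames(counts) <- list(genes, cells)
  cell_matrix(counts = counts, gene_ids = genes, cell_ids = cells)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}
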