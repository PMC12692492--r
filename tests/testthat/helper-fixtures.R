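# Shared fixtures and small oracles used across test files.

# Scaled-down study world: enough structure for every module, fast to draw.
small_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_genes = 300, n_cells = 600, n_samples = 6,
             n_cancers = 3, emt_set_size = 30, n_programs = 3,
             program_size = 50, n_cnv_features = 400,
             cnv_blocks = list(list(features = 41:80, shift = 0.3),
                               list(features = 201:240, shift = -0.3)),
             ...)
}

jaccard_sets <- function(a, b) length(intersect(a, b)) / length(union(a, b))

f1_score <- function(pred, truth) {
  tp <- sum(pred & truth)
  2 * tp / (2 * tp + sum(pred & !truth) + sum(!pred & truth))
}

# Build a cell_matrix directly from a log-layer matrix.
cm_from_log <- function(L) {
  cell_matrix(logcounts = L,
              gene_ids = rownames(L) %||% sprintf("g%03d", seq_len(nrow(L))),
              cell_ids = colnames(L) %||% sprintf("c%03d", seq_len(ncol(L))))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Adjusted Rand index between two labelings (standard contingency formula).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
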