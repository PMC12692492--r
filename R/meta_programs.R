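#' Multiplicative-update non-negative matrix factorization
#'
#' Lee-Seung Frobenius NMF: `X ~ W %*% H` with `W`, `H >= 0`, updated
#' multiplicatively so the reconstruction error is non-increasing.
#'
#' @param X Non-negative matrix (genes x cells).
#' @param k Factorization rank.
#' @param max_iter Update iterations (default 200).
#' @param seed Seed for the random uniform initialization.
#' @param eps Numerical floor in the update denominators.
#' @return List: `W` (genes x k), `H` (k x cells), `loss` (Frobenius error
#'   trajectory, recorded every 10 iterations).
#' @export
nmf_mu <- function(X, k, max_iter = 200, seed = 1L, eps = 1e-9) {
  X <- as.matrix(X)
  if (any(X < 0)) stop("NMF input must be non-negative")
  if (nrow(X) < 2) stop("need at least 2 genes")
  with_seed(seed, {
    G <- nrow(X); N <- ncol(X)
    sc <- sqrt(mean(X) / k)
    W <- matrix(stats::runif(G * k, 0, 2 * sc), G, k)
    H <- matrix(stats::runif(k * N, 0, 2 * sc), k, N)
    loss <- numeric(0)
    for (it in seq_len(max_iter)) {
      H <- H * (crossprod(W, X)) / (crossprod(W, W %*% H) + eps)
      W <- W * (X %*% t(H)) / (W %*% tcrossprod(H) + eps)
      if (it %% 10 == 0 || it == max_iter)
        loss <- c(loss, sqrt(sum((X - W %*% H)^2)))
    }
    list(W = W, H = H, loss = loss)
  })
}

#' Per-sample NMF with stability-based rank selection
#'
#' Factorizes one sample's non-negative highly-variable-gene submatrix at
#' each rank in `ranks`, `repeats` times per rank, and selects the rank with
#' the highest cophenetic correlation of the repeat-consensus cell
#' clustering (cells assigned to their argmax factor; ties in the criterion
#' go to the smaller rank). Each factor of the winning fit (lowest
#' reconstruction error) yields one gene module: its `top_n` genes by
#' factor weight.
#'
#' @param matrix A [cell_matrix()] restricted to one sample's cells, or a
#'   plain non-negative genes x cells matrix.
#' @param sample Sample label stored in the modules (provenance).
#' @param ranks Candidate ranks (default 4:12).
#' @param repeats NMF restarts per rank (default 10).
#' @param seed Master seed; each (rank, repeat) uses a derived substream.
#' @param top_n Genes per module (default 50).
#' @param n_hvg When non-NULL, restrict to the `n_hvg` most variable genes.
#' @param max_iter Iterations per fit.
#' @return List of gene modules (`sample`, `rank`, `factor`, `genes`,
#'   `weights`), with the chosen rank in `attr(, "rank")` and per-rank
#'   cophenetic scores in `attr(, "cophenetic")`.
#' @export
run_sample_nmf <- function(matrix, sample = "S1", ranks = 4:12, repeats = 10,
                           seed = 1L, top_n = 50, n_hvg = NULL,
                           max_iter = 200) {
  X <- if (inherits(matrix, "cell_matrix")) matrix$logcounts else as.matrix(matrix)
  if (ncol(X) <= 5) stop("sample must have more than 5 cells")
  if (any(X < 0)) stop("NMF input must be non-negative")
  if (!is.null(n_hvg)) {
    v <- apply(X, 1, stats::var)
    X <- X[order(-v)[seq_len(min(n_hvg, nrow(X)))], , drop = FALSE]
  }
  if (nrow(X) < 2) stop("need at least 2 highly variable genes")
  if (is.null(rownames(X))) rownames(X) <- sprintf("g%05d", seq_len(nrow(X)))

  coph <- numeric(length(ranks))
  fits_by_rank <- vector("list", length(ranks))
  N <- ncol(X)
  for (ri in seq_along(ranks)) {
    k <- ranks[ri]
    fits <- lapply(seq_len(repeats), function(rep)
      nmf_mu(X, k, max_iter = max_iter,
             seed = substream(seed, 1000L * ri + rep)))
    consensus <- matrix(0, N, N)
    for (f in fits) {
      cl <- max.col(t(f$H), ties.method = "first")
      consensus <- consensus + outer(cl, cl, "==")
    }
    consensus <- consensus / repeats
    d <- stats::as.dist(1 - consensus)
    coph[ri] <- if (stats::sd(d) == 0) 1 else {
      hc <- stats::hclust(d, method = "average")
      suppressWarnings(stats::cor(stats::cophenetic(hc), d))
    }
    fits_by_rank[[ri]] <- fits
  }
  best_ri <- order(-coph, ranks)[1]
  fits <- fits_by_rank[[best_ri]]
  best_fit <- fits[[which.min(vapply(fits, function(f) utils::tail(f$loss, 1), 0))]]
  k <- ranks[best_ri]
  modules <- lapply(seq_len(k), function(fa) {
    w <- best_fit$W[, fa]
    ord <- order(-w, seq_along(w))[seq_len(min(top_n, length(w)))]
    list(sample = sample, rank = k, factor = fa,
         genes = rownames(X)[ord], weights = unname(w[ord]))
  })
  attr(modules, "rank") <- k
  attr(modules, "cophenetic") <- stats::setNames(coph, ranks)
  modules
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Keep modules recurring across the collection
#'
#' A module is robust if its gene set has Jaccard similarity above
#' `jaccard_min` with at least `min_partners` other modules — the
#' cross-sample recurrence filter that precedes program detection.
#'
#' @param modules List of modules (each with a `genes` element).
#' @param jaccard_min Similarity threshold (default 0.05).
#' @param min_partners Required number of similar partners (default 5).
#' @return The retained sublist.
#' @export
filter_robust_modules <- function(modules, jaccard_min = 0.05,
                                  min_partners = 5) {
  M <- length(modules)
  if (M < min_partners + 1)
    stop("need at least min_partners + 1 modules")
  sets <- lapply(modules, `[[`, "genes")
  partners <- integer(M)
  for (i in seq_len(M)) {
    for (j in seq_len(M)) {
      if (i != j && jaccard(sets[[i]], sets[[j]]) > jaccard_min)
        partners[i] <- partners[i] + 1L
    }
  }
  modules[partners >= min_partners]
}

#' Gene co-occurrence network from module membership
#'
#' Genes are nodes; the edge weight between two genes is the number of
#' modules containing both. Edges supported by fewer than `min_weight`
#' modules are dropped (a pair seen in a single module is not recurrence
#' evidence), and nodes whose weighted degree then falls below `min_degree`
#' (low-connectivity genes) are removed.
#'
#' @param modules List of modules with `genes` elements.
#' @param min_degree Minimum weighted degree kept (default 2).
#' @param min_weight Minimum module support per edge (default 2).
#' @return An [igraph::graph] with integer edge `weight`s and no self-loops.
#' @export
build_cooccurrence_graph <- function(modules, min_degree = 2,
                                     min_weight = 2) {
  if (length(modules) < 2) stop("need at least 2 modules")
  sets <- lapply(modules, `[[`, "genes")
  genes <- sort(unique(unlist(sets)))
  B <- vapply(sets, function(s) genes %in% s, logical(length(genes)))
  C <- tcrossprod(B * 1L)           # co-membership counts
  diag(C) <- 0
  C[C < min_weight] <- 0
  dimnames(C) <- list(genes, genes)
  g <- igraph::graph_from_adjacency_matrix(C, mode = "undirected",
                                           weighted = TRUE)
  repeat {
    deg <- igraph::strength(g)
    drop <- names(deg)[deg < min_degree]
    if (length(drop) == 0) break
    g <- igraph::delete_vertices(g, drop)
  }
  g
}

#' Partition the co-occurrence network into meta-programs
#'
#' Runs map-equation (Infomap) community detection on the weighted gene
#' co-occurrence graph; each non-singleton community becomes one
#' meta-program.
#'
#' @param graph Weighted undirected [igraph::graph].
#' @param seed RNG seed (Infomap's trials draw from R's RNG).
#' @param nb_trials Infomap optimization trials.
#' @return List of programs: `id`, `genes`.
#' @export
detect_programs <- function(graph, seed = 1L, nb_trials = 10) {
  if (igraph::vcount(graph) == 0) stop("empty graph")
  comm <- with_seed(seed,
    igraph::cluster_infomap(graph,
                            e.weights = igraph::E(graph)$weight,
                            nb.trials = nb_trials))
  memb <- igraph::membership(comm)
  split_genes <- split(names(memb), memb)
  split_genes <- split_genes[lengths(split_genes) > 1]  # drop singletons
  split_genes <- split_genes[order(-lengths(split_genes))]
  lapply(seq_along(split_genes), function(i)
    list(id = sprintf("MP%02d", i), genes = sort(unname(split_genes[[i]]))))
}

#' Two-level map equation of a partition
#'
#' Description length (bits) of a random walk on an undirected weighted
#' graph under a two-level coding with the given module membership; lower is
#' better. Used to sanity-check that a detected partition beats the
#' all-singletons code.
#'
#' @param graph Weighted undirected [igraph::graph].
#' @param membership Integer module id per vertex (vertex order).
#' @return The map-equation value in bits.
#' @export
map_equation <- function(graph, membership) {
  w <- igraph::E(graph)$weight %||% rep(1, igraph::ecount(graph))
  tot <- 2 * sum(w)
  p <- igraph::strength(graph, weights = w) / tot    # node visit rates
  ends <- igraph::ends(graph, igraph::E(graph), names = FALSE)
  inter <- membership[ends[, 1]] != membership[ends[, 2]]
  mods <- sort(unique(membership))
  # exit probability of each module: inter-module edge weight incident to it
  q <- vapply(mods, function(m) {
    idx <- inter & (membership[ends[, 1]] == m | membership[ends[, 2]] == m)
    sum(w[idx]) / tot
  }, 0)
  plogp <- function(x) ifelse(x > 0, x * log2(x), 0)
  qt <- sum(q)
  index_H <- if (qt > 0) -sum(plogp(q / qt)) else 0
  module_H <- vapply(seq_along(mods), function(i) {
    pm <- p[membership == mods[i]]
    tot_i <- q[i] + sum(pm)
    if (tot_i == 0) return(0)
    -sum(plogp(c(q[i], pm) / tot_i)) * tot_i
  }, 0)
  qt * index_H + sum(module_H)
}

#' Merge near-duplicate programs across cancers
#'
#' Single-linkage merging: programs whose pairwise Jaccard similarity
#' exceeds `jaccard_merge` are chained into one merged program whose gene
#' list is the union; provenance (contributing program ids) is retained.
#'
#' @param programs List of programs (`id`, `genes`).
#' @param jaccard_merge Merge threshold (default 0.25).
#' @return List of merged programs: `id`, `genes`, `members`.
#' @export
merge_programs <- function(programs, jaccard_merge = 0.25) {
  if (length(programs) == 0) stop("need at least one program")
  n <- length(programs)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (n > 1) {
    pairs <- utils::combn(n, 2)
    hit <- apply(pairs, 2, function(ij)
      jaccard(programs[[ij[1]]]$genes, programs[[ij[2]]]$genes) > jaccard_merge)
    if (any(hit))
      g <- igraph::add_edges(g, as.vector(pairs[, hit, drop = FALSE]))
  }
  comp <- igraph::components(g)$membership
  lapply(sort(unique(comp)), function(cid) {
    members <- programs[comp == cid]
    list(id = sprintf("MP%02d", cid),
         genes = sort(unique(unlist(lapply(members, `[[`, "genes")))),
         members = vapply(members, `[[`, "", "id"))
  })
}

#' Screen co-expression modules against program activities
#'
#' A module is selected when the Pearson correlation between its per-cell
#' score and any metastasis-labelled program's per-cell score satisfies
#' `|r| > r_min` with two-sided `p < p_max` (both strict). The union of the
#' kept modules' genes forms the first metastasis signature batch.
#'
#' @param module_scores Cells x modules numeric matrix (module score =
#'   mean scaled expression of the module's genes).
#' @param program_scores Cells x programs numeric matrix, aligned on cells.
#' @param r_min,p_max Selection thresholds (defaults 0.2 and 0.05).
#' @return Character vector of kept module column names.
#' @export
screen_modules_by_program <- function(module_scores, program_scores,
                                      r_min = 0.2, p_max = 0.05) {
  module_scores <- as.matrix(module_scores)
  program_scores <- as.matrix(program_scores)
  if (nrow(module_scores) != nrow(program_scores))
    stop("module and program scores must be aligned on cells")
  if (nrow(module_scores) < 3) stop("need at least 3 cells")
  keep <- vapply(seq_len(ncol(module_scores)), function(m) {
    any(vapply(seq_len(ncol(program_scores)), function(p) {
      ct <- stats::cor.test(module_scores[, m], program_scores[, p])
      abs(ct$estimate) > r_min && ct$p.value < p_max
    }, TRUE))
  }, TRUE)
  colnames(module_scores)[keep] %||% which(keep)
}

#' Full meta-program discovery pipeline
#'
#' Per-sample NMF with stability rank selection, gene-recurrence filtering
#' (genes appearing in at least `min_recurrence` modules), the Jaccard
#' robust-module filter, the gene co-occurrence network, Infomap
#' partitioning, and cross-run merging.
#'
#' @param matrix A [cell_matrix()].
#' @param samples Per-cell sample labels aligned with the matrix columns.
#' @inheritParams run_sample_nmf
#' @param min_recurrence Minimum number of modules a gene must recur in.
#' @inheritParams filter_robust_modules
#' @inheritParams build_cooccurrence_graph
#' @param jaccard_merge Merge threshold for near-duplicate programs.
#' @return List: `programs` (merged meta-programs), `modules` (robust
#'   modules), `graph` (co-occurrence network).
#' @export
discover_meta_programs <- function(matrix, samples, ranks = 4:12,
                                   repeats = 10, seed = 1L, top_n = 50,
                                   n_hvg = 150, max_iter = 200,
                                   min_recurrence = 2, jaccard_min = 0.05,
                                   min_partners = 5, min_degree = 2,
                                   min_weight = 2, jaccard_merge = 0.25) {
  stopifnot(inherits(matrix, "cell_matrix"),
            length(samples) == length(matrix$cell_ids))
  modules <- list()
  for (s in unique(samples)) {
    idx <- which(samples == s)
    if (length(idx) <= 5) next
    sub <- subset_cells(matrix, idx)
    modules <- c(modules,
                 run_sample_nmf(sub, sample = s, ranks = ranks,
                                repeats = repeats,
                                seed = substream(seed, match(s, unique(samples))),
                                top_n = top_n, n_hvg = n_hvg,
                                max_iter = max_iter))
  }
  if (length(modules) == 0) stop("no sample had more than 5 cells")
  counts <- table(unlist(lapply(modules, `[[`, "genes")))
  stable <- names(counts)[counts >= min_recurrence]
  modules <- lapply(modules, function(m) {
    m$genes <- intersect(m$genes, stable); m
  })
  modules <- modules[lengths(lapply(modules, `[[`, "genes")) > 0]
  modules <- filter_robust_modules(modules, jaccard_min, min_partners)
  graph <- build_cooccurrence_graph(modules, min_degree, min_weight)
  programs <- detect_programs(graph, seed = substream(seed, 999L))
  programs <- merge_programs(programs, jaccard_merge)
  list(programs = programs, modules = modules, graph = graph)
}
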