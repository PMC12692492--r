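make_modules <- function(sets, sample = "S1") {
  lapply(seq_along(sets), function(i)
    list(sample = sample, rank = length(sets), factor = i,
         genes = sets[[i]], weights = rep(1, length(sets[[i]]))))
}

test_that("multiplicative updates factorize exactly and never increase loss", {
  set.seed(1)
  w <- abs(rnorm(30)); h <- abs(rnorm(20))
  X <- outer(w, h)                       # rank-1 non-negative matrix
  fit <- nmf_mu(X, 1, max_iter = 500, seed = 2)
  expect_lt(tail(fit$loss, 1) / sqrt(sum(X^2)), 1e-3)
  expect_true(all(diff(fit$loss) <= 1e-8))

  set.seed(3)
  X2 <- matrix(abs(rnorm(40 * 25)), 40, 25)
  fit2 <- nmf_mu(X2, 4, max_iter = 300, seed = 4)
  expect_true(all(diff(fit2$loss) <= 1e-8))
  expect_error(nmf_mu(-X2, 2), "non-negative")
})

test_that("stability selection recovers the planted rank on a 3-block matrix", {
  set.seed(5)
  G <- 60; N <- 90
  X <- matrix(abs(rnorm(G * N, sd = 0.3)), G, N)
  for (b in 1:3)
    X[(b - 1) * 20 + 1:20, (b - 1) * 30 + 1:30] <-
      X[(b - 1) * 20 + 1:20, (b - 1) * 30 + 1:30] + 1
  rownames(X) <- sprintf("g%02d", 1:G)
  hits <- vapply(1:10, function(s) {
    mods <- run_sample_nmf(X, ranks = 2:6, repeats = 10, seed = s,
                           top_n = 20, max_iter = 150)
    attr(mods, "rank") == 3
  }, TRUE)
  expect_gte(sum(hits), 8)
})

test_that("robust-module filter matches a brute-force all-pairs oracle", {
  same <- make_modules(replicate(6, letters[1:10], simplify = FALSE))
  expect_length(filter_robust_modules(same), 6)

  sets <- c(replicate(10, letters[1:8], simplify = FALSE),
            list(LETTERS[1:8]))
  mods <- make_modules(sets)
  kept <- filter_robust_modules(mods)
  expect_length(kept, 10)
  expect_false(any(vapply(kept, function(m)
    identical(m$genes, LETTERS[1:8]), TRUE)))

  set.seed(6)
  rand <- make_modules(replicate(12, sample(letters, 8), simplify = FALSE))
  kept2 <- filter_robust_modules(rand, jaccard_min = 0.05, min_partners = 3)
  # O(M^2) oracle
  sets2 <- lapply(rand, `[[`, "genes")
  partners <- vapply(seq_along(sets2), function(i)
    sum(vapply(seq_along(sets2), function(j)
      i != j && jaccard_sets(sets2[[i]], sets2[[j]]) > 0.05, TRUE)), 0L)
  expect_equal(length(kept2), sum(partners >= 3))
  # output never grows under re-application
  if (length(kept2) >= 4)
    expect_lte(length(filter_robust_modules(kept2, min_partners = 3)),
               length(kept2))
})

test_that("co-occurrence graph counts shared module membership", {
  mods <- make_modules(list(c("a", "b", "c"), c("x", "y", "z")))
  g <- build_cooccurrence_graph(mods, min_degree = 0, min_weight = 1)
  expect_equal(igraph::ecount(g), 6)  # two within-module triangles
  expect_equal(igraph::distances(g)["a", "x"], Inf)

  mods2 <- make_modules(list(c("a", "b"), c("a", "b"), c("a", "b", "c")))
  g2 <- build_cooccurrence_graph(mods2, min_degree = 0, min_weight = 1)
  eid <- igraph::get_edge_ids(g2, c("a", "b"))
  expect_equal(igraph::E(g2)$weight[eid], 3)
  # hand-computed weighted degrees: a-b 3, a-c 1, b-c 1
  expect_equal(sort(igraph::strength(g2)), sort(c(a = 4, b = 4, c = 2)))
  # low-connectivity removal
  g3 <- build_cooccurrence_graph(mods2, min_degree = 3)
  expect_false("c" %in% igraph::V(g3)$name)
})

test_that("infomap partitions cliques and planted blocks correctly", {
  mods <- make_modules(list(letters[1:6], letters[10:15]))
  g <- build_cooccurrence_graph(mods, min_degree = 0, min_weight = 1)
  progs <- detect_programs(g, seed = 1)
  expect_length(progs, 2)
  expect_setequal(progs[[1]]$genes, letters[1:6])
  expect_setequal(progs[[2]]$genes, letters[10:15])

  # planted partition p_in = 0.3, p_out = 0.01, 3 blocks of 40
  set.seed(7)
  n <- 120; blocks <- rep(1:3, each = 40)
  pm <- matrix(0.01, 3, 3); diag(pm) <- 0.3
  adj <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    adj[i, j] <- adj[j, i] <- rbinom(1, 1, pm[blocks[i], blocks[j]])
  dimnames(adj) <- list(sprintf("v%03d", 1:n), sprintf("v%03d", 1:n))
  gp <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                            weighted = TRUE)
  progs2 <- detect_programs(gp, seed = 2)
  memb <- rep(NA_integer_, n); names(memb) <- rownames(adj)
  for (k in seq_along(progs2)) memb[progs2[[k]]$genes] <- k
  ok <- !is.na(memb)
  ari <- adjusted_rand(memb[ok], blocks[ok])
  expect_gte(ari, 0.9)

  # map equation of detected partition beats all-singletons
  full_memb <- memb; full_memb[is.na(full_memb)] <-
    max(memb, na.rm = TRUE) + seq_len(sum(is.na(full_memb)))
  L_det <- map_equation(gp, full_memb[igraph::V(gp)$name])
  L_sing <- map_equation(gp, seq_len(n))
  expect_lte(L_det, L_sing)
})

test_that("program merging is single-linkage on Jaccard", {
  p <- function(id, genes) list(id = id, genes = genes)
  twice <- merge_programs(list(p("A", letters[1:5]), p("B", letters[1:5])))
  expect_length(twice, 1)

  disjoint <- merge_programs(list(p("A", letters[1:5]), p("B", letters[10:14])),
                             jaccard_merge = 0.25)
  expect_length(disjoint, 2)

  # chain A~B, B~C, A!~C still merges into one via transitivity
  chain <- merge_programs(list(p("A", letters[1:6]),
                               p("B", letters[4:9]),
                               p("C", letters[7:12])),
                          jaccard_merge = 0.25)
  expect_length(chain, 1)
  expect_setequal(chain[[1]]$genes, letters[1:12])
  expect_setequal(chain[[1]]$members, c("A", "B", "C"))
})

test_that("module screening applies both strict thresholds", {
  set.seed(8)
  n <- 200
  prog <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "met_program"))
  mods <- cbind(identical_mod = prog[, 1],
                noise_mod = rnorm(n))
  kept <- screen_modules_by_program(mods, prog)
  expect_true("identical_mod" %in% kept)
  expect_false("noise_mod" %in% kept)

  # r just under the threshold is rejected even when p is tiny
  x <- rnorm(5000)
  e <- as.numeric(scale(residuals(lm(rnorm(5000) ~ x))))
  y <- 0.19 * as.numeric(scale(x)) + sqrt(1 - 0.19^2) * e
  expect_equal(cor(x, y), 0.19, tolerance = 1e-10)
  expect_lt(cor.test(x, y)$p.value, 0.05)
  expect_length(screen_modules_by_program(cbind(m = x), cbind(p = y)), 0)
  expect_error(screen_modules_by_program(cbind(m = 1:2), cbind(p = 1:2)),
               "3 cells")
})

test_that("independent scores pass the joint screen at about the null rate", {
  set.seed(9)
  n <- 1000
  hits <- vapply(1:400, function(i)
    length(screen_modules_by_program(cbind(m = rnorm(n)),
                                     cbind(p = rnorm(n)))) > 0, TRUE)
  # joint rule |r| > 0.2 AND p < 0.05 at n = 1000: |r| > 0.2 dominates and
  # is essentially never met under the null, so the rate is ~ 0
  expect_lte(mean(hits), 0.01)
})

test_that("the full chain recovers planted programs across samples", {
  cfg <- small_config(seed = 21)
  sc <- gen_single_cell(cfg)
  res <- discover_meta_programs(sc$matrix, sc$meta$sample, ranks = 4:8,
                                repeats = 5, seed = 1, n_hvg = 150,
                                max_iter = 100)
  truth <- split(names(sc$truth$program_membership),
                 sc$truth$program_membership)
  expect_gte(length(res$programs), 3)
  best <- vapply(truth, function(tp)
    max(vapply(res$programs, function(p) jaccard_sets(p$genes, tp), 0)), 0)
  expect_true(all(best >= 0.6))
  # programs are a partition of the clustered genes
  all_genes <- unlist(lapply(res$programs, `[[`, "genes"))
  expect_equal(anyDuplicated(all_genes), 0)
})
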