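test_that("mutual kNN keeps only reciprocal neighbor relations", {
  # 3 equally spaced collinear points, k = 1: the middle point is the
  # nearest neighbor of both ends, so only (1,2) and (2,3) survive
  coords <- matrix(c(0, 1, 2), 3, 1,
                   dimnames = list(paste0("c", 1:3), NULL))
  g <- mutual_knn_graph(coords, 1)
  a <- as.matrix(g$adjacency)
  expect_equal(a, rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)),
               ignore_attr = TRUE)
  # k = n - 1 yields the complete graph
  withr::with_seed(2, {
    r <- matrix(rnorm(12), 6, 2, dimnames = list(paste0("c", 1:6), NULL))
  })
  gc <- mutual_knn_graph(r, 5)
  expect_equal(n_edges(gc), choose(6, 2))
  # duplicate points are always connected
  r[2, ] <- r[1, ]
  gd <- mutual_knn_graph(r, 1)
  expect_equal(as.numeric(gd$adjacency[1, 2]), 1)
  expect_error(mutual_knn_graph(r, 0), "positive")
  expect_error(mutual_knn_graph(r, 6), "smaller")
})

test_that("mutual kNN equals the brute-force oracle on random instances", {
  withr::with_seed(31, {
    for (rep in 1:5) {
      n <- sample(10:60, 1)
      k <- sample.int(n - 1, 1)
      coords <- matrix(rnorm(n * 3), n, 3,
                       dimnames = list(paste0("c", seq_len(n)), NULL))
      g <- suppressMessages(mutual_knn_graph(coords, k))
      expect_equal(unname(as.matrix(g$adjacency)),
                   oracle_mutual_knn(coords, k))
    }
  })
})

test_that("CCA shared space recovers matched cells under row permutation", {
  withr::with_seed(13, {
    m <- matrix(rnorm(20 * 15), 20, 15)
    m[1:10, 1:5] <- m[1:10, 1:5] + 2
  })
  xr <- standardize(feature_matrix(m - min(m), paste0("r", 1:20),
                                   paste0("g", 1:15), "rna"))
  perm <- sample(20)
  xg <- feature_matrix(as.matrix(xr$values)[perm, ], paste0("a", 1:20),
                       paste0("g", 1:15), "gene_activity")
  cc <- cca_shared_space(xr, xg, 5)
  expect_true(all(abs(sqrt(rowSums(cc$rna$coords^2)) - 1) < 1e-12))
  expect_true(all(abs(sqrt(rowSums(cc$gam$coords^2)) - 1) < 1e-12))
  # each RNA cell's nearest ATAC cell in the shared space is its own copy
  d <- as.matrix(dist(rbind(cc$rna$coords, cc$gam$coords)))
  cross <- d[1:20, 21:40]
  nn <- apply(cross, 1, which.min)
  expect_gte(mean(perm[nn] == seq_len(20)), 0.95)
  expect_error(cca_shared_space(xr, xg, 25), "rank")
})

test_that("anchor detection is reciprocal with cosine scores", {
  withr::with_seed(4, {
    u <- matrix(rnorm(15), 5, 3)
  })
  u <- u / sqrt(rowSums(u^2))
  rownames(u) <- paste0("c", 1:5)
  er <- embedding_matrix(u, "cca")
  an <- detect_anchors(er, er, k2 = 1)
  # identical embeddings with k2 = 1: exactly the diagonal pairs
  expect_equal(an$pairs$rna_index, 1:5)
  expect_equal(an$pairs$atac_index, 1:5)
  expect_equal(an$pairs$score, rep(1, 5), tolerance = 1e-12)
  # reciprocity verifiable post hoc: every pair is a mutual cross-kNN pair
  an2 <- detect_anchors(er, er, k2 = 3)
  d <- as.matrix(dist(rbind(u, u)))[1:5, 6:10]
  for (r in seq_len(nrow(an2$pairs))) {
    i <- an2$pairs$rna_index[r]; j <- an2$pairs$atac_index[r]
    expect_lte(d[i, j], sort(d[i, ])[3])
    expect_lte(d[i, j], sort(d[, j])[3])
  }
  # all-neighbors limit: every ATAC cell becomes an anchor
  an3 <- detect_anchors(er, er, k2 = 5)
  expect_equal(an3$atac_anchors, 1:5)
})

test_that("anchors on well-separated synthetic data are pure", {
  ds <- small_dataset()
  hvg <- select_hvg(ds$x_rna, 200)
  xr <- standardize(chromanno:::normalize_log_cp10k(hvg))
  gam <- gene_activity(ds$x_atac, ds$peaks, ds$genes,
                       gene_ids = feature_ids(hvg))
  xg <- standardize(chromanno:::normalize_log_cp10k(gam))
  cc <- cca_shared_space(xr, xg, 15)
  an <- detect_anchors(cc$rna, cc$gam, 15)
  expect_gte(anchor_purity(an, ds$labels_rna, ds$labels_atac), 0.9)
})

test_that("hybrid graph stacks RNA cells and anchors with gene features", {
  # 1 anchor pair and an empty RNA graph -> a single edge
  g_rna <- cell_graph(Matrix::Matrix(0, 2, 2, sparse = TRUE),
                      c("r1", "r2"), c("rna", "rna"))
  xr <- feature_matrix(matrix(1:4 / 10, 2, 2), c("r1", "r2"),
                       c("g1", "g2"), "rna")
  xg <- feature_matrix(matrix(8:1 / 10, 4, 2), paste0("a", 1:4),
                       c("g1", "g2"), "gene_activity")
  anchors <- structure(list(
    pairs = data.frame(rna_index = 2L, atac_index = 3L, score = 1),
    atac_anchors = 3L, k2 = 1L), class = "AnchorSet")
  hy <- build_hybrid_graph(g_rna, anchors, xr, xg)
  expect_equal(length(hy$graph$node_ids), 3L)       # n1 + |A|
  expect_equal(n_edges(hy$graph), 1)
  expect_equal(as.numeric(hy$graph$adjacency[2, 3]), 1)
  expect_identical(hy$graph$node_modality, c("rna", "rna", "atac"))
  expect_equal(unname(hy$features),
               unname(rbind(as.matrix(xr$values), as.matrix(xg$values)[3, ])))
  bad <- anchors; bad$pairs$atac_index <- 9L; bad$atac_anchors <- 9L
  expect_error(build_hybrid_graph(g_rna, bad, xr, xg), "out of range")
})

test_that("merged graph equals hand-constructed block assembly", {
  # toy: n1 = 3, n2 = 4, 2 anchor pairs
  a_rna <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  a_atac <- matrix(0, 4, 4); a_atac[1, 2] <- a_atac[2, 1] <- 1
  a_atac[3, 4] <- a_atac[4, 3] <- 1
  g_rna <- cell_graph(a_rna, paste0("r", 1:3), rep("rna", 3))
  g_atac <- cell_graph(a_atac, paste0("a", 1:4), rep("atac", 4))
  xr <- feature_matrix(matrix(rnorm(6), 3, 2), paste0("r", 1:3),
                       c("g1", "g2"), "rna")
  xg <- feature_matrix(matrix(rnorm(8), 4, 2), paste0("a", 1:4),
                       c("g1", "g2"), "gene_activity")
  anchors <- structure(list(
    pairs = data.frame(rna_index = c(1L, 3L), atac_index = c(2L, 4L),
                       score = c(1, 1)),
    atac_anchors = c(2L, 4L), k2 = 1L), class = "AnchorSet")
  hy <- build_hybrid_graph(g_rna, anchors, xr, xg)
  gm <- build_merged_graph(hy, g_atac)
  oracle <- oracle_merged(a_rna, a_atac,
                          cbind(c(1L, 3L), c(2L, 4L)), 3L, 4L)
  expect_equal(unname(as.matrix(gm$adjacency)), oracle)
  expect_true(Matrix::isSymmetric(gm$adjacency))
  expect_true(all(Matrix::diag(gm$adjacency) == 0))
  # disjoint index ranges: total edges add up
  expect_equal(n_edges(gm), n_edges(g_rna) + n_edges(g_atac) + 2)
  expect_identical(gm$node_modality, c(rep("rna", 3), rep("atac", 4)))
})
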