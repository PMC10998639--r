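counts_fm <- function(m, modality = "rna", prefix = "g") {
  feature_matrix(m, paste0("c", seq_len(nrow(m))),
                 paste0(prefix, seq_len(ncol(m))), modality)
}

test_that("HVG selection ranks by variance of log1p CP10K", {
  withr::with_seed(11, {
    m <- matrix(rpois(20, 5), 5, 4)
  })
  m[, 2] <- 7  # constant gene can never win
  fm <- counts_fm(m)
  # brute-force oracle on the 20 numbers
  ln <- t(apply(m, 1, function(r) log1p(1e4 * r / sum(r))))
  vr <- apply(ln, 2, var)
  top2 <- order(vr, decreasing = TRUE)[1:2]
  sel <- select_hvg(fm, 2)
  expect_identical(feature_ids(sel), paste0("g", top2))
  expect_false("g2" %in% feature_ids(sel))
  # g equal to total genes keeps the full set
  expect_setequal(feature_ids(select_hvg(fm, 4)), feature_ids(fm))
  expect_error(select_hvg(fm, 1), "at least 2")
  expect_error(select_hvg(fm, 5), "exceeds")
})

test_that("standardization uses population sd and zeroes flat features", {
  fm <- counts_fm(cbind(c(1, 1, 1), c(0, 1, 2)))
  z <- standardize(fm)
  expect_equal(as.numeric(z$values[, 1]), c(0, 0, 0))
  fm2 <- counts_fm(cbind(c(0, 2), c(1, 5)))
  z2 <- as.matrix(standardize(fm2)$values)
  expect_equal(z2[, 1], c(-1, 1), ignore_attr = TRUE)   # population sd = 1
  withr::with_seed(3, {
    r <- counts_fm(matrix(rpois(60, 4), 6, 10))
  })
  zr <- standardize(r)
  expect_true(all(abs(Matrix::colSums(zr$values) / 6) < 1e-12))
  # idempotence: standardizing a standardized matrix changes nothing
  expect_equal(as.matrix(standardize(zr)$values), as.matrix(zr$values),
               tolerance = 1e-10)
})

test_that("TF-IDF follows the log1p(scale * TF * IDF) formula", {
  # single cell, single nonzero peak: tf = 1, idf = 1 / (1 + 1)
  fm <- counts_fm(matrix(c(3, 0), 1, 2), "atac", "p")
  tf <- tfidf(fm)
  expect_equal(tf$values[1, 1], log1p(1e4 * 1 * (1 / 2)))
  expect_equal(tf$values[1, 2], 0)
  # row scaling invariance: doubling one cell's counts changes nothing
  withr::with_seed(5, {
    m <- matrix(rbinom(40, 2, 0.4), 4, 10)
  })
  m[1, 1] <- 1  # ensure no zero cells
  m2 <- m
  m2[2, ] <- 2 * m2[2, ]
  if (any(rowSums(m) == 0)) m[rowSums(m) == 0, 1] <- 1
  m2[rowSums(m2) == 0, 1] <- 2
  t1 <- tfidf(counts_fm(m, "atac", "p"))
  t2 <- tfidf(counts_fm(m2, "atac", "p"))
  expect_equal(as.matrix(t1$values)[2, ], as.matrix(t2$values)[2, ])
  # all-zero cells dropped with warning; all-zero peak column stays zero
  mz <- rbind(m, 0)
  expect_warning(tz <- tfidf(counts_fm(mz, "atac", "p")), "all-zero cell")
  expect_equal(nrow(tz$values), nrow(m))
})

test_that("gene activity matches a brute-force interval oracle", {
  withr::with_seed(21, {
    npk <- 100; ng <- 20
    gstart <- sort(sample.int(200000, ng))
    genes <- gene_table(paste0("g", seq_len(ng)), "chr1", gstart,
                        gstart + sample(500:3000, ng, replace = TRUE),
                        sample(c("+", "-"), ng, replace = TRUE))
    pstart <- sample.int(210000, npk)
    peaks <- peak_table("chr1", pstart, pstart + 300,
                        paste0("p", seq_len(npk)))
    counts <- matrix(rpois(5 * npk, 0.5), 5, npk)
    fm <- feature_matrix(counts, paste0("c", 1:5), peaks$peak_id, "atac")
  })
  act <- gene_activity(fm, peaks, genes, upstream = 2000)
  oracle <- oracle_gene_activity(counts, peaks, genes, upstream = 2000)
  expect_equal(unname(as.matrix(act$values)), oracle)
})

test_that("gene activity handles containment, strand and absent genes", {
  genes <- gene_table(c("gA", "gB"), "chr1", c(500, 0), c(3000, 1000),
                      c("+", "-"))
  peaks <- peak_table("chr1", c(1200, 950), c(1400, 1050), c("p1", "p2"))
  counts <- matrix(c(3, 2), 1, 2)
  fm <- feature_matrix(counts, "c1", c("p1", "p2"), "atac")
  act <- gene_activity(fm, peaks, genes, upstream = 100)
  # p1 fully inside gA body (count 3); p2 overlaps gA body too (count 2)
  expect_equal(act$values[1, "gA"], 5)
  # gB is - strand: 5' extension is past its end, window [0, 1100);
  # p2 [950,1050) overlaps body and extension but is counted once, and
  # p1 [1200,1400) misses the window entirely
  expect_equal(act$values[1, "gB"], 2)
  expect_warning(
    act2 <- gene_activity(fm, peaks, genes, gene_ids = c("gA", "gMissing")),
    "absent")
  expect_equal(act2$values[1, "gMissing"], 0)
  # zero-count matrix gives zero activity
  fm0 <- feature_matrix(matrix(0, 1, 2), "c1", c("p1", "p2"), "atac")
  expect_equal(sum(gene_activity(fm0, peaks, genes)$values), 0)
})

test_that("PCA embedding matches an eigen-decomposition oracle", {
  withr::with_seed(8, {
    m <- matrix(rnorm(40), 10, 4)
  })
  m[1:5, 1] <- m[1:5, 1] + 6   # two clusters along one feature
  fm <- counts_fm(m)
  z <- standardize(fm)
  emb <- pca_embed(z, 3)
  # oracle: eigen-decomposition of the covariance of the standardized data
  zm <- as.matrix(z$values)
  eg <- eigen(crossprod(zm), symmetric = TRUE)
  scores <- zm %*% eg$vectors[, 1:3]
  expect_equal(abs(unname(emb$coords)), abs(unname(scores)), tolerance = 1e-8)
  # PC1 separates the clusters
  lab <- rep(c("a", "b"), each = 5)
  expect_gt(silhouette_scores(matrix(emb$coords[, 1]), lab)$overall, 0)
  expect_error(pca_embed(z, 4), "min")
})

test_that("PCA gives duplicate cells identical coordinates", {
  withr::with_seed(9, {
    m <- matrix(rpois(50, 6), 10, 5)
  })
  m[2, ] <- m[1, ]
  emb <- pca_embed(standardize(counts_fm(m)), 3)
  expect_equal(emb$coords[1, ], emb$coords[2, ])
})

test_that("LSI component scores are orthogonal and first tracks depth", {
  ds <- small_dataset()
  tf <- tfidf(ds$x_atac)
  emb <- lsi_embed(tf, 10, drop_first = FALSE)
  ztz <- crossprod(emb$coords)
  off <- ztz - diag(diag(ztz))
  expect_lt(max(abs(off)) / max(diag(ztz)), 1e-6)
  depth <- log(Matrix::rowSums(ds$x_atac$values))
  cors <- abs(cor(emb$coords, depth))
  expect_identical(which.max(cors), 1L)   # motivates drop_first
  dropped <- lsi_embed(tf, 10, drop_first = TRUE)
  expect_equal(ncol(dropped$coords), 9L)
  expect_equal(unname(dropped$coords), unname(emb$coords[, -1]),
               tolerance = 1e-8)
})

test_that("LSI reconstructs a rank-2 toy exactly and checks rank", {
  u <- cbind(c(1, 2, 3, 4), c(0, 1, -1, 2))
  v <- cbind(c(1, 0, 1), c(0.5, 1, 0))
  m <- u %*% t(v)
  m <- m - min(m)           # non-negative
  fm <- counts_fm(m, "atac", "p")
  emb <- lsi_embed(fm, 2, drop_first = FALSE)
  # scores x loadings reproduce the matrix: check via projection residual
  gram <- tcrossprod(m)
  eg <- eigen(gram, symmetric = TRUE)
  expect_lt(sum(eg$values[-(1:3)]), 1e-8 * sum(eg$values))
  expect_error(lsi_embed(fm, 4, drop_first = FALSE), "rank")
})
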