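test_that("adjacency normalization has the GCN closed forms", {
  empty <- Matrix::Matrix(0, 3, 3, sparse = TRUE)
  expect_equal(as.matrix(normalize_adjacency(empty)), diag(3),
               ignore_attr = TRUE)
  pair <- Matrix::Matrix(rbind(c(0, 1), c(1, 0)), sparse = TRUE)
  ah <- as.matrix(normalize_adjacency(pair))
  expect_equal(ah, matrix(0.5, 2, 2), ignore_attr = TRUE)
  withr::with_seed(6, {
    a <- matrix(rbinom(49, 1, 0.3), 7, 7)
  })
  a <- (a + t(a) > 0) * 1; diag(a) <- 0
  ahat <- normalize_adjacency(Matrix::Matrix(a, sparse = TRUE))
  expect_true(Matrix::isSymmetric(ahat, check.attributes = FALSE))
})

test_that("encoder has closed forms and permutation equivariance", {
  # all-zero features give zero outputs for any weights (no biases)
  w <- chromanno:::init_branch_params(3, 4, 2)
  ahat <- normalize_adjacency(Matrix::Matrix(0, 5, 5, sparse = TRUE))
  enc <- encode(ahat, matrix(0, 5, 3), w)
  expect_equal(enc$mu, matrix(0, 5, 2))
  expect_equal(enc$logsigma, matrix(0, 5, 2))
  # scalar closed form with identity propagation
  w1 <- list(W1 = matrix(0.7), Wmu = matrix(-1.2), Wls = matrix(0.4))
  ident <- Matrix::Diagonal(1)
  e1 <- encode(ident, matrix(2), w1)
  expect_equal(e1$mu[1, 1], max(2 * 0.7, 0) * -1.2)
  expect_equal(e1$logsigma[1, 1], max(2 * 0.7, 0) * 0.4)
  # permuting nodes permutes outputs identically
  withr::with_seed(10, {
    a <- matrix(rbinom(36, 1, 0.4), 6, 6)
    x <- matrix(rnorm(18), 6, 3)
  })
  a <- (a + t(a) > 0) * 1; diag(a) <- 0
  perm <- sample(6)
  ah <- normalize_adjacency(Matrix::Matrix(a, sparse = TRUE))
  ahp <- normalize_adjacency(Matrix::Matrix(a[perm, perm], sparse = TRUE))
  e <- encode(ah, x, w)
  ep <- encode(ahp, x[perm, ], w)
  expect_equal(ep$mu, e$mu[perm, ], tolerance = 1e-12)
})

test_that("reparameterization is deterministic and collapses in eval mode", {
  mu <- matrix(1:6 / 2, 3, 2)
  ls <- matrix(0, 3, 2)
  z1 <- reparameterize(mu, ls, seed = 99)
  z2 <- reparameterize(mu, ls, seed = 99)
  expect_identical(z1, z2)
  # mu = 0, logsigma = 0: Z is the raw normal draw
  n <- withr::with_seed(99, matrix(rnorm(6), 3, 2))
  expect_equal(reparameterize(matrix(0, 3, 2), ls, noise = n), n)
  # evaluation mode: Z = mu
  expect_identical(reparameterize(mu, ls), mu)
  # sigma -> 0 limit
  expect_equal(reparameterize(mu, matrix(-745, 3, 2), noise = n), mu,
               tolerance = 1e-12)
})

test_that("KL loss matches its closed forms and stays non-negative", {
  mu0 <- matrix(0, 4, 2); s1 <- matrix(1, 4, 2)
  expect_equal(kl_loss(mu0, s1, mu0, s1), 0)
  # single element mu = 1, sigma = 1 contributes 1/2 (un-normalized)
  expect_equal(kl_loss(matrix(1), matrix(1), mode = "sum"), 0.5)
  withr::with_seed(14, {
    mu <- matrix(rnorm(8), 4, 2); sg <- matrix(exp(rnorm(8)), 4, 2)
  })
  expect_gte(kl_loss(mu, sg), 0)
  expect_equal(kl_loss(mu, sg, mode = "sum"), oracle_kl(mu, sg, "sum"))
  expect_error(kl_loss(mu, -sg), "positive")
})

test_that("alignment loss is the mean anchor distance and ignores the rest", {
  z_h <- rbind(c(0, 0), c(5, 5), c(3, 4))
  z_a <- rbind(c(0, 0), c(9, 9))
  # one anchor with difference vector (3, 4) -> 5
  expect_equal(alignment_loss(z_h, z_a, hybrid_rows = 3, atac_rows = 1), 5)
  expect_equal(alignment_loss(z_h, z_a, 3, 1, norm = "l1"), 7)
  # identical anchor views -> 0
  expect_equal(alignment_loss(z_h, rbind(z_h[3, ], c(1, 1)), 3, 1), 0)
  # non-anchor rows do not matter
  z_h2 <- z_h; z_h2[1, ] <- c(100, -100)
  expect_equal(alignment_loss(z_h2, z_a, 3, 1),
               alignment_loss(z_h, z_a, 3, 1))
  expect_error(alignment_loss(z_h, z_a, integer(), integer()), "empty")
})

test_that("decoder closed forms and symmetry hold", {
  expect_equal(decode(matrix(0, 3, 2)), matrix(0.5, 3, 3))
  z <- rbind(c(1, 0), c(0, 1))
  g <- decode(z)
  expect_equal(diag(g), rep(plogis(1), 2))
  expect_equal(g[1, 2], 0.5)
  withr::with_seed(15, {
    zr <- matrix(rnorm(20), 10, 2)
  })
  gr <- decode(zr)
  expect_equal(gr, t(gr))
  expect_true(all(gr > 0 & gr < 1))
})

test_that("reconstruction loss matches hand computations", {
  g <- matrix(0, 2, 2)
  expect_equal(reconstruction_loss(g, matrix(0.5, 2, 2), mode = "unweighted"),
               log(2))
  # perfect reconstruction is at epsilon level
  gp <- rbind(c(0, 1), c(1, 0))
  expect_lt(reconstruction_loss(gp, gp, mode = "unweighted"), 1e-5)
  # moving entries toward the target strictly reduces the loss
  l1 <- reconstruction_loss(gp, matrix(0.5, 2, 2), mode = "unweighted")
  l2 <- reconstruction_loss(gp, rbind(c(0.4, 0.6), c(0.6, 0.4)),
                            mode = "unweighted")
  expect_lt(l2, l1)
})

test_that("classification loss has closed forms and ignores targets", {
  y <- diag(4)
  perfect <- rbind(diag(4), matrix(0.25, 2, 4))
  expect_lt(classification_loss(perfect, y, 1:4), 1e-6)
  uniform <- matrix(0.25, 6, 4)
  expect_equal(classification_loss(uniform, y, 1:4), log(4))
  # target-cell rows are irrelevant
  pert <- perfect; pert[5:6, ] <- c(1, 0, 0, 0)
  expect_equal(classification_loss(pert, y, 1:4),
               classification_loss(perfect, y, 1:4))
})

test_that("total loss is the lambda-weighted sum", {
  expect_equal(total_loss(1, 2, 3, 4, lambda = 1), 10)
  expect_equal(total_loss(1, 2, 3, 4, lambda = 0), 7)
  expect_error(total_loss(1, NaN, 3, 4), "finite")
})

test_that("the training-loop losses equal the exported definitions", {
  toy <- make_toy_inputs(n1 = 5, n2 = 3, k = 2, d = 4, seed = 77)
  fw <- chromanno:::vgae_forward(toy$params, toy$inp, toy$noise)
  n1 <- toy$dims$n1
  ghat <- decode(fw$z_m)
  expect_equal(fw$l_rec, reconstruction_loss(toy$inp$g, ghat, "weighted"),
               tolerance = 1e-8)
  expect_equal(fw$l_kl,
               kl_loss(fw$fh$mu, exp(fw$fh$ls), fw$fa$mu, exp(fw$fa$ls)),
               tolerance = 1e-10)
  expect_equal(fw$l_ali,
               alignment_loss(fw$z_h, fw$z_a, toy$inp$anchor_hybrid_rows,
                              toy$inp$anchor_atac_rows),
               tolerance = 1e-10)
  zhat <- chromanno:::row_softmax(fw$z_m)
  expect_equal(fw$l_cls,
               classification_loss(zhat, toy$inp$y, seq_len(n1)),
               tolerance = 1e-10)
  expect_equal(fw$total,
               total_loss(fw$l_kl, fw$l_rec, fw$l_ali, fw$l_cls, lambda = 1))
})

test_that("training is reproducible and ablation flags behave", {
  toy <- make_toy_inputs(n1 = 6, n2 = 4, k = 2, d = 4)
  ds <- small_dataset(seed = 5, n_types = 3, n = 60, g = 120, p = 400)
  hvg <- select_hvg(ds$x_rna, 100)
  xr <- standardize(chromanno:::normalize_log_cp10k(hvg))
  gam <- gene_activity(ds$x_atac, ds$peaks, ds$genes,
                       gene_ids = feature_ids(hvg))
  xg <- standardize(chromanno:::normalize_log_cp10k(gam))
  pca <- pca_embed(xr, 10)
  g_rna <- suppressMessages(mutual_knn_graph(pca, 8, "rna"))
  tf <- tfidf(ds$x_atac)
  lsi <- lsi_embed(tf, 10)
  g_atac <- suppressMessages(mutual_knn_graph(lsi, 8, "atac"))
  cc <- cca_shared_space(xr, xg, 10)
  an <- detect_anchors(cc$rna, cc$gam, 8)
  hy <- build_hybrid_graph(g_rna, an, xr, xg)
  gm <- build_merged_graph(hy, g_atac)
  lab <- ds$labels_rna$label

  cfg <- vgae_config(epochs = 40, seed = 3)
  f1 <- train_parallel_vgae(hy, g_atac, tf, gm, lab, cfg)
  f2 <- train_parallel_vgae(hy, g_atac, tf, gm, lab, cfg)
  expect_identical(f1$trace, f2$trace)           # bit-reproducible
  expect_identical(f1$params, f2$params)
  # loss decreases over training
  expect_lt(mean(tail(f1$trace$total, 5)), mean(head(f1$trace$total, 5)))

  f3 <- train_parallel_vgae(hy, g_atac, tf, gm, lab,
                            vgae_config(epochs = 5, seed = 3,
                                        no_reconstruction = TRUE))
  expect_true(all(f3$trace$reconstruction == 0))
  f4 <- train_parallel_vgae(hy, g_atac, tf, gm, lab,
                            vgae_config(epochs = 5, seed = 3,
                                        single_layer = TRUE))
  expect_null(f4$params$a$W1)
  pi <- peak_importance(f4)
  expect_equal(dim(pi), c(ncol(tf$values), 3L))
  expect_identical(rownames(pi), feature_ids(tf))
  expect_error(peak_importance(f1), "single-layer")
})

test_that("label prediction applies the argmax and 0.5 rules", {
  zhat <- rbind(c(0.7, 0.2, 0.1), c(0.4, 0.35, 0.25), c(1, 1, 1) / 3)
  colnames(zhat) <- c("A", "B", "C")
  pred <- suppressMessages(predict_labels(zhat))
  expect_identical(pred$predicted_label, c("A", "A", "A"))
  expect_identical(pred$meets_threshold, c(TRUE, FALSE, FALSE))
  expect_message(predict_labels(zhat), "tie")
})
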