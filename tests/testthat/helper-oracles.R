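# Independent naive re-implementations used as oracles. Everything here is
# deliberately written with explicit loops / dense arithmetic, independent
# of the package's vectorized code paths.

# ---- losses ---------------------------------------------------------------

oracle_kl <- function(mu, sigma, mode = "mean") {
  tot <- 0
  for (i in seq_len(nrow(mu))) {
    for (j in seq_len(ncol(mu))) {
      tot <- tot + 0.5 * (mu[i, j]^2 + sigma[i, j]^2 - 1 - 2 * log(sigma[i, j]))
    }
  }
  if (mode == "mean") tot / nrow(mu) else tot
}

oracle_bce <- function(g, ghat, mode = "weighted", eps = 1e-7) {
  n2 <- length(g)
  e <- sum(g)
  pw <- if (mode == "weighted") (n2 - e) / e else 1
  nrm <- if (mode == "weighted") n2 / (2 * (n2 - e)) else 1
  tot <- 0
  for (i in seq_len(nrow(g))) {
    for (j in seq_len(ncol(g))) {
      p <- min(max(ghat[i, j], eps), 1 - eps)
      tot <- tot + pw * g[i, j] * (-log(p)) + (1 - g[i, j]) * (-log(1 - p))
    }
  }
  nrm * tot / n2
}

oracle_alignment <- function(z_h, z_a, hrows, arows, norm = "l2") {
  tot <- 0
  for (t in seq_along(hrows)) {
    d <- z_h[hrows[t], ] - z_a[arows[t], ]
    tot <- tot + if (norm == "l2") sqrt(sum(d^2)) else sum(abs(d))
  }
  tot / length(hrows)
}

oracle_classification <- function(zhat, y, idx) {
  tot <- 0
  for (r in seq_along(idx)) {
    for (f in seq_len(ncol(y))) {
      tot <- tot - y[r, f] * log(max(zhat[idx[r], f], 1e-12))
    }
  }
  tot / nrow(y)
}

# ---- graphs ---------------------------------------------------------------

# Brute-force mutual kNN adjacency: O(n^2) distances; j is a neighbor of i
# iff d(i,j) <= i's k-th smallest neighbor distance (ties included).
oracle_mutual_knn <- function(coords, k) {
  n <- nrow(coords)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) d[i, j] <- sqrt(sum((coords[i, ] - coords[j, ])^2))
  }
  nn <- vector("list", n)
  for (i in seq_len(n)) {
    dv <- d[i, -i]
    kth <- sort(dv)[k]
    nn[[i]] <- setdiff(which(d[i, ] <= kth), i)
  }
  a <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && (j %in% nn[[i]]) && (i %in% nn[[j]])) a[i, j] <- 1
    }
  }
  a
}

# Hand block assembly of the merged graph from its pieces.
oracle_merged <- function(a_rna, a_atac, cross_pairs, n1, n2) {
  n <- n1 + n2
  a <- matrix(0, n, n)
  a[seq_len(n1), seq_len(n1)] <- a_rna
  a[n1 + seq_len(n2), n1 + seq_len(n2)] <- a_atac
  for (r in seq_len(nrow(cross_pairs))) {
    i <- cross_pairs[r, 1]
    j <- n1 + cross_pairs[r, 2]
    a[i, j] <- 1
    a[j, i] <- 1
  }
  a
}

# Brute-force interval-overlap gene activity.
oracle_gene_activity <- function(counts, peaks, genes, upstream) {
  act <- matrix(0, nrow(counts), nrow(genes))
  for (gi in seq_len(nrow(genes))) {
    gs <- if (genes$strand[gi] == "+") genes$start[gi] - upstream else genes$start[gi]
    ge <- if (genes$strand[gi] == "+") genes$end[gi] else genes$end[gi] + upstream
    for (pi in seq_len(nrow(peaks))) {
      if (peaks$chrom[pi] == genes$chrom[gi] &&
          peaks$start[pi] < ge && peaks$end[pi] > gs) {
        act[, gi] <- act[, gi] + counts[, pi]
      }
    }
  }
  act
}

# ---- metrics --------------------------------------------------------------

oracle_accuracy <- function(truth, pred) sum(truth == pred) / length(truth)

oracle_f1 <- function(truth, pred) {
  vocab <- sort(unique(c(truth, pred)))
  f1 <- support <- numeric(length(vocab))
  for (v in seq_along(vocab)) {
    l <- vocab[v]
    tp <- sum(truth == l & pred == l)
    fp <- sum(truth != l & pred == l)
    fn <- sum(truth == l & pred != l)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[v] <- if (p + r > 0) 2 * p * r / (p + r) else 0
    support[v] <- sum(truth == l)
  }
  list(per_label = f1, macro = mean(f1),
       weighted = sum(f1 * support) / sum(support))
}

oracle_nmi <- function(truth, pred) {
  tu <- unique(truth); pu <- unique(pred)
  n <- length(truth)
  mi <- 0
  for (a in tu) {
    for (b in pu) {
      pab <- sum(truth == a & pred == b) / n
      if (pab > 0) {
        mi <- mi + pab * log(pab / ((sum(truth == a) / n) * (sum(pred == b) / n)))
      }
    }
  }
  hx <- -sum(sapply(tu, function(a) {
    p <- sum(truth == a) / n; p * log(p)
  }))
  hy <- -sum(sapply(pu, function(b) {
    p <- sum(pred == b) / n; p * log(p)
  }))
  if (hx == 0 || hy == 0) return(0)
  2 * mi / (hx + hy)
}

oracle_silhouette <- function(coords, labels) {
  n <- nrow(coords)
  d <- as.matrix(dist(coords))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- mean(d[i, setdiff(own, i)])
    b <- min(sapply(setdiff(unique(labels), labels[i]), function(l) {
      mean(d[i, labels == l])
    }))
    s[i] <- (b - a) / max(a, b)
  }
  s
}

# ---- fixtures -------------------------------------------------------------

# Small well-separated paired dataset, memoized per (tag) for reuse across
# test files.
.fixture_cache <- new.env(parent = emptyenv())

small_dataset <- function(seed = 7, n_types = 3, n = 120, g = 200, p = 800) {
  key <- paste("ds", seed, n_types, n, g, p, sep = "_")
  if (is.null(.fixture_cache[[key]])) {
    cfg <- sim_config(n_types = n_types, n_rna = n, n_atac = n,
                      n_genes = g, n_peaks = p)
    .fixture_cache[[key]] <- simulate_paired(cfg, seed = seed)
  }
  .fixture_cache[[key]]
}

# A quick trained fit on a tiny dataset, memoized; used by model,
# reliability and pipeline tests.
small_annotation <- function(epochs = 300, single_layer = FALSE) {
  key <- paste("ann", epochs, single_layer, sep = "_")
  if (is.null(.fixture_cache[[key]])) {
    ds <- small_dataset()
    ann <- suppressMessages(suppressWarnings(annotate_atac(
      ds$x_rna, ds$labels_rna, ds$x_atac, peaks = ds$peaks, genes = ds$genes,
      n_hvg = 200, k1 = 10, k2 = 10,
      config = vgae_config(epochs = epochs, seed = 1,
                           single_layer = single_layer),
      holdout_frac = 0.1, target_labels = ds$labels_atac)))
    .fixture_cache[[key]] <- ann
  }
  .fixture_cache[[key]]
}

# Toy inputs for direct calls into the internal forward/backward pass.
make_toy_inputs <- function(n1 = 4, n2 = 2, k = 2, d = 4, f_h = 3, f_a = 4,
                            seed = 42, kl = "mean", bce = "weighted",
                            align_norm = "l2", lambda = 1,
                            no_alignment = FALSE, no_reconstruction = FALSE,
                            single_layer = FALSE) {
  withr::with_seed(seed, {
    n_anchor <- min(n2, 2L)
    m1 <- n1 + n_anchor
    rand_graph <- function(n) {
      a <- matrix(0, n, n)
      for (i in seq_len(n - 1)) a[i, i + 1] <- a[i + 1, i] <- 1
      a
    }
    a_h <- rand_graph(m1)
    a_a <- rand_graph(n2)
    ahat_h <- as.matrix(chromanno::normalize_adjacency(
      Matrix::Matrix(a_h, sparse = TRUE)))
    ahat_a <- as.matrix(chromanno::normalize_adjacency(
      Matrix::Matrix(a_a, sparse = TRUE)))
    x_h <- matrix(rnorm(m1 * f_h), m1, f_h)
    x_a <- matrix(rnorm(n2 * f_a), n2, f_a)
    n <- n1 + n2
    g <- matrix(0, n, n)
    g[1, 2] <- g[2, 1] <- 1
    g[n1 + 1, 1] <- g[1, n1 + 1] <- 1
    if (n2 > 1) g[n1 + 1, n1 + 2] <- g[n1 + 2, n1 + 1] <- 1
    e <- sum(g)
    y <- matrix(0, n1, k)
    y[cbind(seq_len(n1), rep_len(seq_len(k), n1))] <- 1
    inp <- list(ax_h = ahat_h %*% x_h, ahat_h = ahat_h,
                ax_a = ahat_a %*% x_a, ahat_a = ahat_a,
                g = g, edge_idx = which(g == 1), n_entries = length(g),
                n1 = n1, n2 = n2, y = y,
                anchor_hybrid_rows = n1 + seq_len(n_anchor),
                anchor_atac_rows = seq_len(n_anchor),
                pos_weight = if (bce == "weighted") (n^2 - e) / e else 1,
                bce_norm = if (bce == "weighted") n^2 / (2 * (n^2 - e)) else 1,
                lambda = lambda, kl = kl, bce = bce,
                align_norm = align_norm, no_alignment = no_alignment,
                no_reconstruction = no_reconstruction)
    # random weights everywhere so the gradient check exercises every path
    rw <- function(nin, nout) matrix(rnorm(nin * nout, sd = 0.3), nin, nout)
    params <- if (single_layer) {
      list(h = list(W1 = NULL, Wmu = rw(f_h, k), Wls = rw(f_h, k)),
           a = list(W1 = NULL, Wmu = rw(f_a, k), Wls = rw(f_a, k)))
    } else {
      list(h = list(W1 = rw(f_h, d), Wmu = rw(d, k), Wls = rw(d, k)),
           a = list(W1 = rw(f_a, d), Wmu = rw(d, k), Wls = rw(d, k)))
    }
    noise <- list(h = matrix(rnorm(m1 * k), m1, k),
                  a = matrix(rnorm(n2 * k), n2, k))
    list(inp = inp, params = params, noise = noise,
         dims = list(n1 = n1, n2 = n2, m1 = m1, k = k))
  })
}
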