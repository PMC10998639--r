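# Training loop for the parallel VGAE: full-batch manual backpropagation
# with Adam. The gradients below are derived by hand from the loss
# definitions in model.R; a finite-difference check in the test suite
# verifies them on a small instance.

#' Training configuration for the parallel VGAE
#'
#' @param d hidden-layer width of the two-layer GCN encoders.
#' @param lr Adam learning rate.
#' @param epochs number of full-batch epochs.
#' @param lambda weight of the anchor alignment loss.
#' @param seed seed controlling weight initialization and the
#'   reparameterization noise stream.
#' @param single_layer use one-layer encoders (input mapped directly to the
#'   k-dimensional latent); required for [peak_importance()].
#' @param no_alignment ablation: drop the alignment loss.
#' @param no_reconstruction ablation: drop the graph reconstruction loss.
#' @param bce `"weighted"` (VGAE pos-weight/norm, default) or
#'   `"unweighted"` reconstruction BCE.
#' @param kl `"mean"` (per-node, default) or `"sum"` KL normalization.
#' @param align_norm `"l2"` (Euclidean, default) or `"l1"` alignment norm.
#' @param verbose print a progress line every 50 epochs.
#' @return A list of class `vgae_config`.
#' @export
vgae_config <- function(d = 128L, lr = 1e-4, epochs = 500L, lambda = 1,
                        seed = 1L, single_layer = FALSE,
                        no_alignment = FALSE, no_reconstruction = FALSE,
                        bce = c("weighted", "unweighted"),
                        kl = c("mean", "sum"),
                        align_norm = c("l2", "l1"), verbose = FALSE) {
  structure(list(d = as.integer(d), lr = lr, epochs = as.integer(epochs),
                 lambda = lambda, seed = as.integer(seed),
                 single_layer = single_layer, no_alignment = no_alignment,
                 no_reconstruction = no_reconstruction,
                 bce = match.arg(bce), kl = match.arg(kl),
                 align_norm = match.arg(align_norm), verbose = verbose),
            class = "vgae_config")
}

# ---- internal forward/backward ------------------------------------------

branch_forward <- function(ax, ahat, w) {
  if (is.null(w$W1)) {
    list(mu = as_dense(ax %*% w$Wmu), ls = as_dense(ax %*% w$Wls))
  } else {
    hpre <- as_dense(ax %*% w$W1)
    h <- hpre * (hpre > 0)
    ah <- as_dense(ahat %*% h)
    list(mu = ah %*% w$Wmu, ls = ah %*% w$Wls, hpre = hpre, ah = ah)
  }
}

branch_backward <- function(ax, ahat, w, fw, dmu, dls) {
  if (is.null(w$W1)) {
    list(W1 = NULL,
         Wmu = as_dense(Matrix::crossprod(ax, dmu)),
         Wls = as_dense(Matrix::crossprod(ax, dls)))
  } else {
    dah <- tcrossprod(dmu, w$Wmu) + tcrossprod(dls, w$Wls)
    dh <- as_dense(ahat %*% dah)          # ahat symmetric
    dhpre <- dh * (fw$hpre > 0)
    list(W1 = as_dense(Matrix::crossprod(ax, dhpre)),
         Wmu = as_dense(Matrix::crossprod(fw$ah, dmu)),
         Wls = as_dense(Matrix::crossprod(fw$ah, dls)))
  }
}

# Full forward pass: both branches, reparameterization, merged latent and
# all loss terms. `noise` is NULL for evaluation mode (Z = mu).
vgae_forward <- function(params, inp, noise = NULL) {
  fh <- branch_forward(inp$ax_h, inp$ahat_h, params$h)
  fa <- branch_forward(inp$ax_a, inp$ahat_a, params$a)
  sig_h <- exp(fh$ls); sig_a <- exp(fa$ls)
  z_h <- if (is.null(noise)) fh$mu else fh$mu + sig_h * noise$h
  z_a <- if (is.null(noise)) fa$mu else fa$mu + sig_a * noise$a
  n1 <- inp$n1
  z_m <- rbind(z_h[seq_len(n1), , drop = FALSE], z_a)

  kdiv <- function(mu, sg, ls) 0.5 * sum(mu^2 + sg^2 - 1 - 2 * ls)
  ks_h <- if (inp$kl == "mean") 1 / nrow(fh$mu) else 1
  ks_a <- if (inp$kl == "mean") 1 / nrow(fa$mu) else 1
  l_kl <- ks_h * kdiv(fh$mu, sig_h, fh$ls) + ks_a * kdiv(fa$mu, sig_a, fa$ls)

  # weighted BCE against the merged graph in the stable logits form;
  # G is sparse, so the positive-class terms are corrections at the edge
  # indices on top of one softplus pass over all N^2 entries
  l_rec <- 0; s <- NULL
  if (!inp$no_reconstruction) {
    s <- tcrossprod(z_m)
    sp <- softplus(s)
    se <- s[inp$edge_idx]
    l_rec <- inp$bce_norm *
      (sum(sp) + sum(inp$pos_weight * softplus(-se) - sp[inp$edge_idx])) /
      inp$n_entries
  }

  diff <- z_h[inp$anchor_hybrid_rows, , drop = FALSE] -
    z_a[inp$anchor_atac_rows, , drop = FALSE]
  l_ali <- if (inp$align_norm == "l2") mean(sqrt(rowSums(diff^2)))
           else mean(rowSums(abs(diff)))

  pm <- row_softmax(z_m[seq_len(n1), , drop = FALSE])
  l_cls <- -sum(inp$y * log(pmax(pm, 1e-12))) / n1

  lam <- if (inp$no_alignment) 0 else inp$lambda
  list(fh = fh, fa = fa, sig_h = sig_h, sig_a = sig_a,
       z_h = z_h, z_a = z_a, z_m = z_m, s = s, pm = pm, diff = diff,
       l_kl = l_kl, l_rec = l_rec, l_ali = l_ali, l_cls = l_cls,
       total = l_kl + l_rec + lam * l_ali + l_cls)
}

vgae_backward <- function(params, inp, fw, noise) {
  n1 <- inp$n1; k <- ncol(fw$z_m)
  dz_m <- matrix(0, nrow(fw$z_m), k)

  if (!inp$no_reconstruction) {
    # dL/dS: sigmoid(S) off-edge, -pos_weight * (1 - sigmoid(S)) on edges
    csc <- inp$bce_norm / inp$n_entries
    m <- sigmoid(fw$s)
    m[inp$edge_idx] <- -inp$pos_weight * (1 - m[inp$edge_idx])
    dz_m <- dz_m + (2 * csc) * (m %*% fw$z_m)    # m symmetric
  }
  dz_m[seq_len(n1), ] <- dz_m[seq_len(n1), ] + (fw$pm - inp$y) / n1

  dz_h <- matrix(0, nrow(fw$z_h), k)
  dz_h[seq_len(n1), ] <- dz_m[seq_len(n1), , drop = FALSE]
  dz_a <- dz_m[n1 + seq_len(inp$n2), , drop = FALSE]

  lam <- if (inp$no_alignment) 0 else inp$lambda
  if (lam != 0) {
    na <- nrow(fw$diff)
    if (inp$align_norm == "l2") {
      r <- sqrt(rowSums(fw$diff^2))
      gd <- fw$diff / (pmax(r, 1e-12) * na)
      gd[r < 1e-12, ] <- 0
    } else {
      gd <- sign(fw$diff) / na
    }
    gd <- lam * gd
    dz_h[inp$anchor_hybrid_rows, ] <- dz_h[inp$anchor_hybrid_rows, ] + gd
    dz_a[inp$anchor_atac_rows, ] <- dz_a[inp$anchor_atac_rows, ] - gd
  }

  ks_h <- if (inp$kl == "mean") 1 / nrow(fw$fh$mu) else 1
  ks_a <- if (inp$kl == "mean") 1 / nrow(fw$fa$mu) else 1
  dmu_h <- dz_h + ks_h * fw$fh$mu
  dls_h <- dz_h * noise$h * fw$sig_h + ks_h * (fw$sig_h^2 - 1)
  dmu_a <- dz_a + ks_a * fw$fa$mu
  dls_a <- dz_a * noise$a * fw$sig_a + ks_a * (fw$sig_a^2 - 1)

  list(h = branch_backward(inp$ax_h, inp$ahat_h, params$h, fw$fh, dmu_h, dls_h),
       a = branch_backward(inp$ax_a, inp$ahat_a, params$a, fw$fa, dmu_a, dls_a))
}

adam_init <- function(params) {
  lapply(params, function(br) {
    lapply(br, function(w) if (is.null(w)) NULL else list(m = w * 0, v = w * 0))
  })
}

# ---- training -------------------------------------------------------------

#' Train the parallel VGAE
#'
#' Full-batch Adam training of the two-branch VGAE on the hybrid and ATAC
#' graphs, with the merged reference-target graph as the reconstruction
#' target and the reference labels as supervision. The latent dimension is
#' locked to the number of cell types: the softmax of the merged latent is
#' the label indicator.
#'
#' @param hybrid a `HybridGraph` from [build_hybrid_graph()].
#' @param g_atac the ATAC `CellGraph`.
#' @param x_atac a `FeatureMatrix` of TF-IDF peak features for all target
#'   cells (node order must match `g_atac`).
#' @param g_merged the merged `CellGraph` from [build_merged_graph()].
#' @param labels factor of reference cell labels, aligned with the RNA
#'   nodes of `hybrid`; its levels define the label vocabulary.
#' @param config a [vgae_config()].
#' @param target_labels optional factor of true target labels (same
#'   levels) used only to log per-epoch target accuracy.
#' @return A `vgae_fit`: fitted weights, per-epoch loss/accuracy trace,
#'   evaluation-mode latents (`z_h`, `z_atac`, `z_m`), label indicator
#'   `zhat_m` and bookkeeping (vocabulary, node ids, anchor indices).
#' @export
train_parallel_vgae <- function(hybrid, g_atac, x_atac, g_merged, labels,
                                config = vgae_config(),
                                target_labels = NULL) {
  stopifnot(is(hybrid, "HybridGraph"), is(g_atac, "CellGraph"),
            is(x_atac, "FeatureMatrix"), is(g_merged, "CellGraph"))
  labels <- droplevels(as.factor(labels))
  vocab <- levels(labels)
  k <- length(vocab)
  if (k < 2L) stop_validation("need at least 2 cell types")
  n1 <- sum(hybrid$graph$node_modality == "rna")
  n2 <- length(g_atac$node_ids)
  if (length(labels) != n1) stop_validation("labels must align with RNA nodes")
  if (length(hybrid$anchor_atac_index) == 0L) stop_validation("empty anchor set")

  ahat_h <- normalize_adjacency(hybrid$graph)
  ahat_a <- normalize_adjacency(g_atac)
  x_h <- hybrid$features
  x_a <- x_atac$values
  ax_h <- as_dense(ahat_h %*% x_h)
  ax_a <- ahat_a %*% x_a
  if (Matrix::nnzero(ax_a) / prod(dim(ax_a)) > 0.2) ax_a <- as_dense(ax_a)

  n_nodes <- n1 + n2
  am <- as(as(g_merged$adjacency, "TsparseMatrix"), "generalMatrix")
  edge_idx <- as.numeric(am@i) + 1 + as.numeric(am@j) * n_nodes
  e <- length(edge_idx)
  n_entries <- as.numeric(n_nodes)^2
  if (config$bce == "weighted") {
    if (e == 0) stop_validation("merged graph has no edges")
    pos_weight <- (n_entries - e) / e
    bce_norm <- n_entries / (2 * (n_entries - e))
  } else {
    pos_weight <- 1
    bce_norm <- 1
  }
  y <- matrix(0, n1, k)
  y[cbind(seq_len(n1), as.integer(labels))] <- 1

  inp <- list(ax_h = ax_h, ahat_h = ahat_h, ax_a = ax_a, ahat_a = ahat_a,
              edge_idx = edge_idx, n_entries = n_entries,
              n1 = n1, n2 = n2, y = y,
              anchor_hybrid_rows = n1 + seq_along(hybrid$anchor_atac_index),
              anchor_atac_rows = hybrid$anchor_atac_index,
              pos_weight = pos_weight, bce_norm = bce_norm,
              lambda = config$lambda, kl = config$kl, bce = config$bce,
              align_norm = config$align_norm,
              no_alignment = config$no_alignment,
              no_reconstruction = config$no_reconstruction)

  y_int <- as.integer(labels)
  t_int <- if (!is.null(target_labels)) {
    match(as.character(target_labels), vocab)
  }

  withr::with_seed(config$seed, {
    params <- list(h = init_branch_params(ncol(x_h), config$d, k,
                                          config$single_layer),
                   a = init_branch_params(ncol(x_a), config$d, k,
                                          config$single_layer))
    st <- adam_init(params)
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    trace <- vector("list", config$epochs)
    m1 <- nrow(ahat_h)
    last_good <- params
    for (ep in seq_len(config$epochs)) {
      noise <- list(h = matrix(stats::rnorm(m1 * k), m1, k),
                    a = matrix(stats::rnorm(n2 * k), n2, k))
      fw <- vgae_forward(params, inp, noise)
      if (!is.finite(fw$total)) {
        warning(sprintf("training diverged at epoch %d; returning last good parameters", ep))
        params <- last_good
        trace <- trace[seq_len(ep - 1L)]
        break
      }
      gr <- vgae_backward(params, inp, fw, noise)
      # Adam update over every weight matrix
      for (br in c("h", "a")) {
        for (wn in names(params[[br]])) {
          if (is.null(params[[br]][[wn]])) next
          gw <- gr[[br]][[wn]]
          st[[br]][[wn]]$m <- b1 * st[[br]][[wn]]$m + (1 - b1) * gw
          st[[br]][[wn]]$v <- b2 * st[[br]][[wn]]$v + (1 - b2) * gw^2
          mhat <- st[[br]][[wn]]$m / (1 - b1^ep)
          vhat <- st[[br]][[wn]]$v / (1 - b2^ep)
          params[[br]][[wn]] <- params[[br]][[wn]] -
            config$lr * mhat / (sqrt(vhat) + eps)
        }
      }
      last_good <- params
      # evaluation-mode accuracies from the mean latents
      mu_m_ref <- fw$fh$mu[seq_len(n1), , drop = FALSE]
      ref_acc <- mean(argmax_first(mu_m_ref) == y_int)
      tgt_acc <- if (!is.null(t_int)) {
        mean(argmax_first(fw$fa$mu) == t_int, na.rm = TRUE)
      } else NA_real_
      trace[[ep]] <- c(epoch = ep, kl = fw$l_kl, reconstruction = fw$l_rec,
                       alignment = fw$l_ali, classification = fw$l_cls,
                       total = fw$total, ref_acc = ref_acc,
                       target_acc = tgt_acc)
      if (config$verbose && ep %% 50L == 0L) {
        message(sprintf("epoch %d: total %.4f ref_acc %.3f",
                        ep, fw$total, ref_acc))
      }
    }
    trace <- as.data.frame(do.call(rbind, trace))
    ev <- vgae_forward(params, inp, noise = NULL)
    zhat <- row_softmax(ev$z_m)
    structure(list(params = params, config = config, vocab = vocab,
                   trace = trace, z_h = ev$z_h, z_atac = ev$z_a,
                   z_m = ev$z_m, zhat_m = zhat,
                   n1 = n1, n2 = n2,
                   node_ids = g_merged$node_ids,
                   anchor_atac_index = hybrid$anchor_atac_index,
                   atac_feature_ids = feature_ids(x_atac),
                   atac_feature_means = as.numeric(Matrix::colMeans(x_atac$values)),
                   labels_ref = labels),
              class = "vgae_fit")
  })
}

#' @export
print.vgae_fit <- function(x, ...) {
  cat(sprintf("vgae_fit: %d reference + %d target cells, %d types, %d epochs\n",
              x$n1, x$n2, length(x$vocab), nrow(x$trace)))
  if (nrow(x$trace)) {
    cat(sprintf("  final total loss %.4f, reference accuracy %.3f\n",
                x$trace$total[nrow(x$trace)], x$trace$ref_acc[nrow(x$trace)]))
  }
  invisible(x)
}

#' Predict target-cell labels from the label indicator
#'
#' The predicted label of a target cell is the argmax of its softmax
#' indicator row (ties to the lowest label index); `meets_threshold`
#' records whether the maximum probability reaches 0.5.
#'
#' @param fit a `vgae_fit`, or an N x k indicator matrix.
#' @param target_indices rows holding the target cells (defaults to the
#'   ATAC block of a `vgae_fit`).
#' @param vocab label vocabulary (taken from the fit when available).
#' @return A `data.frame`: `cell_id`, `predicted_label`,
#'   `max_probability`, `meets_threshold`.
#' @export
predict_labels <- function(fit, target_indices = NULL, vocab = NULL) {
  if (is(fit, "vgae_fit")) {
    zhat <- fit$zhat_m
    if (is.null(target_indices)) target_indices <- fit$n1 + seq_len(fit$n2)
    vocab <- vocab %||% fit$vocab
    ids <- fit$node_ids[target_indices]
  } else {
    zhat <- as.matrix(fit)
    if (is.null(target_indices)) target_indices <- seq_len(nrow(zhat))
    vocab <- vocab %||% colnames(zhat) %||% as.character(seq_len(ncol(zhat)))
    ids <- rownames(zhat)[target_indices] %||% as.character(target_indices)
  }
  zt <- zhat[target_indices, , drop = FALSE]
  idx <- argmax_first(zt)
  mx <- zt[cbind(seq_len(nrow(zt)), idx)]
  ties <- rowSums(zt == mx) > 1L
  if (any(ties)) {
    message(sprintf("%d tie(s) at argmax resolved to the lowest label index",
                    sum(ties)))
  }
  data.frame(cell_id = ids, predicted_label = vocab[idx],
             max_probability = as.numeric(mx),
             meets_threshold = mx >= 0.5,
             stringsAsFactors = FALSE)
}

#' Peak importance from a single-layer ATAC encoder
#'
#' With a one-layer ATAC branch the mean-head weight matrix connects each
#' peak directly to each latent/label dimension. The importance of peak
#' `p` for type `f` is the signed weight times the peak's mean TF-IDF
#' value (a weight-times-input attribution): the weight alone
#' over-ranks rare background peaks, whose high IDF gives them large
#' feature values in a handful of cells and hence large chance-association
#' weights, while the input scale restores each peak's actual
#' contribution to the latent coordinate. A large positive score means
#' accessibility of the peak drives cells toward type `f`; large negative
#' scores belong to other types' markers, so rankings use the signed
#' value.
#'
#' @param fit a `vgae_fit` trained with `single_layer = TRUE`.
#' @param scale_by_input multiply weights by mean TF-IDF per peak
#'   (default); `FALSE` returns the raw signed weights.
#' @return A peaks x types matrix of signed scores with peak ids as row
#'   names and the label vocabulary as column names.
#' @export
peak_importance <- function(fit, scale_by_input = TRUE) {
  stopifnot(is(fit, "vgae_fit"))
  if (!fit$config$single_layer) {
    stop_validation("peak importance requires a single-layer ATAC encoder ",
                    "(train with single_layer = TRUE)")
  }
  sc <- fit$params$a$Wmu
  if (scale_by_input) sc <- sc * fit$atac_feature_means
  rownames(sc) <- fit$atac_feature_ids
  colnames(sc) <- fit$vocab
  sc
}

#' Top-ranked peaks per cell type
#'
#' @param importance matrix from [peak_importance()].
#' @param m number of peaks per type.
#' @return Named list of character vectors of peak ids.
#' @export
top_peaks <- function(importance, m = 100L) {
  lapply(stats::setNames(seq_len(ncol(importance)), colnames(importance)),
         function(j) {
           rownames(importance)[order(importance[, j],
                                      decreasing = TRUE)[seq_len(m)]]
         })
}
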