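# End-to-end orchestration: features -> graphs -> anchors -> parallel VGAE
# -> predictions -> reliability, with optional edge holdout for
# link-prediction evaluation.

# Remove held-out merged-graph edges from the hybrid and ATAC graphs so the
# encoders never see them either. `test_pos` is in merged coordinates
# (RNA block first).
prune_graphs_for_holdout <- function(hybrid, g_atac, test_pos) {
  n1 <- sum(hybrid$graph$node_modality == "rna")
  ah <- hybrid$graph$adjacency
  aa <- g_atac$adjacency
  for (r in seq_len(nrow(test_pos))) {
    i <- test_pos[r, 1L]; j <- test_pos[r, 2L]
    if (j <= n1) {                       # RNA-RNA
      ah[i, j] <- 0; ah[j, i] <- 0
    } else if (i > n1) {                 # ATAC-ATAC
      aa[i - n1, j - n1] <- 0; aa[j - n1, i - n1] <- 0
    } else {                             # cross: j is an anchor cell
      hj <- match(j - n1, hybrid$anchor_atac_index)
      if (!is.na(hj)) {
        ah[i, n1 + hj] <- 0; ah[n1 + hj, i] <- 0
      }
    }
  }
  hybrid$graph <- cell_graph(Matrix::drop0(ah), hybrid$graph$node_ids,
                             hybrid$graph$node_modality)
  g_atac <- cell_graph(Matrix::drop0(aa), g_atac$node_ids,
                       g_atac$node_modality)
  list(hybrid = hybrid, g_atac = g_atac)
}

#' Fraction of anchor pairs joining cells of the same true type
#'
#' @param anchors an `AnchorSet`.
#' @param labels_rna,labels_atac `LabelTable`s (or aligned label vectors)
#'   for the two modalities.
#' @return Purity in `[0, 1]`.
#' @export
anchor_purity <- function(anchors, labels_rna, labels_atac) {
  lr <- if (is(labels_rna, "LabelTable")) as.character(labels_rna$label)
        else as.character(labels_rna)
  la <- if (is(labels_atac, "LabelTable")) as.character(labels_atac$label)
        else as.character(labels_atac)
  mean(lr[anchors$pairs$rna_index] == la[anchors$pairs$atac_index])
}

#' Annotate scATAC-seq cells from a labeled scRNA-seq reference
#'
#' Runs the full pipeline: HVG selection and standardization of the
#' reference, gene activity (computed from peaks and a gene annotation
#' unless supplied), TF-IDF/LSI on the target, PCA on the reference,
#' mutual-kNN cell graphs, CCA anchor detection, hybrid and merged graph
#' assembly, parallel VGAE training, label prediction and reliability
#' flagging.
#'
#' @param x_rna `FeatureMatrix` of reference RNA counts.
#' @param labels `LabelTable` (or factor aligned with `x_rna` cells) of
#'   reference cell types.
#' @param x_atac `FeatureMatrix` of target peak counts.
#' @param peaks,genes `PeakTable` and `GeneTable` used to compute gene
#'   activity when `x_gam` is not supplied.
#' @param x_gam optional precomputed gene-activity `FeatureMatrix`
#'   (cells x genes); restricted to the HVG set internally.
#' @param n_hvg number of highly variable genes.
#' @param n_dims embedding dimension for PCA/LSI/CCA.
#' @param k1 neighborhood size of the intra-modality graphs.
#' @param k2 neighborhood size of cross-modality anchor detection.
#' @param upstream bp of 5' extension for gene activity.
#' @param tau edge threshold for reliability scoring.
#' @param config a [vgae_config()].
#' @param holdout_frac fraction of merged-graph edges held out before
#'   training for link-prediction AUC (0 disables).
#' @param target_labels optional `LabelTable` of true target labels; when
#'   given, per-epoch target accuracy is logged and a `MetricReport` is
#'   attached.
#' @param verbose log graph properties and training progress.
#' @return An `atac_annotation` object: `predictions`, `reliability`,
#'   `fit`, `anchors`, `embeddings`, optional `auc` and `metrics`.
#' @export
annotate_atac <- function(x_rna, labels, x_atac, peaks = NULL, genes = NULL,
                          x_gam = NULL, n_hvg = 2000L, n_dims = 30L,
                          k1 = 15L, k2 = 15L, upstream = 2000L, tau = 0.5,
                          config = vgae_config(), holdout_frac = 0,
                          target_labels = NULL, verbose = FALSE) {
  stopifnot(is(x_rna, "FeatureMatrix"), is(x_atac, "FeatureMatrix"))
  if (is(labels, "LabelTable")) {
    ix <- match(cell_ids(x_rna), labels$cell_id)
    if (anyNA(ix)) stop_validation("reference cells missing from label table")
    labels <- labels$label[ix]
  }
  labels <- droplevels(as.factor(labels))
  note <- function(...) if (verbose) message(sprintf(...))

  # gene-level features
  n_hvg <- min(n_hvg, ncol(x_rna$values))
  hvg <- select_hvg(x_rna, n_hvg)
  x_rna_std <- standardize(normalize_log_cp10k(hvg))
  if (is.null(x_gam)) {
    if (is.null(peaks) || is.null(genes)) {
      stop_validation("supply either x_gam or peaks + genes")
    }
    x_gam <- gene_activity(x_atac, peaks, genes, upstream = upstream,
                           gene_ids = feature_ids(hvg))
  } else {
    miss <- setdiff(feature_ids(hvg), feature_ids(x_gam))
    if (length(miss)) {
      stop_validation("precomputed gene activity lacks HVG gene(s): ",
                      paste(utils::head(miss, 3), collapse = ", "))
    }
    x_gam <- feature_matrix(
      x_gam$values[, feature_ids(hvg), drop = FALSE],
      cell_ids(x_gam), feature_ids(hvg), "gene_activity")
  }
  x_gam_std <- standardize(normalize_log_cp10k(x_gam))

  # embeddings and intra-modality graphs
  nd <- min(n_dims, nrow(x_rna$values) - 1L, n_hvg - 1L)
  pca <- pca_embed(x_rna_std, nd)
  g_rna <- mutual_knn_graph(pca, k1, "rna")
  tf <- tfidf(x_atac)
  if (nrow(tf$values) != nrow(x_atac$values)) {
    stop_validation("target cells with zero counts; filter them before annotation")
  }
  lsi <- lsi_embed(tf, nd, drop_first = TRUE)
  g_atac <- mutual_knn_graph(lsi, k1, "atac")
  note("RNA graph: %d edges; ATAC graph: %d edges",
       n_edges(g_rna), n_edges(g_atac))

  # anchors, hybrid and merged graphs
  cca <- cca_shared_space(x_rna_std, x_gam_std, nd)
  n1 <- nrow(x_rna_std$values); n2 <- nrow(x_gam_std$values)
  if (n2 > n1 && k2 < 20L) {
    message("target larger than reference: k2 in [20, 25] is recommended")
  }
  anchors <- detect_anchors(cca$rna, cca$gam, k2)
  hybrid <- build_hybrid_graph(g_rna, anchors, x_rna_std, x_gam_std)
  merged <- build_merged_graph(hybrid, g_atac)
  note("anchors: %d pairs / %d cells; merged graph: %d nodes, %d edges",
       nrow(anchors$pairs), length(anchors$atac_anchors),
       length(merged$node_ids), n_edges(merged))

  ho <- NULL
  if (holdout_frac > 0) {
    ho <- holdout_edges(merged, holdout_frac, seed = config$seed)
    pruned <- prune_graphs_for_holdout(hybrid, g_atac, ho$test_pos)
    hybrid <- pruned$hybrid
    g_atac <- pruned$g_atac
    merged <- ho$train_graph
  }

  tgt <- NULL
  if (!is.null(target_labels)) {
    tgt <- if (is(target_labels, "LabelTable")) {
      target_labels$label[match(cell_ids(x_atac), target_labels$cell_id)]
    } else target_labels
  }
  fit <- train_parallel_vgae(hybrid, g_atac, tf, merged, labels, config,
                             target_labels = tgt)
  predictions <- predict_labels(fit)
  reliability <- assess_reliability(fit, tau)
  predictions$flag <- reliability$report$flag

  out <- list(predictions = predictions, reliability = reliability,
              fit = fit, anchors = anchors,
              embeddings = list(pca = pca, lsi = lsi, cca = cca),
              graphs = list(rna_edges = n_edges(g_rna),
                            atac_edges = n_edges(g_atac),
                            merged_edges = n_edges(merged),
                            n_anchor_cells = length(anchors$atac_anchors)))
  if (!is.null(ho)) {
    out$auc <- link_prediction_auc(fit$z_m, ho$test_pos, ho$test_neg)
    out$holdout <- ho[c("test_pos", "test_neg")]
  }
  if (!is.null(tgt)) {
    out$metrics <- metric_report(as.character(tgt),
                                 predictions$predicted_label,
                                 embedding = lsi)
    keep <- predictions$flag == "confident"
    if (any(keep)) {
      out$metrics_confident <- metric_report(
        as.character(tgt)[keep], predictions$predicted_label[keep])
    }
  }
  structure(out, class = "atac_annotation")
}

#' @export
print.atac_annotation <- function(x, ...) {
  cat(sprintf("atac_annotation: %d target cells, %d types\n",
              nrow(x$predictions), length(x$fit$vocab)))
  cat(sprintf("  confident: %.1f%%; anchors: %d cells\n",
              100 * mean(x$predictions$flag == "confident"),
              x$graphs$n_anchor_cells))
  if (!is.null(x$metrics)) {
    cat(sprintf("  target ACC %.3f, NMI %.3f, weighted F1 %.3f\n",
                x$metrics$acc, x$metrics$nmi, x$metrics$weighted_f1))
  }
  if (!is.null(x$auc)) cat(sprintf("  link-prediction AUC %.3f\n", x$auc))
  invisible(x)
}
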