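# Annotation metrics (accuracy, per-type/macro/weighted F1, NMI,
# silhouette width), link-prediction AUC with edge holdout, and metric
# report serialization.

#' Prediction accuracy
#'
#' @param truth,pred aligned label vectors.
#' @return Fraction of agreeing positions.
#' @export
accuracy_score <- function(truth, pred) {
  if (length(truth) != length(pred)) stop_validation("length mismatch")
  mean(as.character(truth) == as.character(pred))
}

#' Per-label, macro and weighted F1 scores
#'
#' Standard one-vs-rest F1 per label over the union of truth and predicted
#' vocabularies; labels never predicted (or never true) score 0 with a
#' warning. The weighted F1 weights each label by its support in the
#' truth.
#'
#' @param truth,pred aligned label vectors.
#' @return List with `per_label` data.frame, `macro_f1`, `weighted_f1`.
#' @export
f1_scores <- function(truth, pred) {
  if (length(truth) != length(pred)) stop_validation("length mismatch")
  truth <- as.character(truth); pred <- as.character(pred)
  vocab <- sort(unique(c(truth, pred)))
  rows <- lapply(vocab, function(l) {
    tp <- sum(truth == l & pred == l)
    fp <- sum(truth != l & pred == l)
    fn <- sum(truth == l & pred != l)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(label = l, support = sum(truth == l), precision = prec,
               recall = rec, f1 = f1, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  missing_pred <- setdiff(unique(truth), unique(pred))
  if (length(missing_pred)) {
    warning("labels never predicted get F1 = 0: ",
            paste(missing_pred, collapse = ", "))
  }
  list(per_label = tab,
       macro_f1 = mean(tab$f1),
       weighted_f1 = sum(tab$f1 * tab$support) / sum(tab$support))
}

#' Normalized mutual information between two labelings
#'
#' Mutual information of the contingency table normalized by the
#' arithmetic mean of the two entropies (default) or their geometric mean.
#' A degenerate single-class partition yields 0 with a warning.
#'
#' @param truth,pred aligned label vectors.
#' @param normalization `"arithmetic"` or `"geometric"`.
#' @return NMI in `[0, 1]`.
#' @export
nmi_score <- function(truth, pred,
                      normalization = c("arithmetic", "geometric")) {
  normalization <- match.arg(normalization)
  if (length(truth) != length(pred)) stop_validation("length mismatch")
  if (length(truth) == 0L) stop_validation("empty labelings")
  tab <- table(as.character(truth), as.character(pred))
  n <- sum(tab)
  pij <- tab / n
  pi <- rowSums(pij); pj <- colSums(pij)
  hx <- -sum(pi[pi > 0] * log(pi[pi > 0]))
  hy <- -sum(pj[pj > 0] * log(pj[pj > 0]))
  if (hx == 0 || hy == 0) {
    warning("single-class partition; NMI defined as 0")
    return(0)
  }
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi, pj)[nz]))
  if (normalization == "arithmetic") 2 * mi / (hx + hy)
  else mi / sqrt(hx * hy)
}

#' Silhouette widths of an embedding against labels
#'
#' Euclidean silhouette via [cluster::silhouette()]; singleton types get
#' width 0 with a warning. Reports per-cell widths, per-type means and the
#' overall average silhouette width (ASW).
#'
#' @param embedding an `EmbeddingMatrix` or numeric matrix.
#' @param labels label vector aligned with the rows.
#' @return List with `per_cell`, `per_type`, `overall`.
#' @export
silhouette_scores <- function(embedding, labels) {
  coords <- if (is(embedding, "EmbeddingMatrix")) embedding$coords
            else as.matrix(embedding)
  labels <- as.factor(labels)
  if (nrow(coords) != length(labels)) stop_validation("length mismatch")
  if (nlevels(droplevels(labels)) < 2L) {
    stop_validation("silhouette needs at least 2 types")
  }
  sizes <- table(labels)
  if (any(sizes == 1L)) {
    warning("singleton type(s) get silhouette width 0: ",
            paste(names(sizes)[sizes == 1L], collapse = ", "))
  }
  sil <- cluster::silhouette(as.integer(labels), stats::dist(coords))
  per_cell <- sil[, "sil_width"]
  per_type <- vapply(split(per_cell, labels), mean, numeric(1))
  list(per_cell = per_cell, per_type = per_type, overall = mean(per_cell))
}

#' Hold out a fraction of graph edges for link-prediction evaluation
#'
#' Samples `frac` of the undirected edges (and an equal number of
#' non-edges) as a test set and returns the graph with the test edges
#' removed.
#'
#' @param graph a `CellGraph`.
#' @param frac fraction of edges to hold out.
#' @param seed integer seed.
#' @return List with `train_graph`, `test_pos`, `test_neg` (2-column index
#'   matrices, i < j).
#' @export
holdout_edges <- function(graph, frac = 0.1, seed = 1L) {
  stopifnot(is(graph, "CellGraph"))
  a <- as(as(graph$adjacency, "TsparseMatrix"), "generalMatrix")
  up <- which(a@i < a@j)
  edges <- cbind(a@i[up] + 1L, a@j[up] + 1L)
  n <- nrow(a)
  withr::with_seed(as.integer(seed), {
    n_test <- max(1L, round(frac * nrow(edges)))
    sel <- sample.int(nrow(edges), n_test)
    test_pos <- edges[sel, , drop = FALSE]
    # rejection-sample non-edges in the upper triangle
    test_neg <- matrix(0L, 0L, 2L)
    while (nrow(test_neg) < n_test) {
      i <- sample.int(n, 2L * n_test, replace = TRUE)
      j <- sample.int(n, 2L * n_test, replace = TRUE)
      lo <- pmin(i, j); hi <- pmax(i, j)
      ok <- lo < hi & graph$adjacency[cbind(lo, hi)] == 0
      test_neg <- unique(rbind(test_neg, cbind(lo[ok], hi[ok])))
    }
    test_neg <- test_neg[seq_len(n_test), , drop = FALSE]
    adj <- graph$adjacency
    adj[test_pos] <- 0
    adj[test_pos[, 2:1, drop = FALSE]] <- 0
    list(train_graph = cell_graph(Matrix::drop0(adj), graph$node_ids,
                                  graph$node_modality),
         test_pos = test_pos, test_neg = test_neg)
  })
}

#' Rank-based AUC of edge scores
#'
#' @param scores_pos,scores_neg scores of held-out edges and non-edges.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores_pos, scores_neg) {
  np <- length(scores_pos); nn <- length(scores_neg)
  if (np == 0L || nn == 0L) stop_validation("need both positive and negative scores")
  r <- rank(c(scores_pos, scores_neg))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Link-prediction AUC of a merged latent against held-out edges
#'
#' @param z_m merged latent (nodes x k).
#' @param test_pos,test_neg index matrices from [holdout_edges()].
#' @return AUC.
#' @export
link_prediction_auc <- function(z_m, test_pos, test_neg) {
  z_m <- as.matrix(z_m)
  score <- function(ix) sigmoid(rowSums(z_m[ix[, 1L], , drop = FALSE] *
                                        z_m[ix[, 2L], , drop = FALSE]))
  auc_score(score(test_pos), score(test_neg))
}

#' Assemble an annotation metric report
#'
#' @param truth,pred aligned target labels.
#' @param embedding optional embedding for silhouette width.
#' @return A list of class `MetricReport`.
#' @export
metric_report <- function(truth, pred, embedding = NULL) {
  f1 <- f1_scores(truth, pred)
  rep <- list(acc = accuracy_score(truth, pred),
              nmi = nmi_score(truth, pred),
              f1_per_label = f1$per_label,
              macro_f1 = f1$macro_f1,
              weighted_f1 = f1$weighted_f1,
              n = length(truth))
  if (!is.null(embedding)) {
    sw <- silhouette_scores(embedding, truth)
    rep$asw <- sw$overall
    rep$asw_per_type <- sw$per_type
  }
  structure(rep, class = "MetricReport")
}

#' @export
print.MetricReport <- function(x, ...) {
  cat(sprintf("MetricReport (n = %d): ACC %.3f, NMI %.3f, weighted F1 %.3f",
              x$n, x$acc, x$nmi, x$weighted_f1))
  if (!is.null(x$asw)) cat(sprintf(", ASW %.3f", x$asw))
  cat("\n")
  invisible(x)
}

#' Serialize / deserialize a MetricReport as JSON
#'
#' @param x a `MetricReport`.
#' @param path JSON path.
#' @return `path` (write) or a `MetricReport` (read).
#' @export
write_metric_report <- function(x, path) {
  stopifnot(is(x, "MetricReport"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_metric_report
#' @export
read_metric_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$f1_per_label)) {
    x$f1_per_label <- as.data.frame(x$f1_per_label,
                                    stringsAsFactors = FALSE)
  }
  if (!is.null(x$asw_per_type)) x$asw_per_type <- unlist(x$asw_per_type)
  structure(x, class = "MetricReport")
}
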