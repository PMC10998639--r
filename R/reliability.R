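# Prediction reliability on the reconstructed reference-target graph:
# per-target-cell edge density and mean edge weight against every
# reference cell-type group, and the confident/ambiguous flag.

#' Threshold the cross-modality block of the reconstructed graph
#'
#' An edge between reference cell `r` and target cell `c` exists iff the
#' decoded probability reaches `tau` (boundary inclusive). Only the
#' RNA x ATAC block is used; the probabilities of kept edges are retained
#' as weights.
#'
#' @param g_hat_cross dense n1 x n2 matrix of decoded probabilities
#'   (reference rows, target columns).
#' @param tau edge-existence threshold in (0, 1).
#' @return List with logical `edges` and numeric `weights` (both n1 x n2).
#' @export
threshold_reconstructed_graph <- function(g_hat_cross, tau = 0.5) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau >= 1) {
    stop_validation("tau must lie strictly between 0 and 1")
  }
  g_hat_cross <- as_dense(g_hat_cross)
  list(edges = g_hat_cross >= tau, weights = g_hat_cross, tau = tau)
}

#' Edge density and mean edge weight per reference group
#'
#' For target cell `c` and reference group `K`:
#' density `d_c^K = e_c^K / |K|` (fraction of group members connected to
#' `c`) and weight `w_c^K = sum of kept edge probabilities / e_c^K`, with
#' `w_c^K = 0` when `e_c^K = 0`.
#'
#' @param thresholded list from [threshold_reconstructed_graph()].
#' @param reference_groups named list mapping each label to the reference
#'   row indices of that type; the groups must partition the rows.
#' @return List with `density` and `weight` matrices (targets x labels).
#' @export
density_weight <- function(thresholded, reference_groups) {
  ed <- thresholded$edges
  wt <- thresholded$weights
  sizes <- lengths(reference_groups)
  if (any(sizes == 0L)) stop_validation("empty reference group")
  if (sum(sizes) != nrow(ed) ||
      anyDuplicated(unlist(reference_groups))) {
    stop_validation("reference groups must partition the reference cells")
  }
  n2 <- ncol(ed)
  kk <- length(reference_groups)
  dens <- wgt <- matrix(0, n2, kk,
                        dimnames = list(colnames(ed), names(reference_groups)))
  for (j in seq_len(kk)) {
    rows <- reference_groups[[j]]
    e <- colSums(ed[rows, , drop = FALSE])
    s <- colSums((wt * ed)[rows, , drop = FALSE])
    dens[, j] <- e / sizes[j]
    wgt[, j] <- ifelse(e > 0, s / pmax(e, 1), 0)
  }
  list(density = dens, weight = wgt)
}

#' Flag predictions as confident or ambiguous
#'
#' A target cell is confident iff its label-probability vector, its edge
#' density vector and its edge weight vector all attain their maximum at
#' the same label; otherwise it is ambiguous. The graph-evidence vectors
#' must attain their maximum *uniquely*: a density or weight maximum
#' shared by several labels does not single out any label, so such cells
#' are ambiguous rather than resolved by an arbitrary tie order (argmax
#' positions themselves use the lowest index on ties, consistently for
#' all three vectors). Cells whose true type is missing from the
#' reference sit near the decoder's decision boundary, where whole
#' reference groups tie at saturated density — exactly the profile this
#' rule flags. Cells with no kept edge at all (all-zero density) are
#' ambiguous by definition: the graph offers no evidence for any label.
#'
#' @param zhat_target targets x k matrix of label probabilities.
#' @param density,weight targets x k matrices from [density_weight()].
#' @param cell_ids optional target cell identifiers.
#' @return A `ReliabilityReport`: data.frame `report` (cell_id,
#'   predicted_label, flag, argmax columns) plus the three matrices and a
#'   per-predicted-type summary of ambiguous fractions.
#' @export
flag_predictions <- function(zhat_target, density, weight, cell_ids = NULL) {
  zhat_target <- as.matrix(zhat_target)
  stopifnot(all(dim(zhat_target) == dim(density)),
            all(dim(zhat_target) == dim(weight)))
  vocab <- colnames(zhat_target) %||% colnames(density) %||%
    as.character(seq_len(ncol(zhat_target)))
  az <- argmax_first(zhat_target)
  ad <- argmax_first(density)
  aw <- argmax_first(weight)
  n <- nrow(zhat_target)
  unique_d <- rowSums(density == density[cbind(seq_len(n), ad)]) == 1
  unique_w <- rowSums(abs(weight - weight[cbind(seq_len(n), aw)]) < 1e-9) == 1
  isolated <- rowSums(density) == 0
  conf <- az == ad & az == aw & unique_d & unique_w & !isolated
  ids <- cell_ids %||% rownames(zhat_target) %||%
    as.character(seq_len(nrow(zhat_target)))
  report <- data.frame(cell_id = ids, predicted_label = vocab[az],
                       flag = ifelse(conf, "confident", "ambiguous"),
                       density_argmax = vocab[ad], weight_argmax = vocab[aw],
                       stringsAsFactors = FALSE)
  summary <- vapply(split(report$flag, report$predicted_label),
                    function(f) mean(f == "ambiguous"), numeric(1))
  structure(list(report = report, density = density, weight = weight,
                 zhat = zhat_target,
                 ambiguous_fraction_by_type = summary),
            class = "ReliabilityReport")
}

#' @export
print.ReliabilityReport <- function(x, ...) {
  cat(sprintf("ReliabilityReport: %d target cells, %.1f%% confident\n",
              nrow(x$report), 100 * mean(x$report$flag == "confident")))
  invisible(x)
}

#' Assess reliability of a fitted annotation model
#'
#' Decodes the reference-target block of the merged latent, thresholds it
#' at `tau`, computes per-type edge density and weight against the true
#' reference label groups and flags every target cell.
#'
#' @param fit a `vgae_fit`.
#' @param tau edge-existence threshold.
#' @return A `ReliabilityReport`.
#' @export
assess_reliability <- function(fit, tau = 0.5) {
  stopifnot(is(fit, "vgae_fit"))
  zr <- fit$z_m[seq_len(fit$n1), , drop = FALSE]
  zt <- fit$z_m[fit$n1 + seq_len(fit$n2), , drop = FALSE]
  ghat_cross <- sigmoid(tcrossprod(zr, zt))
  th <- threshold_reconstructed_graph(ghat_cross, tau)
  groups <- split(seq_len(fit$n1), fit$labels_ref)
  dw <- density_weight(th, groups)
  zhat_t <- fit$zhat_m[fit$n1 + seq_len(fit$n2), , drop = FALSE]
  colnames(zhat_t) <- fit$vocab
  flag_predictions(zhat_t, dw$density, dw$weight,
                   cell_ids = fit$node_ids[fit$n1 + seq_len(fit$n2)])
}

#' Export a reliability report as TSV
#'
#' One row per target cell with its predicted label, flag and the top-3
#' (label, density, weight) triples.
#'
#' @param x a `ReliabilityReport`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reliability <- function(x, path) {
  stopifnot(is(x, "ReliabilityReport"))
  nt <- min(3L, ncol(x$density))
  top3 <- t(vapply(seq_len(nrow(x$density)), function(i) {
    o <- order(x$density[i, ], decreasing = TRUE)[seq_len(nt)]
    vocab <- colnames(x$density)
    as.character(rbind(vocab[o], signif(x$density[i, o], 4),
                       signif(x$weight[i, o], 4)))
  }, character(3L * nt)))
  colnames(top3) <- as.vector(outer(c("label", "density", "weight"),
                                    seq_len(nt),
                                    function(a, b) paste0("top", b, "_", a)))
  out <- cbind(x$report[, c("cell_id", "predicted_label", "flag")], top3)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
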