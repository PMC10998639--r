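# Graph construction: intra-modality mutual-kNN graphs, the shared CCA
# space, cross-modality anchor detection, the hybrid graph (RNA cells plus
# ATAC anchors, gene-level features) and the merged reference-target graph.

# kNN membership per row of a distance matrix: j is a neighbor of i iff
# d(i, j) is no larger than i's k-th smallest neighbor distance. Ties at
# the k-th distance are included, which keeps the relation deterministic
# without an arbitrary ordering among equidistant points.
knn_membership <- function(d, k, exclude_self = TRUE) {
  n <- nrow(d)
  m <- matrix(FALSE, n, ncol(d))
  for (i in seq_len(n)) {
    dv <- d[i, ]
    if (exclude_self) dv[i] <- Inf
    kth <- sort(dv, partial = k)[k]
    m[i, ] <- dv <= kth
  }
  m
}

#' Mutual k-nearest-neighbor graph
#'
#' Connects `i` and `j` iff each is among the other's `k` nearest neighbors
#' under Euclidean distance (exact search; ties at the k-th distance are
#' included). Isolated nodes are permitted and reported via a message.
#'
#' @param emb an `EmbeddingMatrix` (or numeric matrix with cell-id
#'   rownames).
#' @param k neighborhood size, `0 < k < n_cells`.
#' @param modality modality tag recorded on every node.
#' @return A `CellGraph`.
#' @export
mutual_knn_graph <- function(emb, k, modality = "rna") {
  coords <- if (is(emb, "EmbeddingMatrix")) emb$coords else as.matrix(emb)
  n <- nrow(coords)
  if (k <= 0L) stop_validation("k must be positive")
  if (k >= n) stop_validation("k must be smaller than the number of cells")
  d <- as.matrix(stats::dist(coords))
  nn <- knn_membership(d, k)
  a <- as(as(Matrix::Matrix((nn & t(nn)) * 1, sparse = TRUE),
             "generalMatrix"), "CsparseMatrix")   # mutuality
  Matrix::diag(a) <- 0
  a <- Matrix::drop0(a)
  g <- cell_graph(a, rownames(coords), rep(modality, n))
  iso <- sum(Matrix::rowSums(g$adjacency) == 0)
  if (iso > 0) message(sprintf("mutual kNN graph: %d isolated node(s)", iso))
  g
}

#' Project RNA and gene-activity features into a shared CCA space
#'
#' Diagonal-free CCA in the style used for single-cell integration: the
#' SVD of the cells x cells cross-product through the shared gene space,
#' `X_rna %*% t(X_gam) = U S V'`. The top-`n` left/right singular vectors
#' become cell coordinates; each row is L2-normalized.
#'
#' @param x_rna,x_gam standardized `FeatureMatrix` objects over the same
#'   genes (columns aligned).
#' @param n dimension of the shared space.
#' @param weight_singular scale each component by its singular value
#'   before row normalization (default). Equal weighting lets the
#'   trailing, noise-dominated components dilute cross-modality
#'   neighborhoods when `n` exceeds the number of real covariation modes.
#' @return A list with `EmbeddingMatrix` elements `rna` and `gam`.
#' @export
cca_shared_space <- function(x_rna, x_gam, n = 30L, weight_singular = TRUE) {
  stopifnot(is(x_rna, "FeatureMatrix"), is(x_gam, "FeatureMatrix"))
  if (!identical(feature_ids(x_rna), feature_ids(x_gam))) {
    stop_validation("CCA inputs must share the same gene columns")
  }
  k <- as_dense(x_rna$values %*% Matrix::t(x_gam$values))
  sv <- svd(k, nu = n, nv = n)
  if (n > length(sv$d) || sv$d[n] <= max(sv$d) * 1e-10) {
    stop_validation("cross-product rank below n")
  }
  # one sign rule for the pair: largest-|u| entry positive, v flipped with u
  for (j in seq_len(n)) {
    s <- sign(sv$u[which.max(abs(sv$u[, j])), j])
    if (s < 0) {
      sv$u[, j] <- -sv$u[, j]
      sv$v[, j] <- -sv$v[, j]
    }
  }
  l2norm <- function(m) m / pmax(sqrt(rowSums(m^2)), 1e-12)
  ur <- sv$u[, seq_len(n), drop = FALSE]
  ug <- sv$v[, seq_len(n), drop = FALSE]
  if (weight_singular) {
    ur <- sweep(ur, 2L, sv$d[seq_len(n)], "*")
    ug <- sweep(ug, 2L, sv$d[seq_len(n)], "*")
  }
  ur <- l2norm(ur)
  ug <- l2norm(ug)
  rownames(ur) <- cell_ids(x_rna)
  rownames(ug) <- cell_ids(x_gam)
  colnames(ur) <- colnames(ug) <- paste0("CC", seq_len(n))
  list(rna = embedding_matrix(ur, "cca"), gam = embedding_matrix(ug, "cca"))
}

#' Detect cross-modality anchor pairs
#'
#' A pair (r, a) is an anchor iff `a` is among the `k2` ATAC nearest
#' neighbors of `r` and `r` among the `k2` RNA nearest neighbors of `a` in
#' the shared CCA space (Euclidean distance on L2-normalized rows; ties at
#' the k-th distance included). The score is the cosine similarity of the
#' pair.
#'
#' @param u_rna,u_gam `EmbeddingMatrix` objects in the shared space.
#' @param k2 cross-modality neighborhood size.
#' @return An `AnchorSet`: list with `pairs` (data.frame `rna_index`,
#'   `atac_index`, `score`) and `atac_anchors` (ascending distinct ATAC
#'   indices).
#' @export
detect_anchors <- function(u_rna, u_gam, k2 = 15L) {
  ur <- if (is(u_rna, "EmbeddingMatrix")) u_rna$coords else as.matrix(u_rna)
  ug <- if (is(u_gam, "EmbeddingMatrix")) u_gam$coords else as.matrix(u_gam)
  n1 <- nrow(ur); n2 <- nrow(ug)
  if (k2 <= 0L) stop_validation("k2 must be positive")
  k2r <- min(k2, n2); k2a <- min(k2, n1)
  cross <- ur %*% t(ug)
  d2 <- outer(rowSums(ur^2), rowSums(ug^2), "+") - 2 * cross
  d2[d2 < 0] <- 0
  in_r <- knn_membership(d2, k2r, exclude_self = FALSE)    # rna -> atac
  in_a <- t(knn_membership(t(d2), k2a, exclude_self = FALSE)) # atac -> rna
  idx <- which(in_r & in_a, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    stop_validation("no anchor pairs detected; increase k2 ",
                    "(training is impossible without anchors)")
  }
  ord <- order(idx[, 1L], idx[, 2L])
  pairs <- data.frame(rna_index = as.integer(idx[ord, 1L]),
                      atac_index = as.integer(idx[ord, 2L]))
  pairs$score <- cross[cbind(pairs$rna_index, pairs$atac_index)]
  structure(list(pairs = pairs,
                 atac_anchors = sort(unique(pairs$atac_index)),
                 k2 = k2),
            class = "AnchorSet")
}

#' @export
print.AnchorSet <- function(x, ...) {
  cat(sprintf("AnchorSet: %d pairs over %d distinct ATAC anchors\n",
              nrow(x$pairs), length(x$atac_anchors)))
  invisible(x)
}

#' Build the hybrid graph
#'
#' Nodes are the RNA cells followed by the distinct ATAC anchor cells
#' (ascending ATAC index). RNA-RNA edges are copied from the RNA graph;
#' RNA-ATAC edges are the mutual cross-kNN anchor pairs. There are no
#' ATAC-ATAC edges. Features stack the standardized RNA matrix on top of
#' the standardized gene-activity rows of the anchors.
#'
#' @param g_rna the RNA `CellGraph`.
#' @param anchors an `AnchorSet`.
#' @param x_rna_std,x_gam_std standardized gene-level `FeatureMatrix`
#'   objects (same gene columns) for all RNA and all ATAC cells.
#' @return A `HybridGraph`: list with `graph` (`CellGraph`), `features`
#'   (dense matrix), `anchor_atac_index`, `pairs`.
#' @export
build_hybrid_graph <- function(g_rna, anchors, x_rna_std, x_gam_std) {
  stopifnot(is(g_rna, "CellGraph"), is(anchors, "AnchorSet"))
  if (!identical(feature_ids(x_rna_std), feature_ids(x_gam_std))) {
    stop_validation("hybrid features must share gene columns")
  }
  n1 <- length(g_rna$node_ids)
  aidx <- anchors$atac_anchors
  if (max(anchors$pairs$rna_index) > n1 ||
      max(aidx) > nrow(x_gam_std$values)) {
    stop_validation("anchor index out of range")
  }
  m <- n1 + length(aidx)
  a <- Matrix::Matrix(0, m, m, sparse = TRUE)
  a[seq_len(n1), seq_len(n1)] <- g_rna$adjacency
  node_of_atac <- match(anchors$pairs$atac_index, aidx) + n1
  a[cbind(anchors$pairs$rna_index, node_of_atac)] <- 1
  a[cbind(node_of_atac, anchors$pairs$rna_index)] <- 1
  atac_ids <- cell_ids(x_gam_std)[aidx]
  graph <- cell_graph(a, c(g_rna$node_ids, atac_ids),
                      c(rep("rna", n1), rep("atac", length(aidx))))
  feats <- rbind(as_dense(x_rna_std$values),
                 as_dense(x_gam_std$values)[aidx, , drop = FALSE])
  rownames(feats) <- graph$node_ids
  structure(list(graph = graph, features = feats,
                 anchor_atac_index = aidx, pairs = anchors$pairs),
            class = "HybridGraph")
}

#' @export
print.HybridGraph <- function(x, ...) {
  cat(sprintf("HybridGraph: %d RNA + %d anchor nodes, %d edges, %d genes\n",
              sum(x$graph$node_modality == "rna"),
              sum(x$graph$node_modality == "atac"),
              n_edges(x$graph), ncol(x$features)))
  invisible(x)
}

#' Build the merged reference-target graph
#'
#' `N = n1 + n2` nodes (all RNA cells, then all ATAC cells). RNA-RNA edges
#' come from the hybrid graph's RNA block, ATAC-ATAC edges from the ATAC
#' graph, and every cross-modality edge of the hybrid graph is remapped so
#' each anchor node lands on its ATAC index in the full target.
#'
#' @param hybrid a `HybridGraph`.
#' @param g_atac the ATAC `CellGraph` over all `n2` target cells.
#' @return A `CellGraph` over `n1 + n2` nodes.
#' @export
build_merged_graph <- function(hybrid, g_atac) {
  stopifnot(is(hybrid, "HybridGraph"), is(g_atac, "CellGraph"))
  n1 <- sum(hybrid$graph$node_modality == "rna")
  n2 <- length(g_atac$node_ids)
  n <- n1 + n2
  ah <- hybrid$graph$adjacency
  a <- Matrix::Matrix(0, n, n, sparse = TRUE)
  a[seq_len(n1), seq_len(n1)] <- ah[seq_len(n1), seq_len(n1)]
  a[n1 + seq_len(n2), n1 + seq_len(n2)] <- g_atac$adjacency
  cross <- as(as(ah[seq_len(n1), -seq_len(n1), drop = FALSE],
                 "TsparseMatrix"), "generalMatrix")
  if (length(cross@x)) {
    ai <- n1 + hybrid$anchor_atac_index[cross@j + 1L]
    a[cbind(cross@i + 1L, ai)] <- 1
    a[cbind(ai, cross@i + 1L)] <- 1
  }
  cell_graph(a, c(hybrid$graph$node_ids[seq_len(n1)], g_atac$node_ids),
             c(rep("rna", n1), rep("atac", n2)))
}
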