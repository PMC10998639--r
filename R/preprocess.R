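# Feature engineering upstream of graph construction: HVG selection,
# z-scoring, TF-IDF, gene activity from peak counts, PCA and LSI
# embeddings.

# log1p counts-per-10k, the normalization underlying HVG selection and the
# standardized gene-level features.
normalize_log_cp10k <- function(x, scale = 1e4) {
  v <- x$values
  rs <- Matrix::rowSums(v)
  rs[rs == 0] <- 1          # all-zero cells stay all-zero
  v <- Matrix::Diagonal(x = scale / rs) %*% v
  v@x <- log1p(v@x)
  dimnames(v) <- dimnames(x$values)
  feature_matrix(v, cell_ids(x), feature_ids(x), x$modality)
}

#' Select highly variable genes
#'
#' Ranks genes by the variance of their log1p counts-per-10k values across
#' cells and keeps the top `g`, ordered by decreasing variance.
#'
#' @param x a `FeatureMatrix` of raw RNA counts.
#' @param g number of genes to keep (`2 <= g <= ncol(x)`).
#' @return A `FeatureMatrix` of raw counts restricted to the selected genes.
#' @export
select_hvg <- function(x, g) {
  stopifnot(is(x, "FeatureMatrix"))
  if (g < 2L) stop_validation("g must be at least 2")
  if (g > ncol(x$values)) stop_validation("g exceeds the number of genes")
  ln <- normalize_log_cp10k(x)
  n <- nrow(ln$values)
  mu <- Matrix::colSums(ln$values) / n
  ex2 <- Matrix::colSums(ln$values^2) / n
  v <- as.numeric(ex2 - mu^2) * n / max(n - 1L, 1L)
  keep <- order(v, decreasing = TRUE)[seq_len(g)]
  feature_matrix(x$values[, keep, drop = FALSE], cell_ids(x),
                 feature_ids(x)[keep], x$modality)
}

#' Standardize features (per-feature z-score)
#'
#' Centers and scales each feature over cells using the population standard
#' deviation; zero-variance features map to all-zero columns. The result is
#' dense by construction.
#'
#' @param x a `FeatureMatrix`.
#' @return A `FeatureMatrix` whose values are z-scores.
#' @export
standardize <- function(x) {
  stopifnot(is(x, "FeatureMatrix"))
  ms <- col_means_sds(x$values)
  sdv <- ms$sd
  sdv[sdv < 1e-12] <- Inf   # zero-variance features -> all zeros
  z <- sweep(sweep(as_dense(x$values), 2L, ms$mean, "-"), 2L, sdv, "/")
  out <- x
  out$values <- Matrix::Matrix(z, sparse = FALSE,
                               dimnames = dimnames(x$values))
  out
}

#' TF-IDF normalization of a peak count matrix
#'
#' Signac-style normalization:
#' `log1p(scale * (x_cp / total_c) * (n_cells / (1 + n_cells_detecting_p)))`.
#' Zeros stay zero, so sparsity is preserved. Cells with zero total counts
#' are dropped with a warning.
#'
#' @param x a `FeatureMatrix` of non-negative peak counts.
#' @param scale scaling constant inside the log (default `1e4`).
#' @return A `FeatureMatrix` of TF-IDF values (modality kept).
#' @export
tfidf <- function(x, scale = 1e4) {
  stopifnot(is(x, "FeatureMatrix"))
  v <- as(x$values, "CsparseMatrix")
  if (length(v@x) && any(v@x < 0)) stop_validation("negative counts in TF-IDF input")
  rs <- Matrix::rowSums(v)
  drop <- rs == 0
  if (any(drop)) {
    warning(sprintf("dropping %d all-zero cell(s) before TF-IDF", sum(drop)))
    v <- v[!drop, , drop = FALSE]
    rs <- rs[!drop]
  }
  n <- nrow(v)
  df <- Matrix::colSums(v > 0)
  idf <- n / (1 + df)
  tv <- as(v, "TsparseMatrix")
  tv@x <- log1p(scale * (tv@x / rs[tv@i + 1L]) * idf[tv@j + 1L])
  out <- as(tv, "CsparseMatrix")
  feature_matrix(out, rownames(v), colnames(v), x$modality)
}

#' Gene activity from peak counts
#'
#' Sums, per cell, the counts of all peaks overlapping each gene's body
#' extended `upstream` bp past its 5' end (strand-aware). A peak touching
#' both body and extension is counted once. Genes without any overlapping
#' peak — including genes requested via `gene_ids` but absent from the
#' annotation — yield zero columns (with a warning for absent genes).
#'
#' @param x a `FeatureMatrix` of peak counts (cells x peaks).
#' @param peaks a `PeakTable` covering the matrix features.
#' @param genes a `GeneTable`.
#' @param upstream bp of 5' extension (default 2000).
#' @param gene_ids optional character vector fixing the output gene set and
#'   order (typically the HVG set of the RNA reference).
#' @return A `FeatureMatrix` with modality `"gene_activity"`.
#' @export
gene_activity <- function(x, peaks, genes, upstream = 2000L,
                          gene_ids = NULL) {
  stopifnot(is(x, "FeatureMatrix"), is(peaks, "PeakTable"),
            is(genes, "GeneTable"))
  if (!all(feature_ids(x) %in% peaks$peak_id)) {
    stop_validation("matrix features missing from the peak table")
  }
  if (is.null(gene_ids)) gene_ids <- genes$gene_id
  absent <- setdiff(gene_ids, genes$gene_id)
  if (length(absent)) {
    warning(sprintf("%d gene(s) absent from annotation get zero activity",
                    length(absent)))
  }
  gtab <- genes[match(setdiff(gene_ids, absent), genes$gene_id), , drop = FALSE]
  ptab <- peaks[match(feature_ids(x), peaks$peak_id), , drop = FALSE]
  # strand-aware 5' extension on 0-based half-open intervals
  gstart <- ifelse(gtab$strand == "+", pmax(gtab$start - upstream, 0L), gtab$start)
  gend <- ifelse(gtab$strand == "+", gtab$end, gtab$end + upstream)
  pk <- GenomicRanges::GRanges(ptab$chrom,
                               IRanges::IRanges(ptab$start + 1L, ptab$end))
  gn <- GenomicRanges::GRanges(gtab$chrom,
                               IRanges::IRanges(gstart + 1L, gend))
  ov <- GenomicRanges::findOverlaps(pk, gn, ignore.strand = TRUE)
  inc <- Matrix::sparseMatrix(i = S4Vectors::queryHits(ov),
                              j = S4Vectors::subjectHits(ov), x = 1,
                              dims = c(length(pk), length(gn)))
  act <- x$values %*% inc
  # reinsert absent genes as zero columns, restore requested order
  out <- Matrix::Matrix(0, nrow(act), length(gene_ids), sparse = TRUE)
  out[, match(gtab$gene_id, gene_ids)] <- act
  feature_matrix(as(out, "CsparseMatrix"), cell_ids(x), gene_ids,
                 "gene_activity")
}

# Deterministic sign convention shared by PCA/LSI/CCA: flip each component
# so its largest-|loading| entry is positive.
fix_signs <- function(scores, loadings) {
  for (j in seq_len(ncol(scores))) {
    s <- sign(loadings[which.max(abs(loadings[, j])), j])
    if (s < 0) {
      scores[, j] <- -scores[, j]
      loadings[, j] <- -loadings[, j]
    }
  }
  list(scores = scores, loadings = loadings)
}

#' PCA embedding of a standardized feature matrix
#'
#' Top-`n` principal components via SVD; deterministic up to the sign rule
#' that makes each component's largest-|loading| entry positive.
#'
#' @param x a `FeatureMatrix` of standardized (column-centered) values.
#' @param n number of components, `n < min(cells, features)`.
#' @return An `EmbeddingMatrix` with method `"pca"`.
#' @export
pca_embed <- function(x, n = 30L) {
  stopifnot(is(x, "FeatureMatrix"))
  m <- as_dense(x$values)
  if (n >= min(dim(m))) stop_validation("n must be < min(cells, features)")
  sv <- svd(m, nu = n, nv = n)
  fx <- fix_signs(sv$u %*% diag(sv$d[seq_len(n)], n, n), sv$v)
  coords <- fx$scores
  rownames(coords) <- cell_ids(x)
  colnames(coords) <- paste0("PC", seq_len(n))
  embedding_matrix(coords, "pca")
}

#' LSI embedding of a TF-IDF matrix
#'
#' Truncated SVD of the TF-IDF matrix via the cells x cells Gram matrix.
#' The first component typically tracks per-cell sequencing depth and is
#' dropped by default, leaving components `2..n`.
#'
#' @param x a `FeatureMatrix` of TF-IDF values.
#' @param n number of SVD components, `n <= rank(x)`.
#' @param drop_first drop the depth-correlated first component.
#' @return An `EmbeddingMatrix` with method `"lsi"`.
#' @export
lsi_embed <- function(x, n = 30L, drop_first = TRUE) {
  stopifnot(is(x, "FeatureMatrix"))
  v <- x$values
  gram <- as_dense(Matrix::tcrossprod(v))
  eg <- eigen(gram, symmetric = TRUE)
  d <- sqrt(pmax(eg$values, 0))
  if (n > length(d)) stop_validation("n exceeds the number of cells")
  if (d[n] <= max(d) * 1e-10) {
    stop_validation("matrix rank below n; lower n or supply more cells/peaks")
  }
  u <- eg$vectors[, seq_len(n), drop = FALSE]
  dn <- d[seq_len(n)]
  loadings <- as_dense(Matrix::crossprod(v, u)) %*% diag(1 / dn, n, n)
  fx <- fix_signs(u %*% diag(dn, n, n), loadings)
  coords <- fx$scores
  if (drop_first) coords <- coords[, -1L, drop = FALSE]
  rownames(coords) <- cell_ids(x)
  colnames(coords) <- paste0("LSI", if (drop_first) 2L:n else seq_len(n))
  embedding_matrix(coords, "lsi")
}
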