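# Core containers: FeatureMatrix, LabelTable, PeakTable, GeneTable,
# EmbeddingMatrix, CellGraph. All matrices are stored cells-in-rows,
# features-in-columns; files in the 10x layout (features x cells) are
# transposed on ingest.

#' Construct a FeatureMatrix
#'
#' A sparse (or dense) cells x features matrix with unique cell and feature
#' identifiers and a modality tag. This is the container for raw RNA counts,
#' raw peak counts, TF-IDF values, gene-activity scores and standardized
#' features.
#'
#' @param values numeric matrix or `Matrix` sparse matrix, cells in rows.
#' @param cell_ids character vector of unique cell identifiers (rows).
#' @param feature_ids character vector of unique feature identifiers
#'   (columns).
#' @param modality one of `"rna"`, `"atac"`, `"gene_activity"`.
#' @return An object of class `FeatureMatrix`.
#' @export
feature_matrix <- function(values, cell_ids = rownames(values),
                           feature_ids = colnames(values),
                           modality = c("rna", "atac", "gene_activity")) {
  modality <- match.arg(modality)
  if (is.null(cell_ids) || is.null(feature_ids)) {
    stop_validation("cell_ids and feature_ids are required")
  }
  cell_ids <- as.character(cell_ids)
  feature_ids <- as.character(feature_ids)
  if (anyDuplicated(cell_ids)) stop_validation("duplicate cell ids")
  if (anyDuplicated(feature_ids)) stop_validation("duplicate feature ids")
  if (nrow(values) != length(cell_ids) || ncol(values) != length(feature_ids)) {
    stop_validation("dimension mismatch between values and id vectors")
  }
  if (is(values, "Matrix")) {
    vals <- values@x
  } else {
    storage.mode(values) <- "double"
    vals <- values
  }
  if (length(vals) && any(!is.finite(vals))) {
    stop_validation("non-finite values in feature matrix")
  }
  if (!is(values, "Matrix")) values <- Matrix::Matrix(values, sparse = TRUE)
  dimnames(values) <- list(cell_ids, feature_ids)
  structure(list(values = values, modality = modality),
            class = "FeatureMatrix")
}

#' @export
print.FeatureMatrix <- function(x, ...) {
  cat(sprintf("FeatureMatrix [%s]: %d cells x %d features, %.2f%% nonzero\n",
              x$modality, nrow(x$values), ncol(x$values),
              100 * Matrix::nnzero(x$values) / prod(dim(x$values))))
  invisible(x)
}

#' @export
dim.FeatureMatrix <- function(x) dim(x$values)

#' Cell and feature identifiers of a FeatureMatrix
#' @param x a `FeatureMatrix`.
#' @return Character vector of identifiers.
#' @export
cell_ids <- function(x) rownames(x$values)

#' @rdname cell_ids
#' @export
feature_ids <- function(x) colnames(x$values)

#' Construct a label table
#'
#' @param cell_id character vector of unique cell identifiers.
#' @param label character vector (or factor) of cell-type labels; the label
#'   vocabulary must contain at least two types.
#' @return A `data.frame` with class `LabelTable`, columns `cell_id`,
#'   `label` (factor).
#' @export
label_table <- function(cell_id, label) {
  cell_id <- as.character(cell_id)
  if (length(cell_id) == 0L) stop_validation("empty label table")
  if (length(cell_id) != length(label)) {
    stop_validation("cell_id and label lengths differ")
  }
  if (anyDuplicated(cell_id)) stop_validation("duplicate cell_id in label table")
  label <- if (is.factor(label)) droplevels(label) else factor(label)
  if (nlevels(label) < 2L) {
    stop_validation("label vocabulary must contain at least 2 types")
  }
  structure(data.frame(cell_id = cell_id, label = label,
                       stringsAsFactors = FALSE),
            class = c("LabelTable", "data.frame"))
}

#' Construct a peak table (0-based half-open intervals)
#'
#' @param chrom,start,end,peak_id vectors describing peak intervals; `start`
#'   and `end` follow BED conventions (0-based, half-open).
#' @return A `data.frame` with class `PeakTable`.
#' @export
peak_table <- function(chrom, start, end, peak_id) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start >= end)) stop_validation("peak intervals must satisfy start < end")
  peak_id <- as.character(peak_id)
  if (anyDuplicated(peak_id)) stop_validation("duplicate peak ids")
  structure(data.frame(chrom = as.character(chrom), start = start, end = end,
                       peak_id = peak_id, stringsAsFactors = FALSE),
            class = c("PeakTable", "data.frame"))
}

#' Construct a gene table (0-based half-open intervals)
#'
#' @param gene_id,chrom,start,end,strand vectors describing gene bodies;
#'   `strand` is `"+"` or `"-"`. Coordinates are stored 0-based half-open.
#' @return A `data.frame` with class `GeneTable`.
#' @export
gene_table <- function(gene_id, chrom, start, end, strand) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start >= end)) stop_validation("gene intervals must satisfy start < end")
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id)) stop_validation("duplicate gene ids")
  strand <- as.character(strand)
  if (!all(strand %in% c("+", "-"))) stop_validation("strand must be '+' or '-'")
  structure(data.frame(gene_id = gene_id, chrom = as.character(chrom),
                       start = start, end = end, strand = strand,
                       stringsAsFactors = FALSE),
            class = c("GeneTable", "data.frame"))
}

#' Construct an embedding matrix
#'
#' @param coords cells x n real matrix with cell ids as row names.
#' @param method one of `"pca"`, `"lsi"`, `"cca"`, `"latent"`.
#' @return An object of class `EmbeddingMatrix`.
#' @export
embedding_matrix <- function(coords, method = c("pca", "lsi", "cca", "latent")) {
  method <- match.arg(method)
  coords <- as.matrix(coords)
  if (is.null(rownames(coords))) stop_validation("embedding needs cell ids as rownames")
  if (any(!is.finite(coords))) stop_validation("non-finite embedding coordinates")
  structure(list(coords = coords, method = method), class = "EmbeddingMatrix")
}

#' @export
print.EmbeddingMatrix <- function(x, ...) {
  cat(sprintf("EmbeddingMatrix [%s]: %d cells x %d dims\n",
              x$method, nrow(x$coords), ncol(x$coords)))
  invisible(x)
}

#' Construct a cell graph
#'
#' Symmetric binary adjacency over cells with zero diagonal; each node keeps
#' its identifier and modality of origin.
#'
#' @param adjacency symmetric binary sparse matrix with zero diagonal.
#' @param node_ids character vector of node identifiers.
#' @param node_modality character vector, per node, `"rna"` or `"atac"`.
#' @return An object of class `CellGraph`.
#' @export
cell_graph <- function(adjacency, node_ids, node_modality) {
  adjacency <- as(as(Matrix::Matrix(adjacency, sparse = TRUE), "dMatrix"),
                  "CsparseMatrix")
  n <- nrow(adjacency)
  if (ncol(adjacency) != n) stop_validation("adjacency must be square")
  if (length(node_ids) != n) stop_validation("node count does not match ids")
  if (length(node_modality) != n) stop_validation("node count does not match modality")
  if (!all(node_modality %in% c("rna", "atac"))) {
    stop_validation("node_modality entries must be 'rna' or 'atac'")
  }
  if (any(Matrix::diag(adjacency) != 0)) stop_validation("adjacency diagonal must be zero")
  if (!Matrix::isSymmetric(adjacency, check.attributes = FALSE)) {
    stop_validation("adjacency must be symmetric")
  }
  if (length(adjacency@x) && !all(adjacency@x %in% c(0, 1))) {
    stop_validation("adjacency must be binary")
  }
  dimnames(adjacency) <- list(node_ids, node_ids)
  structure(list(adjacency = Matrix::drop0(adjacency),
                 node_ids = as.character(node_ids),
                 node_modality = as.character(node_modality)),
            class = "CellGraph")
}

#' @export
print.CellGraph <- function(x, ...) {
  n <- length(x$node_ids)
  e <- Matrix::nnzero(x$adjacency) / 2
  iso <- sum(Matrix::rowSums(x$adjacency) == 0)
  cat(sprintf("CellGraph: %d nodes (%d rna, %d atac), %d edges, %d isolated\n",
              n, sum(x$node_modality == "rna"), sum(x$node_modality == "atac"),
              e, iso))
  invisible(x)
}

#' Number of undirected edges of a CellGraph
#' @param g a `CellGraph`.
#' @return Edge count.
#' @export
n_edges <- function(g) Matrix::nnzero(g$adjacency) / 2
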