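# Readers and writers for the standard single-cell text formats the
# pipeline touches: MTX triplets with barcode/feature sidecars, dense TSV
# matrices, label TSVs, BED peak files, gene annotation tables, prediction
# and embedding exports. Everything is plain text.

#' Read a count matrix (MTX triplet or dense TSV)
#'
#' Sparse input follows the 10x layout: a Matrix Market coordinate file with
#' features in rows and cells in columns, plus one-column `barcodes` and
#' `features` sidecar files. The matrix is transposed on ingest so that the
#' returned [feature_matrix()] is always cells x features. Dense input is a
#' TSV with a header of feature ids and cell ids in the first column,
#' already cells x features.
#'
#' @param path path to a `.mtx` file or a dense TSV.
#' @param barcodes,features sidecar paths (required for MTX input).
#' @param modality modality tag for the result.
#' @param features_in_rows for MTX input, whether the file stores
#'   features x cells (the 10x convention, default `TRUE`).
#' @return A `FeatureMatrix`.
#' @export
read_matrix <- function(path, barcodes = NULL, features = NULL,
                        modality = c("rna", "atac", "gene_activity"),
                        features_in_rows = TRUE) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop_validation("matrix file not found: ", path)
  if (grepl("\\.mtx$", path)) {
    if (is.null(barcodes) || is.null(features)) {
      stop_validation("MTX input requires barcodes and features sidecar files")
    }
    m <- Matrix::readMM(path)
    bc <- readLines(barcodes)
    ft <- readLines(features)
    # features files may be multi-column (id, name, type); keep column 1
    ft <- vapply(strsplit(ft, "\t"), `[[`, character(1), 1L)
    bc <- vapply(strsplit(bc, "\t"), `[[`, character(1), 1L)
    if (features_in_rows) m <- Matrix::t(m)
    if (nrow(m) != length(bc)) {
      stop_validation(sprintf(
        "format error: MTX declares %d cells but barcodes file has %d rows",
        nrow(m), length(bc)))
    }
    if (ncol(m) != length(ft)) {
      stop_validation(sprintf(
        "format error: MTX declares %d features but features file has %d rows",
        ncol(m), length(ft)))
    }
    feature_matrix(as(m, "CsparseMatrix"), bc, ft, modality)
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                             check.names = FALSE)
    feature_matrix(as.matrix(tab), rownames(tab), colnames(tab), modality)
  }
}

#' Write a FeatureMatrix as an MTX bundle
#'
#' Writes `matrix.mtx`, `barcodes.tsv` and `features.tsv` (10x layout,
#' features x cells) into `dir`.
#'
#' @param x a `FeatureMatrix`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_matrix <- function(x, dir) {
  stopifnot(is(x, "FeatureMatrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(as(Matrix::t(x$values), "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(cell_ids(x), file.path(dir, "barcodes.tsv"))
  writeLines(feature_ids(x), file.path(dir, "features.tsv"))
  invisible(dir)
}

#' Read a cell label table
#'
#' Expects a TSV with a header; the first two columns are taken as
#' `cell_id` and `label`.
#'
#' @param path TSV path.
#' @return A `LabelTable`.
#' @export
read_labels <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(tab) == 0L) stop_validation("empty label table: ", path)
  if (ncol(tab) < 2L) stop_validation("label table needs cell_id and label columns")
  label_table(tab[[1L]], tab[[2L]])
}

#' Read peaks from a BED file
#'
#' BED3 plus a name column; intervals are 0-based half-open as in BED.
#' Chromosome naming is kept as-is. A missing name column is filled with
#' `chrom:start-end` identifiers.
#'
#' @param path BED path.
#' @return A `PeakTable`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf < 3L)
  if (length(bad)) {
    stop_validation(sprintf("malformed BED row at line %d: '%s'",
                            bad[1L], lines[bad[1L]]))
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
  if (anyNA(start) || anyNA(end)) {
    ln <- which(is.na(start) | is.na(end))[1L]
    stop_validation(sprintf("malformed BED row at line %d: '%s'", ln, lines[ln]))
  }
  ids <- ifelse(nf >= 4L,
                vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else "",
                       character(1)),
                sprintf("%s:%d-%d", chrom, start, end))
  peak_table(chrom, start, end, ids)
}

#' Read a gene annotation table
#'
#' A TSV with header columns `gene_id`, `chrom`, `start`, `end`, `strand`.
#' By default coordinates are interpreted as 1-based closed (the GTF
#' dialect) and converted to the internal 0-based half-open convention;
#' set `one_based = FALSE` for BED-style input.
#'
#' @param path TSV path.
#' @param one_based whether input coordinates are 1-based closed.
#' @return A `GeneTable`.
#' @export
read_genes <- function(path, one_based = TRUE) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(tab))) {
    stop_validation("gene table needs columns: ", paste(need, collapse = ", "))
  }
  start <- as.integer(tab$start); end <- as.integer(tab$end)
  if (one_based) start <- start - 1L
  gene_table(tab$gene_id, tab$chrom, start, end, tab$strand)
}

#' Write per-cell predictions
#'
#' One row per target cell: `cell_id`, `predicted_label`,
#' `max_probability`, `flag` (`confident` or `ambiguous`).
#'
#' @param cell_id,predicted_label,max_probability,flag equal-length
#'   per-cell vectors.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(cell_id, predicted_label, max_probability,
                              flag, path) {
  n <- length(cell_id)
  if (length(predicted_label) != n || length(max_probability) != n ||
      length(flag) != n) {
    stop_validation("prediction fields have unequal lengths")
  }
  df <- data.frame(cell_id = as.character(cell_id),
                   predicted_label = as.character(predicted_label),
                   max_probability = as.numeric(max_probability),
                   flag = as.character(flag),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a prediction TSV written by [write_predictions()]
#' @param path TSV path.
#' @return A `data.frame`.
#' @export
read_predictions <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = c("character", "character", "numeric",
                                   "character"))
}

#' Write / read a cell embedding
#'
#' Full-precision TSV (17 significant digits) so that a write/read
#' round-trip reproduces the matrix bitwise.
#'
#' @param x an `EmbeddingMatrix` or numeric matrix with cell-id rownames.
#' @param path output TSV path.
#' @return `path` (write), an `EmbeddingMatrix` (read).
#' @export
write_embedding <- function(x, path) {
  coords <- if (is(x, "EmbeddingMatrix")) x$coords else as.matrix(x)
  method <- if (is(x, "EmbeddingMatrix")) x$method else "latent"
  con <- file(path, "w")
  on.exit(close(con))
  cn <- colnames(coords) %||% paste0("dim", seq_len(ncol(coords)))
  writeLines(paste(c("cell_id", cn), collapse = "\t"), con)
  writeLines(sprintf("# method=%s", method), con)
  body <- apply(coords, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(paste(rownames(coords), body, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(path) {
  lines <- readLines(path)
  header <- strsplit(lines[1L], "\t")[[1L]]
  method <- sub("# method=", "", lines[2L], fixed = TRUE)
  rows <- strsplit(lines[-(1:2)], "\t")
  ids <- vapply(rows, `[[`, character(1), 1L)
  coords <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1L])))
  rownames(coords) <- ids
  colnames(coords) <- header[-1L][seq_len(ncol(coords))]
  embedding_matrix(coords, method = method)
}
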