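# Paired multiome simulator: negative-binomial scRNA-seq counts and sparse
# thinned Bernoulli-Poisson scATAC-seq peak counts over a shared cell-type
# structure, with type-specific marker genes, peaks planted inside marker
# gene windows (so gene activity correlates with expression through peak
# placement, not by copying values), label-noise injection and
# reference-type dropout.

#' Simulation configuration
#'
#' Defaults describe the standard validation scenario: five cell types,
#' 1500 cells per modality, 2000 genes, 10000 peaks, strong type
#' separation.
#'
#' @param n_types number of cell types `k >= 2`.
#' @param n_rna,n_atac cells per modality.
#' @param n_genes,n_peaks feature counts.
#' @param peaks_per_gene peaks placed in each gene's body/upstream window.
#' @param sigma_sep type separation: marker genes are elevated by a
#'   log-fold change of about `sigma_sep` (0 makes all types identical).
#' @param dispersion negative-binomial size parameter of RNA counts.
#' @param q0,q1 background and marker peak accessibility rates
#'   (`q1 > q0` unless both equal for a null construction).
#' @param capture capture efficiency: ATAC counts are binomially thinned
#'   by this probability.
#' @param marker_frac fraction of genes assigned as markers to each type
#'   (disjoint across types).
#' @param gene_length,gene_spacing,peak_width genome geometry in bp.
#' @param upstream upstream window used for peak placement (matches the
#'   default of [gene_activity()]).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_types = 5L, n_rna = 1500L, n_atac = 1500L,
                       n_genes = 2000L, n_peaks = 10000L,
                       peaks_per_gene = 3L, sigma_sep = 4,
                       dispersion = 2, q0 = 0.05, q1 = 0.4,
                       capture = 0.7, marker_frac = 0.1,
                       gene_length = 5000L, gene_spacing = 20000L,
                       peak_width = 500L, upstream = 2000L) {
  cfg <- list(n_types = as.integer(n_types), n_rna = as.integer(n_rna),
              n_atac = as.integer(n_atac), n_genes = as.integer(n_genes),
              n_peaks = as.integer(n_peaks),
              peaks_per_gene = as.integer(peaks_per_gene),
              sigma_sep = sigma_sep, dispersion = dispersion,
              q0 = q0, q1 = q1, capture = capture,
              marker_frac = marker_frac,
              gene_length = as.integer(gene_length),
              gene_spacing = as.integer(gene_spacing),
              peak_width = as.integer(peak_width),
              upstream = as.integer(upstream))
  if (cfg$n_types < 2L) stop_validation("need at least 2 cell types")
  if (cfg$q1 < cfg$q0) stop_validation("q1 must be >= q0")
  if (any(unlist(cfg[c("n_rna", "n_atac", "n_genes", "n_peaks",
                       "peaks_per_gene")]) <= 0L)) {
    stop_validation("all counts must be positive")
  }
  if (cfg$n_genes * cfg$peaks_per_gene > cfg$n_peaks) {
    stop_validation("more gene-linked peaks than total peaks; ",
                    "increase n_peaks or lower peaks_per_gene")
  }
  structure(cfg, class = "sim_config")
}

# Sparse counts from a dense-ish sampling loop over types, kept sparse by
# only storing nonzeros.
counts_to_sparse <- function(m, cell_ids, feature_ids) {
  sm <- Matrix::Matrix(m, sparse = TRUE)
  dimnames(sm) <- list(cell_ids, feature_ids)
  as(sm, "CsparseMatrix")
}

#' Simulate a paired scRNA-seq + scATAC-seq dataset
#'
#' Each cell type elevates a disjoint set of marker genes by a log-fold
#' change of about `sigma_sep`; RNA counts are negative binomial around the
#' type mean. Every gene owns `peaks_per_gene` peaks placed inside its
#' body/upstream window; peaks of a type's marker genes are accessible at
#' rate `q1` in cells of that type and `q0` elsewhere, so the planted peak
#' sets are disjoint across types and gene activity correlates with
#' expression. ATAC counts are Bernoulli x (1 + Poisson), binomially
#' thinned by the capture efficiency. Deterministic given `(config, seed)`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return A `SyntheticDataset`: list with `FeatureMatrix` elements
#'   `x_rna`, `x_atac`, tables `peaks`, `genes`, `links`, `LabelTable`s
#'   `labels_rna`, `labels_atac`, and `planted_peaks` (named list per
#'   type).
#' @export
simulate_paired <- function(config = sim_config(), seed = 1L) {
  stopifnot(is(config, "sim_config"))
  withr::with_seed(as.integer(seed), {
    k <- config$n_types
    types <- paste0("type", seq_len(k))
    g <- config$n_genes; p <- config$n_peaks

    # genome geometry: genes tiled along one chromosome
    gene_len <- config$gene_length
    gstart <- seq_len(g) * config$gene_spacing
    gend <- gstart + gene_len
    strand <- rep(c("+", "-"), length.out = g)
    genes <- gene_table(sprintf("gene%04d", seq_len(g)), "chr1",
                        gstart, gend, strand)

    # marker assignment: disjoint blocks of genes per type
    n_marker <- max(1L, floor(g * config$marker_frac))
    if (n_marker * k > g) n_marker <- floor(g / k)
    marker_sets <- split(seq_len(n_marker * k),
                         rep(seq_len(k), each = n_marker))
    names(marker_sets) <- types

    # per-gene base expression and per-type means
    base_log <- stats::rnorm(g, mean = log(0.3), sd = 1)
    mu <- matrix(exp(base_log), k, g, byrow = TRUE)
    for (t in seq_len(k)) {
      mg <- marker_sets[[t]]
      lfc <- config$sigma_sep * stats::runif(length(mg), 0.75, 1.25)
      mu[t, mg] <- exp(base_log[mg] + lfc)
    }

    # cell-type labels, balanced then shuffled
    lab_rna <- factor(sample(rep_len(types, config$n_rna)), levels = types)
    lab_atac <- factor(sample(rep_len(types, config$n_atac)), levels = types)

    rna_ids <- sprintf("rna_cell%05d", seq_len(config$n_rna))
    atac_ids <- sprintf("atac_cell%05d", seq_len(config$n_atac))

    x_rna <- matrix(0L, config$n_rna, g)
    for (t in seq_len(k)) {
      rows <- which(as.integer(lab_rna) == t)
      if (!length(rows)) next
      x_rna[rows, ] <- matrix(
        stats::rnbinom(length(rows) * g, size = config$dispersion,
                       mu = rep(mu[t, ], each = length(rows))),
        length(rows), g)
    }

    # peaks: peaks_per_gene in each gene's strand-aware window, the rest
    # intergenic (well clear of any gene window)
    ppg <- config$peaks_per_gene
    n_linked <- g * ppg
    win_start <- ifelse(strand == "+", gstart - config$upstream, gstart)
    win_end <- ifelse(strand == "+", gend, gend + config$upstream)
    rel <- matrix(stats::runif(n_linked), g, ppg)
    pstart <- as.integer(rep(win_start, ppg) +
      floor(as.vector(rel) * (rep(win_end - win_start, ppg) - config$peak_width)))
    pstart <- pmax(pstart, 0L)
    link_gene <- rep(seq_len(g), ppg)
    n_inter <- p - n_linked
    if (n_inter > 0) {
      gaps_mid <- gstart[-1L] - config$gene_spacing %/% 2L
      inter_start <- sample(gaps_mid, n_inter, replace = TRUE) +
        sample.int(2000L, n_inter, replace = TRUE)
      pstart <- c(pstart, as.integer(inter_start))
      link_gene <- c(link_gene, rep(NA_integer_, n_inter))
    }
    ord <- order(pstart)
    pstart <- pstart[ord]; link_gene <- link_gene[ord]
    peaks <- peak_table("chr1", pstart, pstart + config$peak_width,
                        sprintf("peak%05d", seq_along(pstart)))
    links <- data.frame(peak_id = peaks$peak_id[!is.na(link_gene)],
                        gene_id = genes$gene_id[link_gene[!is.na(link_gene)]],
                        stringsAsFactors = FALSE)

    # which type (if any) each peak is planted for
    peak_type <- rep(NA_integer_, p)
    for (t in seq_len(k)) {
      peak_type[!is.na(link_gene) & link_gene %in% marker_sets[[t]]] <- t
    }
    planted <- lapply(stats::setNames(seq_len(k), types),
                      function(t) peaks$peak_id[which(peak_type == t)])

    rate <- matrix(config$q0, k, p)
    for (t in seq_len(k)) rate[t, which(peak_type == t)] <- config$q1

    x_atac <- matrix(0L, config$n_atac, p)
    for (t in seq_len(k)) {
      rows <- which(as.integer(lab_atac) == t)
      if (!length(rows)) next
      nrp <- length(rows) * p
      open <- stats::rbinom(nrp, 1L, rep(rate[t, ], each = length(rows)))
      cnt <- open * (1L + stats::rpois(nrp, 0.5))
      cnt <- stats::rbinom(nrp, cnt, config$capture)
      x_atac[rows, ] <- matrix(cnt, length(rows), p)
    }

    structure(list(
      x_rna = feature_matrix(counts_to_sparse(x_rna, rna_ids, genes$gene_id),
                             modality = "rna"),
      x_atac = feature_matrix(counts_to_sparse(x_atac, atac_ids, peaks$peak_id),
                              modality = "atac"),
      peaks = peaks, genes = genes, links = links,
      labels_rna = label_table(rna_ids, lab_rna),
      labels_atac = label_table(atac_ids, lab_atac),
      planted_peaks = planted, marker_genes = lapply(marker_sets, function(i)
        genes$gene_id[i]),
      config = config, seed = as.integer(seed)),
      class = "SyntheticDataset")
  })
}

#' @export
print.SyntheticDataset <- function(x, ...) {
  cat(sprintf(paste0("SyntheticDataset: %d types, %d RNA cells x %d genes, ",
                     "%d ATAC cells x %d peaks (seed %d)\n"),
              x$config$n_types, nrow(x$x_rna$values), ncol(x$x_rna$values),
              nrow(x$x_atac$values), ncol(x$x_atac$values), x$seed))
  invisible(x)
}

#' Inject label noise into a label table
#'
#' Exactly `round(p * n)` cells are chosen uniformly without replacement
#' and each is reassigned a uniformly random WRONG label (never its own).
#'
#' @param labels a `LabelTable`.
#' @param p noise proportion in `[0, 1]`.
#' @param seed integer seed.
#' @return A `LabelTable` with the same vocabulary.
#' @export
inject_label_noise <- function(labels, p, seed = 1L) {
  stopifnot(is(labels, "LabelTable"))
  if (p < 0 || p > 1) stop_validation("p must lie in [0, 1]")
  vocab <- levels(labels$label)
  if (length(vocab) < 2L) stop_validation("cannot corrupt a 1-label vocabulary")
  withr::with_seed(as.integer(seed), {
    n <- nrow(labels)
    flip <- sample.int(n, round(p * n))
    new <- as.character(labels$label)
    for (i in flip) {
      wrong <- setdiff(vocab, new[i])
      new[i] <- wrong[sample.int(length(wrong), 1L)]
    }
    label_table(labels$cell_id, factor(new, levels = vocab))
  })
}

#' Remove one cell type from the reference
#'
#' Drops every reference (RNA) cell of `type_name`; the target is
#' untouched, so its true labels still include the dropped type while the
#' training vocabulary shrinks by one.
#'
#' @param dataset a `SyntheticDataset`.
#' @param type_name type to remove from the reference.
#' @return The modified `SyntheticDataset`.
#' @export
drop_reference_type <- function(dataset, type_name) {
  stopifnot(is(dataset, "SyntheticDataset"))
  vocab <- levels(dataset$labels_rna$label)
  if (!type_name %in% vocab) stop_validation("type not present in reference")
  if (length(vocab) <= 2L) {
    stop_validation("removing this type would leave fewer than 2 types")
  }
  keep <- dataset$labels_rna$label != type_name
  dataset$x_rna$values <- dataset$x_rna$values[keep, , drop = FALSE]
  dataset$labels_rna <- label_table(
    dataset$labels_rna$cell_id[keep],
    droplevels(dataset$labels_rna$label[keep]))
  dataset$dropped_type <- c(dataset$dropped_type, type_name)
  dataset
}

#' Write a SyntheticDataset as a plain-text input bundle
#'
#' MTX bundles for both modalities, label TSVs, a BED peak file and a gene
#' annotation TSV (1-based closed coordinates, readable by
#' [read_genes()]).
#'
#' @param dataset a `SyntheticDataset`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_dataset_bundle <- function(dataset, dir) {
  stopifnot(is(dataset, "SyntheticDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(dataset$x_rna, file.path(dir, "rna"))
  write_matrix(dataset$x_atac, file.path(dir, "atac"))
  utils::write.table(as.data.frame(dataset$labels_rna),
                     file.path(dir, "labels_rna.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(dataset$labels_atac),
                     file.path(dir, "labels_atac.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  with(dataset$peaks,
       writeLines(sprintf("%s\t%d\t%d\t%s", chrom, start, end, peak_id),
                  file.path(dir, "peaks.bed")))
  gt <- dataset$genes
  utils::write.table(
    data.frame(gene_id = gt$gene_id, chrom = gt$chrom,
               start = gt$start + 1L, end = gt$end, strand = gt$strand),
    file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
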