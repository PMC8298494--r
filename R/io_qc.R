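#' Construct an islet count matrix
#'
#' Bundles a sparse genes x cells (or genes x samples) matrix of non-negative
#' integer UMI/read counts with per-gene and per-cell metadata. This is the
#' container every downstream step consumes.
#'
#' @param counts A matrix or sparse \code{Matrix} of non-negative integers,
#'   genes in rows, cells/samples in columns. Row names are gene names, column
#'   names are barcodes/sample ids; both must be unique.
#' @param gene_meta Optional data.frame with one row per gene. A logical
#'   \code{mito} column flags mitochondrial genes; if absent it is derived from
#'   \code{mito_prefix}.
#' @param cell_meta Optional data.frame with one row per cell (columns such as
#'   \code{barcode}, \code{replicate}, \code{fraction}, \code{cluster}).
#' @param mito_prefix Character vector of gene-name prefixes marking
#'   mitochondrial genes (case-sensitive; default covers mouse \code{"mt-"}
#'   and human \code{"MT-"}).
#' @return An object of class \code{islet_counts}: a list with elements
#'   \code{counts} (a \code{dgCMatrix}), \code{gene_meta} and \code{cell_meta}.
#' @export
islet_counts <- function(counts, gene_meta = NULL, cell_meta = NULL,
                         mito_prefix = c("mt-", "MT-")) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  x <- counts@x
  if (any(x < 0)) stop("counts must be non-negative")
  if (any(x != round(x))) stop("counts must be integral")
  if (is.null(rownames(counts))) stop("counts must have gene row names")
  if (is.null(colnames(counts))) stop("counts must have cell/sample column names")
  if (anyDuplicated(rownames(counts))) stop("gene names must be unique")
  if (anyDuplicated(colnames(counts))) stop("cell/sample ids must be unique")
  if (is.null(gene_meta)) {
    gene_meta <- data.frame(name = rownames(counts), stringsAsFactors = FALSE)
  }
  if (nrow(gene_meta) != nrow(counts)) stop("gene_meta row count mismatch")
  if (is.null(gene_meta$mito)) {
    pat <- paste0("^(", paste(vapply(mito_prefix, function(p)
      gsub("([][{}()+*^$.|\\\\?-])", "\\\\\\1", p), ""), collapse = "|"), ")")
    gene_meta$mito <- grepl(pat, rownames(counts))
  }
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(barcode = colnames(counts), stringsAsFactors = FALSE)
  }
  if (nrow(cell_meta) != ncol(counts)) stop("cell_meta row count mismatch")
  if (is.null(cell_meta$barcode)) cell_meta$barcode <- colnames(counts)
  rownames(gene_meta) <- rownames(counts)
  rownames(cell_meta) <- colnames(counts)
  structure(list(counts = counts, gene_meta = gene_meta, cell_meta = cell_meta),
            class = "islet_counts")
}

#' @exportS3Method base::print
print.islet_counts <- function(x, ...) {
  cat(sprintf("islet_counts: %d genes x %d cells (%.1f%% nonzero)\n",
              nrow(x$counts), ncol(x$counts),
              100 * length(x$counts@x) / prod(dim(x$counts))))
  cat(sprintf("  mitochondrial genes: %d\n", sum(x$gene_meta$mito)))
  cat(sprintf("  cell metadata: %s\n", paste(names(x$cell_meta), collapse = ", ")))
  invisible(x)
}

#' @export
dim.islet_counts <- function(x) dim(x$counts)

#' Subset an islet count matrix
#'
#' @param x An \code{islet_counts} object.
#' @param i,j Gene and cell indices (numeric, logical or names).
#' @param ... Ignored.
#' @return A new \code{islet_counts} with metadata subset in step.
#' @export
`[.islet_counts` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  structure(list(counts = x$counts[i, j, drop = FALSE],
                 gene_meta = x$gene_meta[i, , drop = FALSE],
                 cell_meta = x$cell_meta[j, , drop = FALSE]),
            class = "islet_counts")
}

#' Read a 10x-style MTX triplet into an islet count matrix
#'
#' Reads a MatrixMarket count file with companion feature and barcode TSVs,
#' joins optional cell metadata and flags mitochondrial genes by name prefix.
#'
#' @param matrix_path Path to the MatrixMarket \code{.mtx} file
#'   (genes x cells).
#' @param features_path Path to a headerless TSV whose first column is the
#'   gene name, one line per matrix row.
#' @param barcodes_path Path to a headerless TSV of cell barcodes, one line
#'   per matrix column.
#' @param cell_meta_path Optional path to a TSV with a header and a
#'   \code{barcode} column; joined onto the barcodes.
#' @param mito_prefix Gene-name prefixes flagging mitochondrial genes.
#' @return An \code{islet_counts} object.
#' @export
read_counts <- function(matrix_path, features_path, barcodes_path,
                        cell_meta_path = NULL, mito_prefix = c("mt-", "MT-")) {
  for (p in c(matrix_path, features_path, barcodes_path))
    if (!file.exists(p)) stop("file not found: ", p)
  m <- Matrix::readMM(matrix_path)
  feats <- utils::read.delim(features_path, header = FALSE,
                             stringsAsFactors = FALSE)
  bcs <- utils::read.delim(barcodes_path, header = FALSE,
                           stringsAsFactors = FALSE)
  if (nrow(feats) != nrow(m))
    stop(sprintf("feature file has %d lines but matrix header says %d genes",
                 nrow(feats), nrow(m)))
  if (nrow(bcs) != ncol(m))
    stop(sprintf("barcode file has %d lines but matrix header says %d cells",
                 nrow(bcs), ncol(m)))
  if (any(m@x != round(m@x))) stop("matrix contains non-integer entries")
  rownames(m) <- feats[[1]]
  colnames(m) <- bcs[[1]]
  cell_meta <- NULL
  if (!is.null(cell_meta_path)) {
    cm <- utils::read.delim(cell_meta_path, stringsAsFactors = FALSE)
    if (is.null(cm$barcode)) stop("cell metadata needs a 'barcode' column")
    cell_meta <- cm[match(bcs[[1]], cm$barcode), , drop = FALSE]
  }
  islet_counts(m, cell_meta = cell_meta, mito_prefix = mito_prefix)
}

#' Write an islet count matrix as a 10x-style MTX triplet
#'
#' Inverse of \code{\link{read_counts}}: writes \code{matrix.mtx},
#' \code{features.tsv}, \code{barcodes.tsv} and \code{cell_meta.tsv} into a
#' directory.
#'
#' @param m An \code{islet_counts} object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_counts <- function(m, dir) {
  stopifnot(inherits(m, "islet_counts"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv",
                            "cell_meta.tsv"))
  Matrix::writeMM(m$counts, paths[1])
  writeLines(rownames(m$counts), paths[2])
  writeLines(colnames(m$counts), paths[3])
  utils::write.table(m$cell_meta, paths[4], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Quality-control configuration for cell filtering
#'
#' @param min_features Minimum number of detected genes per cell (inclusive).
#' @param min_umis Minimum total UMI count per cell (inclusive).
#' @param max_mito_frac Maximum mitochondrial UMI fraction per cell
#'   (inclusive).
#' @return A \code{qc_config} list.
#' @export
qc_config <- function(min_features = 500, min_umis = 1000,
                      max_mito_frac = 0.07) {
  stopifnot(min_features >= 0, min_umis >= 0,
            max_mito_frac >= 0, max_mito_frac <= 1)
  structure(list(min_features = min_features, min_umis = min_umis,
                 max_mito_frac = max_mito_frac), class = "qc_config")
}

#' Filter cells on UMI depth, detected genes and mitochondrial fraction
#'
#' Keeps exactly the cells with detected-gene count >= \code{min_features},
#' total UMIs >= \code{min_umis} and mitochondrial UMI fraction
#' <= \code{max_mito_frac} (all boundaries inclusive). Genes are untouched;
#' the mitochondrial fraction is computed on raw UMIs before any gene
#' filtering.
#'
#' @param m An \code{islet_counts} object with mitochondrial flags.
#' @param q A \code{\link{qc_config}}.
#' @return The filtered \code{islet_counts}, with an attached
#'   \code{"qc_report"} attribute counting cells removed per criterion
#'   (a removed cell can count against several criteria).
#' @export
qc_filter <- function(m, q = qc_config()) {
  stopifnot(inherits(m, "islet_counts"))
  if (is.null(m$gene_meta$mito)) stop("mitochondrial flags missing")
  totals <- Matrix::colSums(m$counts)
  nfeat <- Matrix::colSums(m$counts > 0)
  mito <- Matrix::colSums(m$counts[m$gene_meta$mito, , drop = FALSE])
  mfrac <- ifelse(totals > 0, mito / totals, 0)
  fail_feat <- nfeat < q$min_features
  fail_umi <- totals < q$min_umis
  fail_mito <- mfrac > q$max_mito_frac
  keep <- !(fail_feat | fail_umi | fail_mito)
  if (!any(keep)) stop("no cells survive QC filtering")
  out <- m[, keep]
  attr(out, "qc_report") <- data.frame(
    criterion = c("min_features", "min_umis", "max_mito_frac", "total_removed"),
    removed = c(sum(fail_feat), sum(fail_umi), sum(fail_mito), sum(!keep)))
  out
}

#' Log-normalize UMI counts
#'
#' Per-cell normalization on the natural-log scale:
#' \code{value(g, c) = ln(1 + scale_factor * count(g, c) / total(c))}.
#' Zeros map exactly to zero, so the sparsity pattern is preserved.
#'
#' @param m An \code{islet_counts} object; every cell must have a positive
#'   UMI total.
#' @param scale_factor Counts-per-X scale (default 10,000).
#' @return An \code{islet_norm} object: list with the sparse \code{values}
#'   matrix, the \code{scale_factor} and the per-cell \code{totals} used.
#' @export
log_normalize <- function(m, scale_factor = 10000) {
  stopifnot(inherits(m, "islet_counts"), scale_factor > 0)
  totals <- Matrix::colSums(m$counts)
  if (any(totals == 0))
    stop("cells with zero total UMIs present; run qc_filter first")
  v <- m$counts
  # scale column-wise on the nonzero entries only
  v@x <- log1p(scale_factor * v@x / rep.int(totals, diff(v@p)))
  structure(list(values = v, scale_factor = scale_factor, totals = totals,
                 cell_meta = m$cell_meta),
            class = "islet_norm")
}

#' @exportS3Method base::print
print.islet_norm <- function(x, ...) {
  cat(sprintf("islet_norm: %d genes x %d cells, ln(1 + %g * count / total)\n",
              nrow(x$values), ncol(x$values), x$scale_factor))
  invisible(x)
}

#' @export
dim.islet_norm <- function(x) dim(x$values)
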