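#' Single-cell cohort container
#'
#' A lightweight container for a multi-patient single-cell UMI experiment:
#' a sparse genes x cells count matrix plus aligned per-cell and per-gene
#' metadata. Genes are rows and cells are columns, following single-cell
#' matrix market convention.
#'
#' @param counts genes x cells matrix of non-negative integer UMI counts
#'   (coerced to [Matrix::dgCMatrix-class]).
#' @param cells data.frame with one row per cell. Must contain `cell_id` and
#'   `patient`; optional columns include `cluster`, `cell_type`, `clone` and
#'   `malignant` (logical).
#' @param genes data.frame with one row per gene. Must contain `gene`;
#'   optional `chromosome` and `start` columns give genomic positions used
#'   for copy-number inference.
#'
#' @return An object of class `cohort`: a list with elements `counts`,
#'   `cells`, `genes`.
#' @export
cohort <- function(counts, cells, genes) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  cells <- as.data.frame(cells)
  genes <- as.data.frame(genes)
  if (!"cell_id" %in% names(cells)) stop("cells must have a 'cell_id' column")
  if (!"patient" %in% names(cells)) stop("cells must have a 'patient' column")
  if (!"gene" %in% names(genes)) stop("genes must have a 'gene' column")
  if (nrow(cells) != ncol(counts))
    stop("cells has ", nrow(cells), " rows but counts has ", ncol(counts), " columns")
  if (nrow(genes) != nrow(counts))
    stop("genes has ", nrow(genes), " rows but counts has ", nrow(counts), " rows")
  if (anyDuplicated(genes$gene)) stop("gene ids must be unique")
  dup <- duplicated(paste(cells$patient, cells$cell_id))
  if (any(dup)) stop("duplicate cell_id within a patient: ", cells$cell_id[dup][1])
  rownames(counts) <- genes$gene
  colnames(counts) <- cells$cell_id
  structure(list(counts = counts, cells = cells, genes = genes),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d genes x %d cells, %d patient(s)\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$cells$patient))))
  extra <- intersect(c("cluster", "cell_type", "clone", "malignant"), names(x$cells))
  if (length(extra)) cat("cell metadata:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.cohort <- function(x) dim(x$counts)

#' Subset a cohort by cells and/or genes
#'
#' @param x a [cohort()].
#' @param cells logical, integer or character index into the cell axis.
#' @param genes logical, integer or character index into the gene axis.
#' @return The subsetted `cohort`.
#' @export
subset_cohort <- function(x, cells = NULL, genes = NULL) {
  stopifnot(inherits(x, "cohort"))
  if (!is.null(genes)) {
    if (is.character(genes)) genes <- match(genes, x$genes$gene)
    x$counts <- x$counts[genes, , drop = FALSE]
    x$genes <- x$genes[genes, , drop = FALSE]
  }
  if (!is.null(cells)) {
    if (is.character(cells)) cells <- match(cells, x$cells$cell_id)
    x$counts <- x$counts[, cells, drop = FALSE]
    x$cells <- x$cells[cells, , drop = FALSE]
  }
  rownames(x$cells) <- NULL
  rownames(x$genes) <- NULL
  x
}

#' Split a cohort into one cohort per patient
#'
#' @param x a [cohort()].
#' @return Named list of single-patient `cohort` objects.
#' @export
split_patients <- function(x) {
  stopifnot(inherits(x, "cohort"))
  ids <- unique(x$cells$patient)
  out <- lapply(ids, function(p) subset_cohort(x, cells = x$cells$patient == p))
  names(out) <- ids
  out
}

#' Write a cohort to disk as MatrixMarket + TSV
#'
#' One subdirectory per patient containing `matrix.mtx` (genes x cells),
#' `features.tsv` and `barcodes.tsv`, plus cohort-level `cells.tsv` and
#' `genes.tsv` tables.
#'
#' @param x a [cohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in unique(x$cells$patient)) {
    sub <- subset_cohort(x, cells = x$cells$patient == p)
    pdir <- file.path(dir, p)
    dir.create(pdir, showWarnings = FALSE)
    Matrix::writeMM(sub$counts, file.path(pdir, "matrix.mtx"))
    utils::write.table(sub$genes["gene"], file.path(pdir, "features.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    utils::write.table(sub$cells["cell_id"], file.path(pdir, "barcodes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  utils::write.table(x$cells, file.path(dir, "cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$genes, file.path(dir, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory produced by [write_cohort()].
#' @return A [cohort()].
#' @export
read_cohort <- function(dir) {
  cells <- utils::read.delim(file.path(dir, "cells.tsv"))
  genes <- utils::read.delim(file.path(dir, "genes.tsv"))
  mats <- lapply(unique(cells$patient), function(p) {
    pdir <- file.path(dir, p)
    m <- Matrix::readMM(file.path(pdir, "matrix.mtx"))
    rownames(m) <- readLines(file.path(pdir, "features.tsv"))
    colnames(m) <- readLines(file.path(pdir, "barcodes.tsv"))
    m
  })
  counts <- do.call(cbind, mats)
  counts <- counts[genes$gene, paste(cells$cell_id), drop = FALSE]
  cohort(counts, cells, genes)
}

#' Read a gene-position table
#'
#' @param path TSV with columns `gene`, `chromosome`, `start`.
#' @return data.frame usable as the `genes` slot of a [cohort()].
#' @export
read_gene_order <- function(path) {
  g <- utils::read.delim(path)
  need <- c("gene", "chromosome", "start")
  if (!all(need %in% names(g)))
    stop("gene order file must have columns: ", paste(need, collapse = ", "))
  g
}
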