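#' QC thresholds for cell filtering
#'
#' The filters applied to each cell after cell calling: cells with fewer
#' than `min_genes` or more than `max_genes` expressed genes are removed, as
#' are cells with more than `max_umis` total UMIs or a mitochondrial UMI
#' fraction above `max_mito_fraction`. All bounds are read strictly, so a
#' cell sitting exactly on a threshold survives.
#'
#' @param min_genes,max_genes bounds on the number of expressed genes.
#' @param max_umis upper bound on total UMIs.
#' @param max_mito_fraction upper bound on the mitochondrial UMI fraction.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_genes = 200, max_genes = 5000,
                          max_umis = 30000, max_mito_fraction = 0.30) {
  if (min_genes >= max_genes) stop("min_genes must be < max_genes")
  if (max_mito_fraction < 0 || max_mito_fraction > 1)
    stop("max_mito_fraction must lie in [0, 1]")
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 max_umis = max_umis, max_mito_fraction = max_mito_fraction),
            class = "qc_thresholds")
}

#' Knee-based cell calling from barcode UMI totals
#'
#' Selects the barcodes above the knee of the descending barcode-rank
#' curve. On the log10(rank) vs log10(total) curve of barcodes with
#' positive totals, the knee is the point with maximum perpendicular
#' distance to the chord joining the curve's endpoints; ties are broken
#' toward higher totals. Every barcode whose total is at least the total at
#' the knee is retained, so the retained set is always a prefix of the
#' rank-sorted barcodes. If all positive totals are equal the curve has no
#' knee and all positive barcodes are kept.
#'
#' @param totals named (or unnamed) numeric vector of per-barcode UMI totals.
#' @return Indices (or names, if `totals` is named) of retained barcodes.
#' @export
call_cells_knee <- function(totals) {
  if (length(totals) == 0 || all(totals == 0)) stop("all barcode totals are zero")
  pos <- which(totals > 0)
  if (length(pos) < 10)
    stop("need at least 10 barcodes with positive totals, got ", length(pos))
  tot <- totals[pos]
  ord <- order(tot, decreasing = TRUE)
  srt <- tot[ord]
  keep_n <- length(srt)
  if (srt[1] > srt[keep_n]) {
    x <- log10(seq_along(srt))
    y <- log10(srt)
    # perpendicular distance from each point to the endpoint chord
    dx <- x[length(x)] - x[1]
    dy <- y[length(y)] - y[1]
    dist <- abs(dy * x - dx * y + dx * y[1] - dy * x[1]) / sqrt(dx^2 + dy^2)
    knee <- which.max(dist)          # first max = highest total on plateaus
    keep_n <- max(which(srt >= srt[knee]))
  }
  kept <- pos[ord[seq_len(keep_n)]]
  if (!is.null(names(totals))) names(totals)[kept] else kept
}

#' Per-cell QC metrics
#'
#' Computes, for every cell, the number of expressed genes (count > 0), the
#' total UMI count, and the mitochondrial fraction (UMIs of genes matching
#' `mito_pattern` over total UMIs; 0 by convention for all-zero cells).
#'
#' @param x a [cohort()] or a genes x cells count matrix with gene rownames.
#' @param mito_pattern regular expression identifying mitochondrial genes by
#'   symbol (case-insensitive).
#' @return data.frame with columns `cell_id`, `n_genes`, `n_umis`,
#'   `mito_fraction`.
#' @export
compute_qc <- function(x, mito_pattern = "^MT-") {
  m <- if (inherits(x, "cohort")) x$counts else x
  if (ncol(m) == 0) stop("matrix has no cells")
  n_genes <- Matrix::colSums(m > 0)
  n_umis <- Matrix::colSums(m)
  mito <- grepl(mito_pattern, rownames(m), ignore.case = TRUE)
  mito_umis <- if (any(mito)) Matrix::colSums(m[mito, , drop = FALSE]) else rep(0, ncol(m))
  data.frame(cell_id = if (!is.null(colnames(m))) colnames(m) else as.character(seq_len(ncol(m))),
             n_genes = as.vector(n_genes),
             n_umis = as.vector(n_umis),
             mito_fraction = ifelse(n_umis > 0, mito_umis / n_umis, 0),
             row.names = NULL)
}

#' Filter cells on QC metrics
#'
#' Retains exactly the cells with
#' `min_genes <= n_genes <= max_genes`, `n_umis <= max_umis` and
#' `mito_fraction <= max_mito_fraction` (strict reading of the exclusion
#' rules: boundary cells survive).
#'
#' @param x a [cohort()] or genes x cells count matrix.
#' @param qc output of [compute_qc()] aligned to `x`; recomputed if `NULL`.
#' @param thresholds a [qc_thresholds()].
#' @return The filtered object, with attributes `n_removed` and `n_kept`.
#' @export
filter_cells <- function(x, qc = NULL, thresholds = qc_thresholds()) {
  m <- if (inherits(x, "cohort")) x$counts else x
  if (ncol(m) == 0) return(x)
  if (is.null(qc)) qc <- compute_qc(x)
  if (nrow(qc) != ncol(m) ||
      (!is.null(colnames(m)) && !identical(as.character(qc$cell_id), colnames(m))))
    stop("qc table is not aligned to the matrix cells")
  keep <- qc$n_genes >= thresholds$min_genes &
    qc$n_genes <= thresholds$max_genes &
    qc$n_umis <= thresholds$max_umis &
    qc$mito_fraction <= thresholds$max_mito_fraction
  out <- if (inherits(x, "cohort")) subset_cohort(x, cells = keep)
         else m[, keep, drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  attr(out, "n_kept") <- sum(keep)
  out
}

#' Library-size log-normalization
#'
#' Each count c in a cell with total T becomes `log(1 + c * scale / T)`
#' (natural log). Cells with zero total are left as zeros. Zeros stay zero,
#' so sparsity is preserved.
#'
#' @param x a [cohort()] or genes x cells count matrix.
#' @param scale library-size scale factor.
#' @return A sparse genes x cells matrix of normalized values.
#' @export
lognormalize <- function(x, scale = 1e4) {
  m <- if (inherits(x, "cohort")) x$counts else x
  m <- methods::as(methods::as(methods::as(m, "dMatrix"), "generalMatrix"),
                   "CsparseMatrix")
  tot <- Matrix::colSums(m)
  fac <- ifelse(tot > 0, scale / tot, 0)
  # scale column j by fac[j], then log1p on the non-zero entries
  cols <- rep(seq_len(ncol(m)), diff(m@p))
  m@x <- log1p(m@x * fac[cols])
  m
}
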