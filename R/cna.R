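#' Parameters for expression-based CNA inference
#'
#' @param window_genes odd number of genes per smoothing window along the
#'   genomic gene order.
#' @param min_cells_expressing genes expressed (count > 0) in fewer than
#'   this many cells are filtered before inference.
#' @param clip_sd half-width of the clipping band, in standard deviations of
#'   the centered residual values.
#' @param center_target value the per-cell median is shifted to.
#' @param viz_cells_per_patient malignant cells per patient kept by
#'   [subsample_for_viz()].
#' @param clip whether the clipped matrix is the default downstream input;
#'   `FALSE` keeps the centered but unclipped values (sensitivity analysis).
#' @return A list of class `cna_params`.
#' @export
cna_params <- function(window_genes = 101, min_cells_expressing = 20,
                       clip_sd = 1.5, center_target = 1.0,
                       viz_cells_per_patient = 100, clip = TRUE) {
  if (window_genes < 1 || window_genes %% 2 != 1)
    stop("window_genes must be odd and >= 1")
  if (min_cells_expressing < 0) stop("min_cells_expressing must be >= 0")
  if (clip_sd <= 0) stop("clip_sd must be > 0")
  structure(list(window_genes = as.integer(window_genes),
                 min_cells_expressing = as.integer(min_cells_expressing),
                 clip_sd = clip_sd, center_target = center_target,
                 viz_cells_per_patient = as.integer(viz_cells_per_patient),
                 clip = clip),
            class = "cna_params")
}

# canonical chromosome order 1..22, X, Y; anything else sorts after
chromosome_rank <- function(chr) {
  lv <- c(as.character(1:22), "X", "Y")
  r <- match(as.character(chr), lv)
  ifelse(is.na(r), length(lv) + 1L, r)
}

#' Sort a gene table by genomic position
#'
#' Orders genes by chromosome (1..22, X, Y, then others) and ascending
#' start coordinate — the 1-D axis along which expression is smoothed.
#'
#' @param genes data.frame with `gene`, `chromosome`, `start`.
#' @return The ordering permutation (integer vector).
#' @export
order_genes <- function(genes) {
  order(chromosome_rank(genes$chromosome), genes$start)
}

#' Filter genes by expression prevalence
#'
#' Removes genes expressed (value > 0) in fewer than
#' `params$min_cells_expressing` cells, preserving gene order.
#'
#' @param m genes x cells matrix (counts or normalized values; the support
#'   is identical).
#' @param params a [cna_params()].
#' @return Logical vector over genes: `TRUE` = retained.
#' @export
filter_genes <- function(m, params = cna_params()) {
  if (nrow(m) == 0 || ncol(m) == 0) stop("empty matrix")
  keep <- Matrix::rowSums(m > 0) >= params$min_cells_expressing
  if (!any(keep)) stop("all genes removed by the expression-prevalence filter")
  as.vector(keep)
}

#' Relative expression against a non-malignant baseline
#'
#' Subtracts from every cell the mean expression of the reference
#' (non-malignant) cells, gene by gene. Reference cells may themselves be
#' profiled; their average deviation is zero by construction.
#'
#' @param m genes x cells normalized matrix.
#' @param reference logical or integer index of reference cells.
#' @return Dense genes x cells matrix of deviations.
#' @export
relative_expression <- function(m, reference) {
  if (is.logical(reference)) reference <- which(reference)
  if (length(reference) == 0) stop("reference cell set is empty")
  m <- as.matrix(m)
  ref_mean <- rowMeans(m[, reference, drop = FALSE])
  m - ref_mean
}

#' Genomic window smoothing
#'
#' Replaces each value by the mean over a window of `window_genes` genes
#' centered on it within its chromosome; windows are truncated (never
#' mirrored) at chromosome ends and never span chromosome boundaries.
#'
#' @param rel genes x cells matrix of relative expression, rows already in
#'   genomic order.
#' @param chromosomes chromosome label per row of `rel`.
#' @param params a [cna_params()].
#' @return Smoothed matrix of the same shape.
#' @export
smooth_windows <- function(rel, chromosomes, params = cna_params()) {
  rel <- as.matrix(rel)
  stopifnot(length(chromosomes) == nrow(rel))
  h <- (params$window_genes - 1L) %/% 2L
  out <- rel
  for (chr in unique(chromosomes)) {
    idx <- which(chromosomes == chr)
    L <- length(idx)
    if (L == 0) { warning("chromosome ", chr, " has no genes; skipped"); next }
    block <- rel[idx, , drop = FALSE]
    cs <- rbind(0, apply(block, 2, cumsum))   # (L+1) x cells
    i <- seq_len(L)
    lo <- pmax(1L, i - h)
    hi <- pmin(L, i + h)
    out[idx, ] <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1)
  }
  out
}

#' Center per cell and clip extreme values
#'
#' Shifts each cell so its median sits at `center_target` (default 1), then
#' clips all values to `center_target +/- clip_sd * sigma`, where sigma is
#' the standard deviation of the centered residuals over the whole matrix.
#' With zero variance the centered matrix is returned unclipped.
#'
#' @param sm smoothed genes x cells matrix.
#' @param params a [cna_params()]; `params$clip = FALSE` skips clipping.
#' @return Matrix of the same shape, per-cell median = `center_target`.
#' @export
center_and_clip <- function(sm, params = cna_params()) {
  sm <- as.matrix(sm)
  if (any(!is.finite(sm))) stop("smoothed matrix must be finite")
  med <- apply(sm, 2, stats::median)
  cent <- sweep(sm, 2, med) + params$center_target
  if (!params$clip) return(cent)
  sigma <- stats::sd(cent - params$center_target)
  if (!is.finite(sigma) || sigma == 0) return(cent)
  pmin(pmax(cent, params$center_target - params$clip_sd * sigma),
       params$center_target + params$clip_sd * sigma)
}

#' Infer relative copy-number profiles from expression
#'
#' Full expression-based CNA inference: sort genes by genomic position
#' (dropping `exclude_chromosomes`), filter lowly expressed genes, subtract
#' the non-malignant reference mean, smooth along the genome with a
#' `window_genes`-gene window, then center each cell at 1 and clip.
#'
#' @param norm genes x cells normalized matrix (see [lognormalize()]).
#' @param genes gene table aligned to `norm` rows (`gene`, `chromosome`,
#'   `start`).
#' @param reference logical/integer index of non-malignant baseline cells.
#' @param params a [cna_params()].
#' @param exclude_chromosomes chromosomes dropped before inference
#'   (mitochondrial genes by default).
#' @return List of class `cna_profile`: `mat` (genes x cells relative
#'   copy-number values centered at 1), `genes` (ordered, filtered table),
#'   `params`.
#' @export
infer_cna <- function(norm, genes, reference, params = cna_params(),
                      exclude_chromosomes = "MT") {
  stopifnot(nrow(norm) == nrow(genes))
  keep_chr <- !genes$chromosome %in% exclude_chromosomes
  norm <- norm[keep_chr, , drop = FALSE]
  genes <- genes[keep_chr, , drop = FALSE]
  ord <- order_genes(genes)
  norm <- norm[ord, , drop = FALSE]
  genes <- genes[ord, , drop = FALSE]
  keep <- filter_genes(norm, params)
  norm <- norm[keep, , drop = FALSE]
  genes <- genes[keep, , drop = FALSE]
  rel <- relative_expression(norm, reference)
  sm <- smooth_windows(rel, genes$chromosome, params)
  mat <- center_and_clip(sm, params)
  rownames(genes) <- NULL
  structure(list(mat = mat, genes = genes, params = params),
            class = "cna_profile")
}

#' Subsample malignant cells for visualization
#'
#' Keeps at most `params$viz_cells_per_patient` malignant cells per patient,
#' sampled without replacement; deterministic given `seed`.
#'
#' @param cna a `cna_profile` from [infer_cna()].
#' @param cells data.frame aligned to the columns of `cna$mat`, with
#'   `patient` and `malignant` columns.
#' @param seed integer seed.
#' @return The `cna_profile` restricted to the sampled malignant cells; the
#'   kept cell table is attached as attribute `cells`.
#' @export
subsample_for_viz <- function(cna, cells, seed = 1L) {
  stopifnot(inherits(cna, "cna_profile"), nrow(cells) == ncol(cna$mat))
  set.seed(seed %% .Machine$integer.max)
  n <- cna$params$viz_cells_per_patient
  keep <- unlist(lapply(split(seq_len(nrow(cells)), cells$patient), function(idx) {
    idx <- idx[cells$malignant[idx]]
    if (length(idx) <= n) idx else sort(sample(idx, n))
  }), use.names = FALSE)
  keep <- sort(keep)
  cna$mat <- cna$mat[, keep, drop = FALSE]
  attr(cna, "cells") <- cells[keep, , drop = FALSE]
  cna
}
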