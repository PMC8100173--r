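#' Canonical marker sets for major NSCLC cell types
#'
#' The ten canonical marker groups used to annotate major cell types in the
#' lung tumor microenvironment, in definition order (used as the tie-break
#' order). "FOLR1" is used as the alveolar folate-receptor marker and
#' "DSG3" as the squamous desmoglein; both are just list entries and can be
#' replaced by supplying a custom marker list.
#'
#' @return Named list: cell type -> character vector of marker gene symbols.
#' @export
default_marker_sets <- function() {
  list(
    "Endothelial cells" = c("CLDN5", "VWF", "PECAM1"),
    "Epithelial cells" = c("CAPS", "SNTN"),
    "Alveolar cells" = c("CLDN18", "AQP4", "FOLR1"),
    "Fibroblasts" = c("COL1A1", "COL1A2", "DCN"),
    "T cells" = c("CD2", "CD3D", "CD3E", "CD3G"),
    "B cells" = c("CD79A", "CD79B"),
    "Myeloid cells" = c("CD14", "LYZ"),
    "Neutrophils" = c("CSF3R", "S100A8", "S100A9"),
    "Follicular dendritic cells" = "FDCSP",
    "Mast cells" = c("GATA2", "TPSAB1", "TPSB2")
  )
}

#' Read marker sets from a two-column TSV
#'
#' @param path TSV with columns `cell_type` and `gene` (one marker per row).
#' @return Named list suitable for [score_clusters()].
#' @export
read_marker_sets <- function(path) {
  tab <- utils::read.delim(path)
  if (!all(c("cell_type", "gene") %in% names(tab)))
    stop("marker file must have columns 'cell_type' and 'gene'")
  split(tab$gene, factor(tab$cell_type, unique(tab$cell_type)))
}

#' Score clusters against marker sets and assign cell types
#'
#' Each marker gene is z-scored across all cells on the normalized matrix;
#' a cluster's score for a cell type is the mean z-score of that type's
#' resolvable markers over the cluster's cells. The highest-scoring type
#' wins; exact ties go to the type defined first in `markers`, with a
#' warning. Marker genes absent from the matrix are skipped with a warning,
#' and a type with no resolvable markers is excluded.
#'
#' @param norm genes x cells normalized matrix with gene rownames.
#' @param clusters cluster label per cell (length = ncol(norm)).
#' @param markers named list, cell type -> marker genes (see
#'   [default_marker_sets()]).
#' @return List of class `cluster_scores`: `scores` (clusters x types
#'   matrix), `assignment` (named character vector cluster -> winning type).
#' @export
score_clusters <- function(norm, clusters, markers = default_marker_sets()) {
  stopifnot(length(clusters) == ncol(norm))
  missing <- setdiff(unique(unlist(markers)), rownames(norm))
  if (length(missing))
    warning("marker gene(s) not in matrix, skipped: ",
            paste(missing, collapse = ", "))
  markers <- lapply(markers, intersect, y = rownames(norm))
  empty <- names(markers)[lengths(markers) == 0]
  if (length(empty)) {
    warning("cell type(s) with no resolvable markers excluded: ",
            paste(empty, collapse = ", "))
    markers <- markers[lengths(markers) > 0]
  }
  if (length(markers) == 0) stop("no resolvable marker sets")

  genes <- unique(unlist(markers))
  m <- as.matrix(norm[genes, , drop = FALSE])
  mu <- rowMeans(m)
  sd_ <- apply(m, 1, stats::sd)
  z <- (m - mu) / ifelse(sd_ > 0, sd_, 1)   # constant genes -> z = 0

  cl <- factor(clusters)
  # cluster means of z-scores, then marker-set means
  cl_mean <- t(apply(z, 1, function(row) tapply(row, cl, mean)))
  if (nlevels(cl) == 1) cl_mean <- matrix(cl_mean, ncol = 1,
                                          dimnames = list(genes, levels(cl)))
  scores <- sapply(markers, function(mk)
    colMeans(cl_mean[mk, , drop = FALSE]))
  if (nlevels(cl) == 1) scores <- matrix(scores, nrow = 1,
                                         dimnames = list(levels(cl), names(markers)))
  winner <- apply(scores, 1, function(s) {
    w <- which(s == max(s))
    if (length(w) > 1)
      warning("tie between types ", paste(names(s)[w], collapse = ", "),
              "; first-defined type chosen", call. = FALSE)
    names(s)[w[1]]
  })
  structure(list(scores = scores,
                 assignment = stats::setNames(winner, rownames(scores))),
            class = "cluster_scores")
}

#' Identify malignant (cancer) clusters
#'
#' A cluster is flagged malignant when it is EPCAM-positive — at least
#' `theta_pos` of its cells have an EPCAM count > 0 — and negative for
#' normal lung epithelial programs: its Epithelial and Alveolar marker
#' scores (from [score_clusters()]) both fall below `theta_neg` on the
#' z-score scale.
#'
#' @param score a `cluster_scores` object.
#' @param counts genes x cells count (or normalized) matrix; positivity is
#'   value > 0.
#' @param clusters cluster label per cell.
#' @param epcam_gene gene symbol of the epithelial cell adhesion marker.
#' @param normal_types marker-score columns that must be low.
#' @param theta_pos minimum EPCAM-positive cell fraction.
#' @param theta_neg maximum normal-epithelial marker score.
#' @return Character vector of malignant cluster ids (possibly empty).
#' @export
identify_cancer_clusters <- function(score, counts, clusters,
                                     epcam_gene = "EPCAM",
                                     normal_types = c("Epithelial cells",
                                                      "Alveolar cells"),
                                     theta_pos = 0.3, theta_neg = 0.5) {
  stopifnot(inherits(score, "cluster_scores"))
  cl_ids <- rownames(score$scores)
  if (length(cl_ids) == 0) return(character(0))
  if (!epcam_gene %in% rownames(counts)) {
    warning("'", epcam_gene, "' not in matrix; no malignant clusters called")
    return(character(0))
  }
  pos <- as.vector(counts[epcam_gene, ] > 0)
  frac <- tapply(pos, factor(clusters, cl_ids), mean)
  normal_types <- intersect(normal_types, colnames(score$scores))
  low_normal <- if (length(normal_types))
    apply(score$scores[, normal_types, drop = FALSE] < theta_neg, 1, all)
  else stats::setNames(rep(TRUE, length(cl_ids)), cl_ids)
  cl_ids[frac[cl_ids] >= theta_pos & low_normal[cl_ids]]
}

#' LUAD/LUSC subtype scores for one patient's malignant cells
#'
#' The LUAD score is the mean, over the adenocarcinoma markers, of the
#' fraction of malignant cells expressing the marker (count > 0); the LUSC
#' score likewise over the squamous markers. Both below `nsclc_cutoff`
#' (fewer than 5% of cells expressing) gives the unclassified label NSCLC;
#' otherwise the higher score wins, ties going to LUAD with a warning.
#'
#' @param counts genes x malignant-cells matrix for a single patient.
#' @param luad_markers,lusc_markers marker gene symbols (TTF-1 is the
#'   protein name of NKX2-1; DSG resolves to DSG3).
#' @param nsclc_cutoff threshold below which both scores mean "unclassified".
#' @return data.frame: `luad_score`, `lusc_score`, `label`.
#' @export
subtype_scores <- function(counts,
                           luad_markers = c("NAPSA", "NKX2-1"),
                           lusc_markers = c("KRT5", "DSG3", "TP63"),
                           nsclc_cutoff = 0.05) {
  if (ncol(counts) == 0) stop("no malignant cells")
  frac <- function(gs) {
    gs <- intersect(gs, rownames(counts))
    if (length(gs) == 0) return(0)
    mean(Matrix::rowMeans(counts[gs, , drop = FALSE] > 0))
  }
  luad <- frac(luad_markers)
  lusc <- frac(lusc_markers)
  label <- if (luad < nsclc_cutoff && lusc < nsclc_cutoff) "NSCLC"
  else if (luad == lusc) {
    warning("tied subtype scores; labeling LUAD (first-defined)", call. = FALSE)
    "LUAD"
  } else if (luad > lusc) "LUAD" else "LUSC"
  data.frame(luad_score = luad, lusc_score = lusc, label = label)
}

#' Classify every patient by LUAD/LUSC marker expression
#'
#' Applies [subtype_scores()] to each patient's malignant cells.
#'
#' @param x a [cohort()] whose `cells` carry `patient` and `malignant`.
#' @param ... passed to [subtype_scores()].
#' @return data.frame: `patient`, `luad_score`, `lusc_score`, `label`,
#'   `n_malignant`.
#' @export
classify_patients <- function(x, ...) {
  stopifnot(inherits(x, "cohort"))
  pats <- unique(x$cells$patient)
  out <- lapply(pats, function(p) {
    idx <- which(x$cells$patient == p & x$cells$malignant)
    if (length(idx) == 0)
      return(data.frame(patient = p, luad_score = NA_real_,
                        lusc_score = NA_real_, label = NA_character_,
                        n_malignant = 0L))
    sc <- subtype_scores(x$counts[, idx, drop = FALSE], ...)
    cbind(patient = p, sc, n_malignant = length(idx))
  })
  do.call(rbind, out)
}
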