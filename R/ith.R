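#' Pairwise Pearson correlations between cells
#'
#' Computes the Pearson correlation coefficient for every unordered pair of
#' cells over their feature profiles. Cells with zero variance (constant
#' profiles) have undefined correlations and are excluded with a warning
#' reporting how many were dropped.
#'
#' @param m features x cells matrix (columns are cells).
#' @return Numeric vector of length choose(n, 2) of correlations in
#'   `[-1, 1]`, ordered column-major over the upper triangle. The number of
#'   excluded constant cells is attached as attribute `n_constant`.
#' @export
pairwise_pearson <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2) stop("need at least 2 features")
  if (ncol(m) < 3) stop("insufficient cells: need at least 3, got ", ncol(m))
  sds <- apply(m, 2, stats::sd)
  const <- sds == 0 | !is.finite(sds)
  if (any(const)) {
    warning(sum(const), " constant cell(s) excluded from pairwise correlations")
    m <- m[, !const, drop = FALSE]
    if (ncol(m) < 3) stop("insufficient cells after removing constant profiles")
  }
  cc <- stats::cor(m)
  r <- cc[upper.tri(cc)]
  r <- pmin(pmax(r, -1), 1)
  attr(r, "n_constant") <- sum(const)
  r
}

#' Intratumor heterogeneity score: IQR of pairwise correlations
#'
#' The heterogeneity score of a distribution of pairwise cell-cell Pearson
#' correlation coefficients is its interquartile range Q3 - Q1, computed
#' with linearly interpolated quantiles ([stats::quantile()] type 7).
#' A homogeneous tumor (all pairs near-perfectly correlated) scores near 0;
#' divergent clones widen the correlation distribution and raise the score.
#'
#' @param correlations numeric vector of pairwise correlation coefficients.
#' @param type quantile algorithm passed to [stats::quantile()].
#' @return Scalar IQR in `[0, 2]`.
#' @export
ith_score <- function(correlations, type = 7) {
  correlations <- as.numeric(correlations)
  if (length(correlations) == 0) stop("empty correlation vector")
  q <- stats::quantile(correlations, c(0.25, 0.75), type = type, names = FALSE)
  q[2] - q[1]
}

#' Per-patient ITH_CNA and ITH_GEX
#'
#' For each patient, restricts to its malignant cells and computes two
#' heterogeneity scores: ITH_CNA on the relative copy-number matrix and
#' ITH_GEX on the log-normalized expression matrix, each as the IQR of all
#' pairwise Pearson correlations ([pairwise_pearson()] then [ith_score()]).
#' Patients with fewer than 3 malignant cells get `NA` scores.
#'
#' @param cna a `cna_profile` from [infer_cna()], or a genes x cells matrix
#'   of relative copy-number values.
#' @param gex genes x cells log-normalized expression matrix with the same
#'   columns (cells) as `cna`.
#' @param cells data.frame aligned to the columns, with `patient` and
#'   `malignant` columns.
#' @return data.frame of class `ith_result`: `patient`, `ith_cna`,
#'   `ith_gex`, `n_malignant`.
#' @export
compute_ith <- function(cna, gex, cells) {
  mat <- if (inherits(cna, "cna_profile")) cna$mat else as.matrix(cna)
  stopifnot(ncol(mat) == nrow(cells), ncol(gex) == nrow(cells))
  pats <- unique(cells$patient)
  res <- lapply(pats, function(p) {
    idx <- which(cells$patient == p & cells$malignant)
    if (length(idx) < 3)
      return(data.frame(patient = p, ith_cna = NA_real_, ith_gex = NA_real_,
                        n_malignant = length(idx)))
    data.frame(patient = p,
               ith_cna = ith_score(pairwise_pearson(mat[, idx, drop = FALSE])),
               ith_gex = ith_score(pairwise_pearson(as.matrix(gex[, idx, drop = FALSE]))),
               n_malignant = length(idx))
  })
  out <- do.call(rbind, res)
  class(out) <- c("ith_result", "data.frame")
  out
}

#' Compare ITH scores between patient groups
#'
#' Two-sided unpaired Wilcoxon rank-sum tests between every pair of patient
#' groups, for each requested score. Exact p-values are used for small
#' tie-free samples, the normal approximation with tie correction otherwise
#' (the [stats::wilcox.test()] defaults). Groups with fewer than 2 patients
#' are skipped with a warning.
#'
#' @param ith an `ith_result` from [compute_ith()] (rows with `NA` score are
#'   dropped per comparison).
#' @param groups named character vector: patient -> group label
#'   (e.g. LUADm / LUADn / LUSCn).
#' @param scores which score columns to test.
#' @return data.frame: `score`, `group1`, `group2`, `n1`, `n2`, `statistic`,
#'   `p_value`.
#' @export
compare_ith_groups <- function(ith, groups,
                               scores = c("ith_cna", "ith_gex")) {
  g <- groups[match(ith$patient, names(groups))]
  lv <- unique(stats::na.omit(g))
  small <- lv[table(factor(g, lv))[lv] < 2]
  if (length(small)) {
    warning("group(s) with < 2 patients skipped: ", paste(small, collapse = ", "))
    lv <- setdiff(lv, small)
  }
  if (length(lv) < 2) stop("need at least 2 groups with >= 2 patients")
  pairs <- utils::combn(lv, 2)
  out <- list()
  for (sc in scores) {
    for (j in seq_len(ncol(pairs))) {
      a <- ith[[sc]][g == pairs[1, j] & !is.na(g)]
      b <- ith[[sc]][g == pairs[2, j] & !is.na(g)]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
      # fully tied samples degenerate to zero variance; no evidence -> p = 1
      p <- if (is.nan(wt$p.value)) 1 else wt$p.value
      out[[length(out) + 1]] <- data.frame(
        score = sc, group1 = pairs[1, j], group2 = pairs[2, j],
        n1 = length(a), n2 = length(b),
        statistic = unname(wt$statistic), p_value = p)
    }
  }
  do.call(rbind, out)
}

#' Per-patient cell-type composition
#'
#' @param cells data.frame with `patient` and `cell_type` columns.
#' @return patients x cell-types matrix of proportions (rows sum to 1).
#' @export
cell_type_composition <- function(cells) {
  tab <- unclass(table(cells$patient, cells$cell_type))
  sweep(tab, 1, rowSums(tab), "/")
}

#' Correlate ITH with cell-type composition across patients
#'
#' Pearson correlation of ITH_GEX (or any score column) against each cell
#' type's proportion across patients; p-values from the two-sided t
#' distribution with n - 2 degrees of freedom ([stats::cor.test()]). Cell
#' types with p < `alpha` are flagged significant.
#'
#' @param ith an `ith_result`.
#' @param composition patients x cell-types proportion matrix (rows must sum
#'   to 1 within 1e-6), e.g. from [cell_type_composition()].
#' @param score which ITH column to correlate.
#' @param alpha significance level for the report flag.
#' @return data.frame: `cell_type`, `r`, `p_value`, `significant`.
#' @export
correlate_ith_composition <- function(ith, composition, score = "ith_gex",
                                      alpha = 0.05) {
  composition <- as.matrix(composition)
  if (any(abs(rowSums(composition) - 1) > 1e-6))
    stop("composition rows must sum to 1")
  common <- intersect(ith$patient, rownames(composition))
  v <- ith[[score]][match(common, ith$patient)]
  ok <- !is.na(v)
  if (sum(ok) < 4) stop("need at least 4 patients with defined ITH scores")
  v <- v[ok]; common <- common[ok]
  out <- lapply(colnames(composition), function(ct) {
    ct_prop <- composition[common, ct]
    if (stats::sd(ct_prop) == 0 || stats::sd(v) == 0)
      return(data.frame(cell_type = ct, r = NA_real_, p_value = NA_real_,
                        significant = FALSE))
    tst <- stats::cor.test(v, ct_prop, method = "pearson")
    data.frame(cell_type = ct, r = unname(tst$estimate),
               p_value = tst$p.value,
               significant = tst$p.value < alpha)
  })
  do.call(rbind, out)
}
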