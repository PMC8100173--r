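#' Configuration for the synthetic NSCLC cohort generator
#'
#' Builds and validates the configuration consumed by [generate_cohort()].
#' The generator draws UMI counts from a negative binomial model in which a
#' cell's mean for gene g is the product of a gene baseline, a cell-type
#' marker multiplier, a malignant-clone copy-number fold at g, any planted
#' ligand-receptor multiplier, and a log-normal per-cell library factor.
#' Copy number therefore acts multiplicatively on expression, the dosage
#' assumption that underlies expression-based CNA inference.
#'
#' @param n_patients number of patients in the cohort.
#' @param genes_per_chromosome named integer vector, chromosome -> number of
#'   genes. Mitochondrial genes are added separately on chromosome "MT".
#' @param n_cells_per_type named integer vector, cell type -> cells per
#'   patient. The type named by `malignant_type` provides the malignant
#'   compartment.
#' @param cell_type_markers named list, cell type -> marker genes upregulated
#'   (by `marker_effect`) in that type. Defaults to the bundled canonical
#'   marker sets restricted to the simulated types, plus EPCAM on the
#'   malignant type.
#' @param malignant_type which entry of `n_cells_per_type` is malignant.
#' @param clones list of copy-number clone profiles; each a data.frame with
#'   columns `chromosome`, `start` (1-based gene index within the
#'   chromosome), `length` (genes) and `fold` (> 0 multiplier). Patient p
#'   uses the first `clones_per_patient[p]` profiles, splitting its
#'   malignant cells equally among them.
#' @param clones_per_patient integer scalar or length-`n_patients` vector.
#'   `NULL` (default) assigns 2 clones to LUSC patients and 1 to LUAD
#'   patients, emulating the higher copy-number heterogeneity of squamous
#'   tumors.
#' @param patient_subtypes character vector of true subtypes ("LUAD"/"LUSC"),
#'   recycled over patients. Subtype marker genes (NAPSA, NKX2-1 for LUAD;
#'   KRT5, DSG3, TP63 for LUSC) are upregulated in malignant cells.
#' @param marker_effect fold upregulation of marker genes in their own type.
#' @param nb_dispersion negative binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param baseline_shape,baseline_scale Gamma parameters for per-gene
#'   baseline means.
#' @param marker_baseline_mean baseline mean of marker/subtype genes in
#'   non-cognate cells.
#' @param lr_baseline_mean baseline mean of ligand/receptor genes; the
#'   default keeps their expressing fraction near 5%, below the 10%
#'   expression floor of the interaction test, so planted signals are
#'   type-specific.
#' @param lr_signals data.frame with columns `ligand`, `receptor`, `sender`,
#'   `receiver`, `effect` of planted ligand-receptor co-expression signals,
#'   or `NULL` for none.
#' @param library_sdlog sdlog of the log-normal per-cell library factor
#'   (meanlog chosen so the factor has mean 1).
#' @param mito_gene_count number of "MT-"-prefixed mitochondrial genes.
#' @param mito_fraction target baseline mitochondrial UMI fraction.
#' @param high_mito_fraction fraction of cells whose mitochondrial means are
#'   scaled by `high_mito_scale`, pushing them past the 30% QC cutoff.
#' @param high_mito_scale multiplier on MT- gene means in high-mito cells.
#' @param seed default seed used by [generate_cohort()] when none is given.
#'
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 12,
                          genes_per_chromosome = stats::setNames(rep(250L, 6), as.character(1:6)),
                          n_cells_per_type = c("Cancer" = 200L, "T cells" = 120L,
                                               "Myeloid cells" = 100L, "Fibroblasts" = 60L,
                                               "Epithelial cells" = 50L, "Neutrophils" = 50L),
                          cell_type_markers = NULL,
                          malignant_type = "Cancer",
                          clones = list(
                            data.frame(chromosome = "1", start = 51L, length = 150L, fold = 2.0),
                            data.frame(chromosome = "2", start = 51L, length = 150L, fold = 0.5)
                          ),
                          clones_per_patient = NULL,
                          patient_subtypes = c("LUAD", "LUSC"),
                          marker_effect = 8,
                          nb_dispersion = 0.5,
                          baseline_shape = 2,
                          baseline_scale = 0.5,
                          marker_baseline_mean = 0.1,
                          lr_baseline_mean = 0.05,
                          lr_signals = data.frame(
                            ligand = c("CXCL8", "CXCL12"),
                            receptor = c("CXCR2", "CXCR4"),
                            sender = c("Cancer", "Fibroblasts"),
                            receiver = c("Neutrophils", "T cells"),
                            effect = c(8, 8)
                          ),
                          library_sdlog = 0.35,
                          mito_gene_count = 13,
                          mito_fraction = 0.05,
                          high_mito_fraction = 0.05,
                          high_mito_scale = 10,
                          seed = 1L) {
  if (n_patients < 1) stop("n_patients must be >= 1")
  if (is.null(names(genes_per_chromosome)))
    stop("genes_per_chromosome must be a named vector")
  if (any(genes_per_chromosome < 1)) stop("each chromosome needs >= 1 gene")
  if (any(n_cells_per_type < 0)) stop("cell counts must be >= 0")
  if (sum(n_cells_per_type) == 0) stop("zero-cell patients are not allowed")
  if (!malignant_type %in% names(n_cells_per_type))
    stop("malignant_type '", malignant_type, "' not in n_cells_per_type")
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0")

  patient_subtypes <- rep_len(patient_subtypes, n_patients)
  if (is.null(clones_per_patient))
    clones_per_patient <- ifelse(patient_subtypes == "LUSC", 2L, 1L)
  clones_per_patient <- rep_len(as.integer(clones_per_patient), n_patients)
  if (any(clones_per_patient < 1)) stop("clones_per_patient must be >= 1")
  if (max(clones_per_patient) > length(clones))
    stop("clones_per_patient exceeds the number of clone profiles (", length(clones), ")")

  for (k in seq_along(clones)) {
    seg <- clones[[k]]
    need <- c("chromosome", "start", "length", "fold")
    if (!all(need %in% names(seg)))
      stop("clone ", k, ": segments need columns ", paste(need, collapse = ", "))
    if (any(seg$fold <= 0)) stop("clone ", k, ": fold-changes must be > 0")
    if (any(seg$start < 1) || any(seg$length < 1))
      stop("clone ", k, ": segment start/length must be >= 1")
    for (chr in unique(seg$chromosome)) {
      if (!chr %in% names(genes_per_chromosome))
        stop("clone ", k, ": unknown chromosome '", chr, "'")
      s <- seg[seg$chromosome == chr, , drop = FALSE]
      if (any(s$start + s$length - 1 > genes_per_chromosome[[chr]]))
        stop("clone ", k, ": segment exceeds chromosome '", chr, "' gene range")
      if (nrow(s) > 1) {
        s <- s[order(s$start), , drop = FALSE]
        if (any(s$start[-1] <= (s$start + s$length - 1)[-nrow(s)]))
          stop("clone ", k, ": overlapping segments on chromosome '", chr, "'")
      }
    }
  }

  if (is.null(cell_type_markers)) {
    ms <- default_marker_sets()
    keep <- intersect(names(ms), names(n_cells_per_type))
    cell_type_markers <- ms[keep]
    cell_type_markers[[malignant_type]] <- "EPCAM"
  }

  if (!is.null(lr_signals)) {
    bad <- setdiff(unique(c(lr_signals$sender, lr_signals$receiver)),
                   names(n_cells_per_type))
    if (length(bad)) stop("lr_signals reference unknown cell type: ", bad[1])
    if (any(lr_signals$effect <= 0)) stop("lr_signals effects must be > 0")
  }

  structure(list(
    n_patients = as.integer(n_patients),
    genes_per_chromosome = genes_per_chromosome,
    n_cells_per_type = n_cells_per_type,
    cell_type_markers = cell_type_markers,
    malignant_type = malignant_type,
    clones = clones,
    clones_per_patient = clones_per_patient,
    patient_subtypes = patient_subtypes,
    marker_effect = marker_effect,
    nb_dispersion = nb_dispersion,
    baseline_shape = baseline_shape,
    baseline_scale = baseline_scale,
    marker_baseline_mean = marker_baseline_mean,
    lr_baseline_mean = lr_baseline_mean,
    lr_signals = lr_signals,
    library_sdlog = library_sdlog,
    mito_gene_count = as.integer(mito_gene_count),
    mito_fraction = mito_fraction,
    high_mito_fraction = high_mito_fraction,
    high_mito_scale = high_mito_scale,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

mt_gene_names <- function(n) {
  base <- c("MT-ND1", "MT-ND2", "MT-CO1", "MT-CO2", "MT-ATP8", "MT-ATP6",
            "MT-CO3", "MT-ND3", "MT-ND4L", "MT-ND4", "MT-ND5", "MT-ND6", "MT-CYB")
  if (n <= length(base)) base[seq_len(n)] else c(base, paste0("MT-G", seq_len(n - length(base))))
}

# Lay out the gene universe: generic genes per chromosome with special
# (marker / subtype / ligand-receptor) symbols substituted at the tail of
# each chromosome, round-robin, so default CNA segments do not cover them.
build_gene_universe <- function(config) {
  chrs <- names(config$genes_per_chromosome)
  genes <- do.call(rbind, lapply(chrs, function(chr) {
    n <- config$genes_per_chromosome[[chr]]
    data.frame(gene = sprintf("G%s-%04d", chr, seq_len(n)),
               chromosome = chr, start = seq_len(n) * 1e5)
  }))
  specials <- unique(c(unlist(config$cell_type_markers, use.names = FALSE),
                       "NAPSA", "NKX2-1", "KRT5", "DSG3", "TP63",
                       if (!is.null(config$lr_signals))
                         c(config$lr_signals$ligand, config$lr_signals$receptor)))
  if (length(specials) > nrow(genes))
    stop("gene universe too small for the requested special genes")
  # positions: last index of chr1, last of chr2, ..., then second-to-last ...
  ends <- cumsum(config$genes_per_chromosome)
  slot <- unlist(lapply(0:(ceiling(length(specials) / length(chrs)) - 1),
                        function(k) ends - k))
  slot <- slot[slot > 0][seq_along(specials)]
  genes$gene[slot] <- specials
  if (config$mito_gene_count > 0) {
    mito <- data.frame(gene = mt_gene_names(config$mito_gene_count),
                       chromosome = "MT",
                       start = seq_len(config$mito_gene_count) * 1e3)
    genes <- rbind(genes, mito)
  }
  rownames(genes) <- NULL
  genes
}

#' Generate a synthetic multi-patient cohort with known ground truth
#'
#' Draws one UMI count matrix per patient under the model described in
#' [cohort_config()] and returns them combined in a single [cohort()]
#' together with the ground truth (cell types, clones, malignancy, true
#' patient subtypes and per-clone copy-number folds).
#'
#' Reproducibility: all randomness derives from the single integer `seed`.
#' Gene baselines use the stream seeded with `seed` itself; patient p uses
#' an independent stream seeded with `(seed + 9973 * p) mod 2^31`. Identical
#' config + seed therefore give byte-identical output, and patient p's data
#' do not depend on how many patients follow it.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return A list of class `sim_cohort` with elements:
#'   \describe{
#'     \item{cohort}{a [cohort()]; `cells` carries `cell_type`, `cluster`
#'       (ground-truth type used as a precomputed clustering), `clone`,
#'       `malignant`.}
#'     \item{truth}{list: `subtype` (named by patient), `group`
#'       (LUADm/LUADn/LUSCn), `gene_means` (baseline negative binomial mean
#'       per gene), `clone_folds` (clones x genes fold matrix),
#'       `clones_per_patient`.}
#'     \item{config}{the config used.}
#'   }
#' @export
generate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  genes <- build_gene_universe(config)
  n_genes <- nrow(genes)
  is_mito <- genes$chromosome == "MT"

  set.seed(seed %% .Machine$integer.max)
  base_mean <- stats::rgamma(n_genes, shape = config$baseline_shape,
                             scale = config$baseline_scale)
  base_mean <- pmax(base_mean, 1e-3)
  specials <- unique(c(unlist(config$cell_type_markers, use.names = FALSE),
                       "NAPSA", "NKX2-1", "KRT5", "DSG3", "TP63"))
  base_mean[genes$gene %in% specials] <- config$marker_baseline_mean
  if (!is.null(config$lr_signals)) {
    lrg <- unique(c(config$lr_signals$ligand, config$lr_signals$receptor))
    base_mean[genes$gene %in% lrg] <- config$lr_baseline_mean
  }
  if (any(is_mito)) {
    target <- config$mito_fraction / (1 - config$mito_fraction) *
      sum(base_mean[!is_mito]) / sum(is_mito)
    base_mean[is_mito] <- target
  }

  # per-type multiplier matrix (genes x types)
  types <- names(config$n_cells_per_type)
  type_mult <- matrix(1, n_genes, length(types), dimnames = list(genes$gene, types))
  for (ty in names(config$cell_type_markers)) {
    mk <- intersect(config$cell_type_markers[[ty]], genes$gene)
    if (length(mk) && ty %in% types) type_mult[mk, ty] <- config$marker_effect
  }

  # clone fold profiles over the full gene axis
  n_clones <- length(config$clones)
  clone_folds <- matrix(1, max(n_clones, 1), n_genes,
                        dimnames = list(if (n_clones) paste0("clone", seq_len(n_clones)),
                                        genes$gene))
  for (k in seq_len(n_clones)) {
    seg <- config$clones[[k]]
    for (i in seq_len(nrow(seg))) {
      chr_idx <- which(genes$chromosome == seg$chromosome[i])
      span <- chr_idx[seg$start[i]:(seg$start[i] + seg$length[i] - 1)]
      clone_folds[k, span] <- seg$fold[i]
    }
  }

  subtype_mark <- list(LUAD = c("NAPSA", "NKX2-1"), LUSC = c("KRT5", "DSG3", "TP63"))
  size <- 1 / config$nb_dispersion
  pat_ids <- sprintf("P%02d", seq_len(config$n_patients))

  mats <- vector("list", config$n_patients)
  cell_tabs <- vector("list", config$n_patients)
  for (p in seq_len(config$n_patients)) {
    set.seed((seed + 9973 * p) %% .Machine$integer.max)
    n_per <- config$n_cells_per_type
    n_cells <- sum(n_per)
    cell_type <- rep(names(n_per), n_per)
    malignant <- cell_type == config$malignant_type
    clone <- rep(NA_character_, n_cells)
    kp <- config$clones_per_patient[p]
    clone[malignant] <- paste0("clone", rep_len(seq_len(kp), sum(malignant)))

    mu <- base_mean * type_mult[, cell_type, drop = FALSE]
    # malignant cells: clone folds and subtype markers
    st <- config$patient_subtypes[p]
    sm <- intersect(subtype_mark[[st]], genes$gene)
    for (k in seq_len(kp)) {
      idx <- which(!is.na(clone) & clone == paste0("clone", k))
      mu[, idx] <- mu[, idx] * clone_folds[k, ]
    }
    mu[sm, malignant] <- mu[sm, malignant, drop = FALSE] * config$marker_effect
    # planted ligand-receptor co-expression
    if (!is.null(config$lr_signals)) {
      for (i in seq_len(nrow(config$lr_signals))) {
        s <- config$lr_signals[i, ]
        if (s$ligand %in% genes$gene)
          mu[s$ligand, cell_type == s$sender] <-
            mu[s$ligand, cell_type == s$sender] * s$effect
        if (s$receptor %in% genes$gene)
          mu[s$receptor, cell_type == s$receiver] <-
            mu[s$receptor, cell_type == s$receiver] * s$effect
      }
    }
    # high-mito cells and library factors
    high <- stats::runif(n_cells) < config$high_mito_fraction
    if (any(is_mito) && any(high))
      mu[is_mito, high] <- mu[is_mito, high, drop = FALSE] * config$high_mito_scale
    lib <- stats::rlnorm(n_cells, meanlog = -config$library_sdlog^2 / 2,
                         sdlog = config$library_sdlog)
    mu <- sweep(mu, 2, lib, "*")

    counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu), size = size),
                     nrow = n_genes)
    mats[[p]] <- Matrix::Matrix(counts, sparse = TRUE)
    cell_tabs[[p]] <- data.frame(
      cell_id = sprintf("%s_C%04d", pat_ids[p], seq_len(n_cells)),
      patient = pat_ids[p], cell_type = cell_type, cluster = cell_type,
      clone = clone, malignant = malignant)
  }

  counts <- do.call(cbind, mats)
  cells <- do.call(rbind, cell_tabs)
  subtype <- stats::setNames(config$patient_subtypes, pat_ids)
  group <- ifelse(subtype == "LUSC", "LUSCn",
                  ifelse(seq_along(subtype) %% 2 == 1, "LUADm", "LUADn"))
  # alternate LUADm/LUADn among the LUAD patients
  luad <- which(subtype == "LUAD")
  group[luad] <- rep_len(c("LUADm", "LUADn"), length(luad))
  names(group) <- pat_ids

  structure(list(cohort = cohort(counts, cells, genes),
                 truth = list(subtype = subtype, group = group,
                              gene_means = stats::setNames(base_mean, genes$gene),
                              clone_folds = clone_folds,
                              clones_per_patient = stats::setNames(
                                config$clones_per_patient, pat_ids)),
                 config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("synthetic cohort\n")
  print(x$cohort)
  cat("subtypes:", paste(sprintf("%s=%s", names(x$truth$subtype), x$truth$subtype),
                         collapse = " "), "\n")
  invisible(x)
}

#' Plant a ligand-receptor co-expression signal into realized counts
#'
#' Multiplies the ligand's counts in all sender-type cells and the
#' receptor's counts in all receiver-type cells by `effect` (rounded back to
#' integers), leaving every other entry untouched. With `effect = 1` the
#' cohort is returned unchanged. Use the `lr_signals` field of
#' [cohort_config()] instead to plant signals at the level of the negative
#' binomial mean before sampling.
#'
#' @param x a [cohort()] whose `cells` carry a `cell_type` column.
#' @param ligand,receptor gene symbols present in the cohort.
#' @param sender,receiver cell types present in the cohort.
#' @param effect multiplier (> 0).
#' @return The modified [cohort()].
#' @export
plant_lr_signal <- function(x, ligand, receptor, sender, receiver, effect) {
  stopifnot(inherits(x, "cohort"))
  if (effect <= 0) stop("effect must be > 0")
  for (g in c(ligand, receptor))
    if (!g %in% x$genes$gene) stop("unknown gene: '", g, "'")
  for (ty in c(sender, receiver))
    if (!ty %in% x$cells$cell_type) stop("unknown cell type: '", ty, "'")
  if (effect == 1) return(x)
  m <- as.matrix(x$counts[c(ligand, receptor), , drop = FALSE])
  m[ligand, x$cells$cell_type == sender] <-
    round(m[ligand, x$cells$cell_type == sender] * effect)
  m[receptor, x$cells$cell_type == receiver] <-
    round(m[receptor, x$cells$cell_type == receiver] * effect)
  x$counts[c(ligand, receptor), ] <- m
  x
}
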