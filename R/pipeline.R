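#' Pipeline configuration
#'
#' Bundles every stage's parameters for [run_pipeline()]. In `"simulated"`
#' mode the cohort comes from [generate_cohort()]; in `"user"` mode it is
#' read from `input_dir` (a directory written by [write_cohort()], whose
#' `genes.tsv` must carry `chromosome` and `start` columns).
#'
#' @param mode `"simulated"` or `"user"`.
#' @param sim a [cohort_config()] (simulated mode).
#' @param input_dir cohort directory (user mode).
#' @param thresholds a [qc_thresholds()].
#' @param cna a [cna_params()].
#' @param markers marker list for [score_clusters()].
#' @param lr_pairs ligand-receptor table ([default_lr_pairs()]).
#' @param n_perm,alpha,rank_max,min_patients interaction-test settings (see
#'   [lr_permutation_test()], [lr_rank()], [aggregate_lr()]).
#' @param min_interactions node filter of [build_celltype_network()]; the
#'   published analysis used 500, small synthetic cohorts need a smaller
#'   value.
#' @param groups optional named character vector patient -> group label; in
#'   simulated mode the ground-truth groups are used when `NULL`.
#' @param out_dir optional output directory for stage TSVs and the JSON run
#'   manifest.
#' @param seed global integer seed; stage s uses `seed + offset(s)` (offsets
#'   documented in [run_pipeline()]).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulated", "user"),
                            sim = cohort_config(),
                            input_dir = NULL,
                            thresholds = qc_thresholds(),
                            cna = cna_params(),
                            markers = default_marker_sets(),
                            lr_pairs = default_lr_pairs(),
                            n_perm = 1000, alpha = 0.05, rank_max = 0.1,
                            min_patients = 6, min_interactions = 5,
                            groups = NULL, out_dir = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "user") {
    if (is.null(input_dir)) stop("user mode requires input_dir")
    for (f in c("cells.tsv", "genes.tsv"))
      if (!file.exists(file.path(input_dir, f)))
        stop("missing input file: ", file.path(input_dir, f))
    g <- utils::read.delim(file.path(input_dir, "genes.tsv"), nrows = 1)
    if (!all(c("chromosome", "start") %in% names(g)))
      stop("genes.tsv must provide 'chromosome' and 'start' for CNA inference")
  }
  structure(list(mode = mode, sim = sim, input_dir = input_dir,
                 thresholds = thresholds, cna = cna, markers = markers,
                 lr_pairs = lr_pairs, n_perm = n_perm, alpha = alpha,
                 rank_max = rank_max, min_patients = min_patients,
                 min_interactions = min_interactions, groups = groups,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Recognized top-level keys mirror the arguments of [pipeline_config()];
#' `sim`, `thresholds` and `cna` may be mappings passed to their
#' constructors.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (k in c("mode", "input_dir", "n_perm", "alpha", "rank_max",
              "min_patients", "min_interactions", "out_dir", "seed"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  if (!is.null(y$sim)) args$sim <- do.call(cohort_config, y$sim)
  if (!is.null(y$thresholds)) args$thresholds <- do.call(qc_thresholds, y$thresholds)
  if (!is.null(y$cna)) args$cna <- do.call(cna_params, y$cna)
  if (!is.null(y$markers_file)) args$markers <- read_marker_sets(y$markers_file)
  if (!is.null(y$lr_pairs_file)) args$lr_pairs <- default_lr_pairs(y$lr_pairs_file)
  if (!is.null(y$groups)) args$groups <- unlist(y$groups)
  do.call(pipeline_config, args)
}

#' Run the full heterogeneity pipeline
#'
#' Orchestrates simulate/load -> QC -> normalization -> marker cell typing
#' and cancer-cluster identification -> LUAD/LUSC classification -> CNA
#' inference -> ITH scoring -> group comparisons and composition
#' correlations -> per-patient ligand-receptor testing -> cross-patient
#' aggregation and networks.
#'
#' Stage seeds derive from the global seed: simulation uses `seed`,
#' patient p's permutation test uses `seed + 101 * p`, visualization
#' subsampling uses `seed + 7`. Identical config and seed give identical
#' results.
#'
#' @param config a [pipeline_config()].
#' @return List of class `pipeline_result` with elements `cohort_table`
#'   (one row per patient: subtype scores and label, group, ITH scores,
#'   cell-type proportions), `qc`, `cluster_scores`, `malignant_clusters`,
#'   `subtype`, `ith`, `group_tests`, `composition`, `composition_cor`,
#'   `interactions` (per-patient tests after rank filtering), `retained`
#'   (aggregated triples), `celltype_network`, `gene_network`, `log`
#'   (stage records), and in simulated mode `truth`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- list(seed = config$seed, started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  truth <- NULL
  co <- stage("input", {
    if (config$mode == "simulated") {
      sim <- generate_cohort(config$sim, seed = config$seed)
      truth <- sim$truth
      sim$cohort
    } else read_cohort(config$input_dir)
  })
  log$n_cells_input <- ncol(co$counts)

  co <- stage("qc", {
    qc_tab <- compute_qc(co)
    out <- filter_cells(co, qc_tab, config$thresholds)
    log$qc <- list(n_removed = attr(out, "n_removed"), n_kept = attr(out, "n_kept"))
    attr(out, "qc_table") <- qc_tab
    out
  })
  qc_tab <- attr(co, "qc_table")
  norm <- stage("normalize", lognormalize(co))

  cl <- co$cells$cluster
  if (is.null(cl)) stop("pipeline stage 'celltype' failed: no cluster labels; ",
                        "supply a 'cluster' column (clustering itself is pluggable)")
  cs <- stage("celltype", score_clusters(norm, cl, config$markers))
  mal_clusters <- stage("cancer_clusters",
                        identify_cancer_clusters(cs, co$counts, cl))
  co$cells$malignant <- cl %in% mal_clusters
  # malignant clusters are labeled as cancer cells, not as their best
  # (necessarily poor) match among the normal marker programs
  assigned <- cs$assignment
  assigned[names(assigned) %in% mal_clusters] <- "Cancer cells"
  co$cells$cell_type_assigned <- unname(assigned[as.character(cl)])

  subtype <- stage("subtype", classify_patients(co))

  cna <- stage("cna", infer_cna(norm, co$genes, reference = !co$cells$malignant,
                                params = config$cna))
  ith <- stage("ith", compute_ith(cna, norm, co$cells))

  groups <- config$groups
  if (is.null(groups) && !is.null(truth)) groups <- truth$group
  group_tests <- if (!is.null(groups) &&
                     length(unique(groups[unique(co$cells$patient)])) >= 2)
    stage("group_tests", tryCatch(compare_ith_groups(ith, groups),
                                  error = function(e) NULL))
  else NULL

  comp <- stage("composition",
                cell_type_composition(data.frame(patient = co$cells$patient,
                                                 cell_type = co$cells$cell_type_assigned)))
  comp_cor <- tryCatch(correlate_ith_composition(ith, comp),
                       error = function(e) NULL)

  per_pat <- stage("interactions", {
    pats <- unique(co$cells$patient)
    res <- lapply(seq_along(pats), function(i) {
      idx <- co$cells$patient == pats[i]
      t <- lr_permutation_test(norm[, idx, drop = FALSE],
                               co$cells$cell_type_assigned[idx],
                               pairs = config$lr_pairs,
                               n_perm = config$n_perm,
                               seed = (config$seed + 101L * i) %% .Machine$integer.max,
                               alpha = config$alpha)
      cbind(patient = pats[i], lr_rank(t, config$rank_max))
    })
    do.call(rbind, res)
  })
  retained <- stage("aggregate",
                    aggregate_lr(per_pat, min_patients = config$min_patients,
                                 groups = groups))
  ct_net <- stage("celltype_network",
                  suppressWarnings(build_celltype_network(retained,
                                                          config$min_interactions)))
  type_means <- {
    fac <- factor(co$cells$cell_type_assigned)
    lr_genes <- intersect(unique(c(config$lr_pairs$ligand, config$lr_pairs$receptor)),
                          rownames(norm))
    sub <- as.matrix(norm[lr_genes, , drop = FALSE])
    sapply(levels(fac), function(tp) rowMeans(sub[, fac == tp, drop = FALSE]))
  }
  g_net <- stage("gene_network", build_gene_network(retained, type_means))

  cohort_table <- data.frame(patient = unique(co$cells$patient))
  cohort_table <- merge(cohort_table, subtype, by = "patient", all.x = TRUE)
  cohort_table <- merge(cohort_table,
                        as.data.frame(ith)[c("patient", "ith_cna", "ith_gex")],
                        by = "patient", all.x = TRUE)
  if (!is.null(groups)) cohort_table$group <- unname(groups[cohort_table$patient])
  cohort_table <- cbind(cohort_table,
                        as.data.frame(comp[cohort_table$patient, , drop = FALSE],
                                      row.names = NULL))
  cohort_table <- cohort_table[order(cohort_table$patient), , drop = FALSE]
  rownames(cohort_table) <- NULL

  res <- structure(list(cohort_table = cohort_table, qc = qc_tab,
                        cluster_scores = cs, malignant_clusters = mal_clusters,
                        subtype = subtype, ith = ith, group_tests = group_tests,
                        composition = comp, composition_cor = comp_cor,
                        interactions = per_pat, retained = retained,
                        celltype_network = ct_net, gene_network = g_net,
                        truth = truth, log = log),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_result(res, config)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline result: %d patients, %d cells post-QC\n",
              nrow(x$cohort_table), x$log$qc$n_kept))
  cat(sprintf("malignant clusters: %s\n",
              paste(x$malignant_clusters, collapse = ", ")))
  cat(sprintf("retained interactions: %d triples\n", nrow(x$retained)))
  invisible(x)
}

write_pipeline_result <- function(res, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name)
    utils::write.table(df, file.path(config$out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  w(res$cohort_table, "cohort_table.tsv")
  w(res$qc, "qc.tsv")
  w(as.data.frame(res$ith), "ith.tsv")
  w(res$subtype, "subtype.tsv")
  if (!is.null(res$group_tests)) w(res$group_tests, "group_tests.tsv")
  if (!is.null(res$composition_cor)) w(res$composition_cor, "composition_correlation.tsv")
  w(res$interactions, "interactions.tsv")
  w(res$retained, "interactions_retained.tsv")
  w(res$celltype_network$edges, "celltype_network_edges.tsv")
  manifest <- list(seed = config$seed, mode = config$mode,
                   package_version = as.character(utils::packageVersion("scITH")),
                   n_cells_input = res$log$n_cells_input, qc = res$log$qc,
                   params = list(thresholds = unclass(config$thresholds),
                                 cna = unclass(config$cna),
                                 n_perm = config$n_perm, alpha = config$alpha,
                                 rank_max = config$rank_max,
                                 min_patients = config$min_patients))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(NULL)
}
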