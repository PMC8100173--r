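# Small simulation configs used across tests (kept tiny for speed).

tiny_config <- function(n_patients = 1,
                        n_cells = c("Cancer" = 60L, "T cells" = 50L,
                                    "Myeloid cells" = 40L),
                        clones = list(data.frame(chromosome = "1", start = 21L,
                                                 length = 60L, fold = 2.0)),
                        clones_per_patient = 1,
                        genes_per_chr = 100L, n_chr = 3,
                        lr_signals = data.frame(
                          ligand = "CXCL8", receptor = "CXCR2",
                          sender = "Cancer", receiver = "T cells",
                          effect = 8), ...) {
  cohort_config(
    n_patients = n_patients,
    genes_per_chromosome = stats::setNames(rep(genes_per_chr, n_chr),
                                           as.character(seq_len(n_chr))),
    n_cells_per_type = n_cells,
    clones = clones,
    clones_per_patient = clones_per_patient,
    lr_signals = lr_signals,
    ...
  )
}

# cohort from explicit dense counts, for hand-built fixtures
manual_cohort <- function(counts, patient = "P01", chromosomes = NULL,
                          cell_type = NULL, malignant = NULL) {
  ng <- nrow(counts); nc <- ncol(counts)
  genes <- data.frame(
    gene = if (!is.null(rownames(counts))) rownames(counts) else sprintf("g%03d", 1:ng),
    chromosome = if (is.null(chromosomes)) rep("1", ng) else chromosomes,
    start = seq_len(ng))
  cells <- data.frame(
    cell_id = if (!is.null(colnames(counts))) colnames(counts) else sprintf("c%03d", 1:nc),
    patient = patient)
  if (!is.null(cell_type)) { cells$cell_type <- cell_type; cells$cluster <- cell_type }
  if (!is.null(malignant)) cells$malignant <- malignant
  cohort(counts, cells, genes)
}
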