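test_that("identical config and seed give byte-identical cohorts", {
  cfg <- tiny_config()
  a <- generate_cohort(cfg, seed = 11)
  b <- generate_cohort(cfg, seed = 11)
  expect_identical(a$cohort$counts, b$cohort$counts)
  expect_identical(a$cohort$cells, b$cohort$cells)
  c <- generate_cohort(cfg, seed = 12)
  expect_false(identical(a$cohort$counts, c$cohort$counts))
})

test_that("neutral copy state gives malignant and reference cells the same means", {
  cfg <- tiny_config(
    n_cells = c("Cancer" = 500L, "T cells" = 500L),
    clones = list(data.frame(chromosome = "1", start = 21L, length = 60L, fold = 1.0)),
    lr_signals = NULL, library_sdlog = 1e-8)
  sim <- generate_cohort(cfg, seed = 3)
  co <- sim$cohort
  # compare on non-marker genes (markers differ by design)
  markers <- unique(c(unlist(cfg$cell_type_markers), "NAPSA", "NKX2-1",
                      "KRT5", "DSG3", "TP63"))
  plain <- !(co$genes$gene %in% markers) & co$genes$chromosome != "MT"
  mal_mean <- Matrix::rowMeans(co$counts[plain, co$cells$malignant])
  ref_mean <- Matrix::rowMeans(co$counts[plain, !co$cells$malignant])
  ok <- mal_mean + ref_mean > 0.5
  ratio <- (mal_mean[ok] + 0.01) / (ref_mean[ok] + 0.01)
  expect_lt(abs(median(ratio) - 1), 0.05)
})

test_that("a fold-2 segment roughly doubles malignant means over the segment", {
  cfg <- tiny_config(
    n_cells = c("Cancer" = 500L, "T cells" = 500L),
    genes_per_chr = 300L, n_chr = 1,
    clones = list(data.frame(chromosome = "1", start = 100L, length = 150L, fold = 2.0)),
    lr_signals = NULL)
  sim <- generate_cohort(cfg, seed = 5)
  co <- sim$cohort
  inside <- which(co$genes$chromosome == "1")[100:249]
  mal <- Matrix::rowMeans(co$counts[inside, co$cells$malignant])
  ref <- Matrix::rowMeans(co$counts[inside, !co$cells$malignant])
  ok <- ref >= 0.2
  expect_gt(sum(ok), 100)
  expect_lt(abs(median(mal[ok] / ref[ok]) - 2), 0.2)
})

test_that("per-gene empirical means track configured means at 1000 cells", {
  cfg <- tiny_config(n_cells = c("T cells" = 500L, "Myeloid cells" = 500L,
                                 "Cancer" = 0L),
                     lr_signals = NULL, library_sdlog = 1e-8,
                     high_mito_fraction = 0)
  sim <- generate_cohort(cfg, seed = 9)
  mu <- sim$truth$gene_means
  # restrict to plain genes (no marker upregulation applies to these cells)
  markers <- unique(unlist(cfg$cell_type_markers))
  plain <- !(sim$cohort$genes$gene %in% markers) & mu >= 1
  expect_gt(sum(plain), 50)
  emp <- Matrix::rowMeans(sim$cohort$counts)[plain]
  relerr <- abs(emp - mu[plain]) / mu[plain]
  expect_lt(stats::quantile(relerr, 0.95), 0.10)
  expect_lt(median(relerr), 0.05)
})

test_that("ground truth is internally consistent", {
  cfg <- tiny_config(n_patients = 3, clones_per_patient = 1)
  sim <- generate_cohort(cfg, seed = 2)
  cells <- sim$cohort$cells
  expect_true(all(is.na(cells$clone) == !cells$malignant))
  expect_equal(sum(cells$malignant),
               sum(cells$cell_type == cfg$malignant_type))
  expect_equal(nrow(cells), 3 * sum(cfg$n_cells_per_type))
  expect_setequal(names(sim$truth$subtype), unique(cells$patient))
})

test_that("invalid configs are rejected", {
  expect_error(tiny_config(clones = list(
    data.frame(chromosome = "1", start = 10L, length = 50L, fold = c(2, 0.5),
               stringsAsFactors = FALSE)[c(1, 1), ])), "overlap")
  expect_error(tiny_config(clones = list(
    data.frame(chromosome = "9", start = 1L, length = 10L, fold = 2))),
    "unknown chromosome")
  expect_error(tiny_config(clones = list(
    data.frame(chromosome = "1", start = 90L, length = 50L, fold = 2))),
    "exceeds")
  expect_error(tiny_config(clones = list(
    data.frame(chromosome = "1", start = 1L, length = 10L, fold = -1))),
    "fold")
  expect_error(cohort_config(n_cells_per_type = c(Cancer = 0L)), "zero-cell")
})

test_that("mitochondrial genes are emitted with MT- prefix and high-mito cells exist", {
  cfg <- tiny_config(n_cells = c("Cancer" = 200L, "T cells" = 200L),
                     high_mito_fraction = 0.2)
  sim <- generate_cohort(cfg, seed = 21)
  expect_equal(sum(startsWith(sim$cohort$genes$gene, "MT-")), cfg$mito_gene_count)
  qc <- compute_qc(sim$cohort)
  expect_gt(sum(qc$mito_fraction > 0.3), 0)      # some cells exercise the QC cut
  expect_gt(mean(qc$mito_fraction < 0.3), 0.5)   # most do not
})

test_that("plant_lr_signal scales only the targeted entries", {
  cfg <- tiny_config()
  co <- generate_cohort(cfg, seed = 4)$cohort
  expect_identical(plant_lr_signal(co, "CXCL8", "CXCR2", "Cancer", "T cells", 1),
                   co)
  out <- plant_lr_signal(co, "CXCL8", "CXCR2", "Cancer", "T cells", 10)
  sender <- co$cells$cell_type == "Cancer"
  expect_gt(mean(out$counts["CXCL8", sender]), mean(co$counts["CXCL8", sender]))
  expect_equal(out$counts["CXCL8", !sender], co$counts["CXCL8", !sender])
  other <- setdiff(rownames(co$counts), c("CXCL8", "CXCR2"))
  expect_equal(out$counts[other, ], co$counts[other, ])
  expect_error(plant_lr_signal(co, "CXCL8", "CXCR2", "X", "T cells", 2),
               "unknown cell type: 'X'")
  expect_error(plant_lr_signal(co, "NOPE", "CXCR2", "Cancer", "T cells", 2),
               "unknown gene: 'NOPE'")
})
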