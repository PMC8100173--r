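test_that("pairwise correlations match the covariance-formula oracle", {
  set.seed(5)
  for (i in 1:20) {
    m <- matrix(stats::rnorm(50), 10, 5)
    expect_equal(as.vector(pairwise_pearson(m)), oracle_pearson_pairs(m),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("pairwise correlations handle degenerate profiles", {
  v <- stats::rnorm(10)
  m <- cbind(v, v, v)
  expect_equal(as.vector(pairwise_pearson(m)), c(1, 1, 1))
  m2 <- cbind(v, -v, v)   # pairs (1,2), (1,3), (2,3)
  expect_equal(as.vector(pairwise_pearson(m2)), c(-1, 1, -1))
  expect_error(pairwise_pearson(cbind(v, v)), "insufficient cells")
  const <- cbind(v, v, v, rep(2, 10))
  expect_warning(r <- pairwise_pearson(const), "constant")
  expect_equal(attr(r, "n_constant"), 1)
  expect_length(r, 3)
})

test_that("the heterogeneity score is the interpolated IQR", {
  expect_equal(ith_score(c(0.1, 0.2, 0.3, 0.4)), 0.15)
  expect_equal(ith_score(rep(0.7, 10)), 0)     # point mass -> exactly 0
  expect_error(ith_score(numeric(0)), "empty")
  set.seed(2)
  for (i in 1:25) {
    v <- stats::runif(sample(3:200, 1), -1, 1)
    expect_equal(ith_score(v), oracle_iqr(v), tolerance = 1e-12)
  }
})

test_that("ITH is invariant to per-cell affine transforms of the profiles", {
  set.seed(6)
  m <- matrix(stats::rnorm(200), 20, 10)
  a <- stats::runif(10, 0.5, 3)
  b <- stats::rnorm(10)
  m2 <- sweep(sweep(m, 2, a, "*"), 2, b, "+")
  expect_equal(ith_score(pairwise_pearson(m)), ith_score(pairwise_pearson(m2)),
               tolerance = 1e-10)
})

test_that("near-identical malignant cells give near-zero ITH, and scores are deterministic", {
  set.seed(10)
  base <- stats::rnorm(100)
  prof <- matrix(base, 100, 30) + matrix(stats::rnorm(3000, sd = 0.01), 100, 30)
  cells <- data.frame(patient = "P1", malignant = TRUE)
  cells <- cells[rep(1, 30), ]
  ith <- compute_ith(prof, prof, cells)
  expect_lt(ith$ith_cna, 0.02)
  expect_lt(ith$ith_gex, 0.02)
  ith2 <- compute_ith(prof, prof, cells)
  expect_identical(ith, ith2)
})

test_that("patients with fewer than 3 malignant cells get undefined scores", {
  m <- matrix(stats::rnorm(40), 10, 4)
  cells <- data.frame(patient = c("A", "A", "B", "B"),
                      malignant = c(TRUE, TRUE, TRUE, FALSE))
  ith <- compute_ith(m, m, cells)
  expect_true(all(is.na(ith$ith_cna)))
  expect_equal(ith$n_malignant, c(2, 1))
})

test_that("two divergent clones raise ITH_CNA over a single clone", {
  wins <- 0
  for (s in 1:5) {
    cfg <- tiny_config(
      n_patients = 2,
      n_cells = c("Cancer" = 120L, "T cells" = 80L),
      genes_per_chr = 150L, n_chr = 3,
      clones = list(data.frame(chromosome = "1", start = 11L, length = 100L, fold = 2),
                    data.frame(chromosome = "2", start = 11L, length = 100L, fold = 0.5)),
      clones_per_patient = c(2, 1), lr_signals = NULL)
    sim <- generate_cohort(cfg, seed = 100 + s)
    co <- sim$cohort
    norm <- lognormalize(co)
    cna <- infer_cna(norm, co$genes, reference = !co$cells$malignant)
    ith <- compute_ith(cna, norm, co$cells)
    if (ith$ith_cna[ith$patient == "P01"] > ith$ith_cna[ith$patient == "P02"])
      wins <- wins + 1
  }
  expect_gte(wins, 4)
})

test_that("group comparisons reproduce exact rank-sum p-values", {
  ith <- structure(data.frame(
    patient = paste0("P", 1:6),
    ith_cna = c(1, 2, 3, 10, 11, 12),
    ith_gex = c(5, 5, 5, 5, 5, 5),
    n_malignant = 10L), class = c("ith_result", "data.frame"))
  groups <- stats::setNames(rep(c("LUADm", "LUSCn"), each = 3), paste0("P", 1:6))
  res <- compare_ith_groups(ith, groups)
  # fully separated n=3 vs 3: exact two-sided p = 2 / choose(6,3) = 0.1
  expect_equal(res$p_value[res$score == "ith_cna"], 0.1)
  # identical groups: p = 1 (all ties)
  expect_equal(res$p_value[res$score == "ith_gex"], 1)
  # groups with < 2 patients are skipped with a warning
  g2 <- c(groups, P7 = "LUADn")
  ith2 <- rbind(ith, data.frame(patient = "P7", ith_cna = 5, ith_gex = 5,
                                n_malignant = 10L))
  expect_warning(res2 <- compare_ith_groups(ith2, g2), "LUADn")
  expect_setequal(unique(c(res2$group1, res2$group2)), c("LUADm", "LUSCn"))
})

test_that("composition correlations recover planted linear relations", {
  set.seed(9)
  n <- 20
  ith <- structure(data.frame(patient = sprintf("P%02d", 1:n),
                              ith_cna = stats::runif(n, 0, 0.6),
                              ith_gex = stats::runif(n, 0, 0.6),
                              n_malignant = 50L),
                   class = c("ith_result", "data.frame"))
  neut <- 0.05 + 0.5 * ith$ith_gex + stats::rnorm(n, sd = 0.02)
  other <- stats::runif(n, 0.1, 0.3)
  comp <- cbind(Neutrophils = neut, Other = other,
                Rest = 1 - neut - other)
  rownames(comp) <- ith$patient
  res <- correlate_ith_composition(ith, comp)
  neut_row <- res[res$cell_type == "Neutrophils", ]
  expect_gt(neut_row$r, 0.5)
  expect_true(neut_row$significant)
  # exact linear relation gives r = 1
  comp2 <- cbind(A = 0.1 + 0.5 * ith$ith_gex)
  comp2 <- cbind(comp2, B = 1 - comp2[, "A"])
  rownames(comp2) <- ith$patient
  res2 <- correlate_ith_composition(ith, comp2)
  expect_equal(res2$r[res2$cell_type == "A"], 1, tolerance = 1e-12)
  expect_error(correlate_ith_composition(ith[1:3, ], comp[1:3, ]), "at least 4")
  bad <- comp; bad[1, 1] <- bad[1, 1] + 0.1
  expect_error(correlate_ith_composition(ith, bad), "sum to 1")
})

test_that("permuted compositions show no spurious correlation enrichment", {
  set.seed(13)
  n <- 24
  ith <- structure(data.frame(patient = sprintf("P%02d", 1:n),
                              ith_cna = stats::runif(n), ith_gex = stats::runif(n),
                              n_malignant = 50L),
                   class = c("ith_result", "data.frame"))
  pvals <- replicate(200, {
    a <- stats::runif(n, 0.2, 0.8)
    comp <- cbind(A = a, B = 1 - a)
    rownames(comp) <- ith$patient
    correlate_ith_composition(ith, comp)$p_value[1]
  })
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
})
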