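make_lr_cohort <- function(seed, effect = 8, n_perm = 200) {
  cfg <- tiny_config(
    n_cells = c("Cancer" = 100L, "T cells" = 80L, "Neutrophils" = 80L,
                "Fibroblasts" = 80L),
    lr_signals = data.frame(ligand = "CXCL8", receptor = "CXCR2",
                            sender = "Cancer", receiver = "Neutrophils",
                            effect = effect))
  co <- generate_cohort(cfg, seed = seed)$cohort
  norm <- lognormalize(co)
  suppressWarnings(lr_permutation_test(norm, co$cells$cell_type,
                                       n_perm = n_perm, seed = seed))
}

test_that("a strongly planted signal reaches the minimal attainable p-value", {
  tests <- make_lr_cohort(seed = 51, effect = 10, n_perm = 200)
  hit <- tests[tests$pair_id == "CXCL8_CXCR2" & tests$sender == "Cancer" &
                 tests$receiver == "Neutrophils", ]
  expect_equal(hit$p_value, 1 / 201)
  expect_true(hit$significant)
})

test_that("p-values respect their pseudocount bounds and the expression floor", {
  tests <- make_lr_cohort(seed = 52, n_perm = 100)
  expect_true(all(tests$p_value >= 1 / 101 & tests$p_value <= 1))
  # below-floor expression forces p = 1
  floor_rows <- tests$ligand_frac < 0.1 | tests$receptor_frac < 0.1
  expect_true(all(tests$p_value[floor_rows] == 1))
  # an all-zero ligand gives p = 1 everywhere
  m <- matrix(stats::rpois(5 * 60, 2), 5, 60,
              dimnames = list(c("CXCL8", "CXCR2", "a", "b", "c"), NULL))
  m["CXCL8", ] <- 0
  types <- rep(c("A", "B"), each = 30)
  pairs <- data.frame(pair_id = "CXCL8_CXCR2", ligand = "CXCL8", receptor = "CXCR2")
  res <- lr_permutation_test(m, types, pairs, n_perm = 50, seed = 1)
  expect_true(all(res$p_value == 1))
})

test_that("the permutation test is seed-reproducible", {
  a <- make_lr_cohort(seed = 53, n_perm = 100)
  b <- make_lr_cohort(seed = 53, n_perm = 100)
  expect_identical(a, b)
})

test_that("specificity rank is the fraction of significant type-pairs", {
  tests <- data.frame(
    pair_id = rep(c("p1", "p2"), each = 4),
    ligand = "L", receptor = "R",
    sender = rep(c("A", "A", "B", "B"), 2),
    receiver = rep(c("A", "B", "A", "B"), 2),
    p_value = c(0.01, 1, 1, 1, 0.01, 0.02, 0.03, 1),
    significant = c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE))
  rk <- lr_rank(tests, rank_max = 0.5)
  expect_equal(unique(rk$rank[rk$pair_id == "p1"]), 0.25)
  expect_equal(unique(rk$rank[rk$pair_id == "p2"]), 0.75)
  expect_true(all(rk$retained[rk$pair_id == "p1"] == rk$significant[rk$pair_id == "p1"]))
  expect_false(any(rk$retained[rk$pair_id == "p2"]))   # rank above the cutoff
  # rank 0 when nothing is significant
  tests$significant <- FALSE
  expect_equal(unique(lr_rank(tests)$rank), 0)
})

test_that("patient recurrence keeps triples retained in strictly more than five patients", {
  mk <- function(patients) data.frame(
    patient = patients, pair_id = "p", ligand = "L", receptor = "R",
    sender = "A", receiver = "B", significant = TRUE, rank = 0.05,
    retained = TRUE)
  expect_equal(nrow(aggregate_lr(mk(sprintf("P%d", 1:5)), min_patients = 6)), 0)
  agg <- aggregate_lr(mk(sprintf("P%d", 1:6)), min_patients = 6)
  expect_equal(nrow(agg), 1)
  expect_equal(agg$n_patients, 6)
})

test_that("rank/recurrence filters and both networks match brute-force enumeration", {
  set.seed(77)
  for (i in 1:25) {
    tests <- expand.grid(patient = sprintf("P%d", 1:8),
                         pair_id = sprintf("lr%d", 1:6),
                         sender = c("A", "B", "C"),
                         receiver = c("A", "B", "C"),
                         stringsAsFactors = FALSE)
    tests$ligand <- paste0(tests$pair_id, "_L")
    tests$receptor <- paste0(tests$pair_id, "_R")
    tests$significant <- stats::runif(nrow(tests)) < 0.25
    ranked <- do.call(rbind, lapply(split(tests, tests$patient),
                                    lr_rank, rank_max = 0.4))
    minp <- sample(2:4, 1)
    agg <- aggregate_lr(ranked, min_patients = minp)
    oracle <- oracle_aggregate(ranked, minp)
    if (is.null(oracle)) {
      expect_equal(nrow(agg), 0)
    } else {
      agg <- agg[order(agg$pair_id, agg$sender, agg$receiver), ]
      expect_equal(agg[c("pair_id", "sender", "receiver", "n_patients")],
                   oracle[c("pair_id", "sender", "receiver", "n_patients")],
                   ignore_attr = TRUE)
    }
    if (!is.null(oracle) && nrow(agg) > 0) {
      # cell-type network weights = brute tally over unordered type pairs
      net <- suppressWarnings(build_celltype_network(agg, min_interactions = 0))
      tally <- table(paste(pmin(agg$sender, agg$receiver),
                           pmax(agg$sender, agg$receiver)))
      got <- stats::setNames(net$edges$weight,
                             paste(net$edges$type1, net$edges$type2))
      expect_equal(got[names(tally)], stats::setNames(as.numeric(tally), names(tally)))
      # gene network components match union-find
      gn <- build_gene_network(agg)
      oc <- oracle_components(data.frame(from = agg$ligand, to = agg$receptor))
      oc <- oc[order(-lengths(oc), vapply(oc, min, character(1)))]
      expect_equal(gn$components, unname(utils::head(oc, 4)), ignore_attr = TRUE)
    }
  }
})

test_that("network node filter drops low-interaction cell types", {
  agg <- data.frame(pair_id = c("p1", "p2", "p3", "p4"),
                    ligand = c("a", "b", "c", "d"),
                    receptor = c("w", "x", "y", "z"),
                    sender = c("A", "A", "B", "A"),
                    receiver = c("B", "B", "A", "C"),
                    n_patients = 6L)
  net <- build_celltype_network(agg, min_interactions = 2)
  expect_setequal(igraph::V(net$graph)$name, c("A", "B"))
  ab <- net$edges[net$edges$type1 == "A" & net$edges$type2 == "B", ]
  expect_equal(ab$weight, 3)   # both directions summed
  expect_false("C" %in% net$edges$type2)
})

test_that("gene networks rank components by size and never contain type nodes", {
  agg <- data.frame(pair_id = sprintf("p%d", 1:3),
                    ligand = c("a", "b", "x"),
                    receptor = c("b", "c", "y"),
                    sender = "A", receiver = "B", n_patients = 6L)
  gn <- build_gene_network(agg)
  expect_equal(gn$components, list(c("a", "b", "c"), c("x", "y")),
               ignore_attr = TRUE)
  expect_false(any(grepl("^type:", unlist(gn$components))))
  expect_match(gn$note, "2 connected component")
  # empty retained set
  empty <- aggregate_lr(data.frame(patient = character(0), pair_id = character(0),
                                   ligand = character(0), receptor = character(0),
                                   sender = character(0), receiver = character(0),
                                   significant = logical(0), rank = numeric(0),
                                   retained = logical(0)), 6)
  expect_length(build_gene_network(empty)$components, 0)
})
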