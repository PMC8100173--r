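#' Bundled ligand-receptor pair list
#'
#' A small curated list of one-to-one ligand-receptor pairs (chemokines,
#' growth factors, immune checkpoints) bundled for testing and examples.
#' Real analyses should supply a full database via `pairs_file`.
#'
#' @param pairs_file optional TSV with columns `ligand`, `receptor` and
#'   optionally `pair_id`.
#' @return data.frame: `pair_id`, `ligand`, `receptor`.
#' @export
default_lr_pairs <- function(pairs_file = NULL) {
  path <- if (is.null(pairs_file))
    system.file("extdata", "lr_pairs.tsv", package = "scITH")
  else pairs_file
  tab <- utils::read.delim(path)
  if (!all(c("ligand", "receptor") %in% names(tab)))
    stop("pair list must have columns 'ligand' and 'receptor'")
  if (!"pair_id" %in% names(tab))
    tab$pair_id <- paste(tab$ligand, tab$receptor, sep = "_")
  if (anyDuplicated(tab$pair_id)) stop("pair ids must be unique")
  tab[c("pair_id", "ligand", "receptor")]
}

#' Ligand-receptor permutation test for one patient
#'
#' For every ligand-receptor pair and every ordered (sender, receiver)
#' cell-type pair, the interaction statistic is the mean of the ligand's
#' mean expression in the sender type and the receptor's mean expression in
#' the receiver type. The null distribution comes from `n_perm` random
#' permutations of the cell-type labels across cells, and
#' `p = (1 + #(null >= observed)) / (n_perm + 1)`. Pairs whose ligand is
#' expressed in less than `min_expr_frac` of sender cells, or receptor in
#' less than `min_expr_frac` of receiver cells, are non-specific and get
#' p = 1.
#'
#' @param norm genes x cells normalized matrix with gene rownames.
#' @param types cell-type label per cell.
#' @param pairs data.frame from [default_lr_pairs()]; pairs whose ligand or
#'   receptor is absent from the matrix are dropped with a warning.
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @param alpha significance level for the `significant` flag.
#' @param min_expr_frac expression floor (fraction of cells with count > 0).
#' @return data.frame: `pair_id`, `ligand`, `receptor`, `sender`,
#'   `receiver`, `statistic`, `ligand_frac`, `receptor_frac`, `p_value`,
#'   `significant`.
#' @export
lr_permutation_test <- function(norm, types, pairs = default_lr_pairs(),
                                n_perm = 1000, seed = 1L, alpha = 0.05,
                                min_expr_frac = 0.1) {
  stopifnot(length(types) == ncol(norm))
  types <- as.character(types)
  tl <- unique(types)
  if (length(tl) < 2) stop("need at least 2 cell types")
  drop <- !(pairs$ligand %in% rownames(norm) & pairs$receptor %in% rownames(norm))
  if (any(drop)) {
    warning(sum(drop), " pair(s) with genes absent from the matrix dropped")
    pairs <- pairs[!drop, , drop = FALSE]
  }
  if (nrow(pairs) == 0) stop("no testable ligand-receptor pairs")

  genes <- unique(c(pairs$ligand, pairs$receptor))
  X <- as.matrix(norm[genes, , drop = FALSE])
  fac <- factor(types, tl)
  cnt <- as.vector(table(fac))
  Tn <- length(tl); P <- nrow(pairs)

  group_means <- function(lab_idx) {
    # genes x types means for an integer label vector (values 1..Tn)
    ind <- matrix(0, ncol(X), Tn)
    ind[cbind(seq_len(ncol(X)), lab_idx)] <- 1
    sweep(X %*% ind, 2, cnt, "/")
  }
  stat_array <- function(M) {
    lig <- M[pairs$ligand, , drop = FALSE]    # P x T
    rec <- M[pairs$receptor, , drop = FALSE]
    A <- array(lig, c(P, Tn, Tn))                          # [p, sender, .]
    B <- aperm(array(rec, c(P, Tn, Tn)), c(1, 3, 2))       # [p, ., receiver]
    0.5 * (A + B)
  }

  lab0 <- as.integer(fac)
  obs <- stat_array(group_means(lab0))
  set.seed(seed %% .Machine$integer.max)
  ge <- array(0L, dim(obs))
  for (b in seq_len(n_perm)) {
    null_stat <- stat_array(group_means(sample(lab0)))
    ge <- ge + (null_stat >= obs)
  }
  pval <- (1 + ge) / (n_perm + 1)

  # expression floor: fraction of cells with value > 0 per gene and type
  posfrac <- t(sapply(genes, function(g) tapply(X[g, ] > 0, fac, mean)))
  if (Tn == 1) posfrac <- matrix(posfrac, ncol = 1, dimnames = list(genes, tl))

  grid <- expand.grid(pair = seq_len(P), sender = seq_len(Tn),
                      receiver = seq_len(Tn))
  lig_frac <- posfrac[cbind(match(pairs$ligand[grid$pair], genes), grid$sender)]
  rec_frac <- posfrac[cbind(match(pairs$receptor[grid$pair], genes), grid$receiver)]
  p <- pval[cbind(grid$pair, grid$sender, grid$receiver)]
  p[lig_frac < min_expr_frac | rec_frac < min_expr_frac] <- 1

  data.frame(pair_id = pairs$pair_id[grid$pair],
             ligand = pairs$ligand[grid$pair],
             receptor = pairs$receptor[grid$pair],
             sender = tl[grid$sender], receiver = tl[grid$receiver],
             statistic = obs[cbind(grid$pair, grid$sender, grid$receiver)],
             ligand_frac = lig_frac, receptor_frac = rec_frac,
             p_value = p, significant = p < alpha,
             row.names = NULL)
}

#' Specificity rank of each ligand-receptor pair
#'
#' A pair's rank within a patient is the fraction of (sender, receiver)
#' cell-type pairs in which it is significant; a low rank means the
#' interaction is specific to few type pairs. Rows gain `rank` and
#' `retained` (significant AND rank <= `rank_max`) columns; pairs with rank
#' above `rank_max` are discarded from the retained set to increase
#' specificity.
#'
#' @param tests output of [lr_permutation_test()] for one patient.
#' @param rank_max maximum rank retained.
#' @return `tests` with `rank` and `retained` columns added.
#' @export
lr_rank <- function(tests, rank_max = 0.1) {
  rk <- tapply(tests$significant, tests$pair_id, mean)
  tests$rank <- as.vector(rk[tests$pair_id])
  tests$retained <- tests$significant & tests$rank <= rank_max
  tests
}

#' Aggregate retained interactions across patients
#'
#' A (pair, sender, receiver) triple is kept when it is retained
#' (significant with rank <= rank_max, see [lr_rank()]) in strictly more
#' than `min_patients - 1` patients, i.e. in at least `min_patients`
#' patients. With the default `min_patients = 6` this is the
#' "more than five patients" recurrence rule. If `groups` is given, the
#' fraction of each group's patients in which the triple is retained is
#' reported for dot-plot style summaries.
#'
#' @param tests row-bound [lr_rank()] outputs with a `patient` column.
#' @param min_patients minimum number of patients in which a triple must be
#'   retained.
#' @param groups optional named character vector patient -> group.
#' @return data.frame of retained triples: `pair_id`, `ligand`, `receptor`,
#'   `sender`, `receiver`, `n_patients`, plus `frac_<group>` columns.
#' @export
aggregate_lr <- function(tests, min_patients = 6, groups = NULL) {
  stopifnot("patient" %in% names(tests), "retained" %in% names(tests))
  hit <- tests[tests$retained, , drop = FALSE]
  if (nrow(hit) == 0)
    return(data.frame(pair_id = character(0), ligand = character(0),
                      receptor = character(0), sender = character(0),
                      receiver = character(0), n_patients = integer(0)))
  key <- paste(hit$pair_id, hit$sender, hit$receiver, sep = "\r")
  npat <- tapply(hit$patient, key, function(p) length(unique(p)))
  first <- hit[!duplicated(key), c("pair_id", "ligand", "receptor",
                                   "sender", "receiver")]
  first$n_patients <- as.integer(npat[paste(first$pair_id, first$sender,
                                            first$receiver, sep = "\r")])
  out <- first[first$n_patients >= min_patients, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(groups) && nrow(out) > 0) {
    okey <- paste(out$pair_id, out$sender, out$receiver, sep = "\r")
    for (g in unique(groups)) {
      gp <- names(groups)[groups == g]
      cnt <- tapply(hit$patient, key, function(p) length(unique(intersect(p, gp))))
      out[[paste0("frac_", g)]] <- as.vector(cnt[okey]) / length(gp)
    }
  }
  out
}

#' Cell-type interaction network
#'
#' Undirected weighted graph over cell types; the weight of edge {A, B} is
#' the number of retained interactions between A and B summed over both
#' directions. Cell types whose total incident interaction count is below
#' `min_interactions` are removed from the reported network (the published
#' analysis used 500; scale it down for small cohorts).
#'
#' @param retained output of [aggregate_lr()].
#' @param min_interactions node filter on total incident interactions.
#' @return List of class `celltype_network`: `graph` (an
#'   \pkg{igraph} object with edge attribute `weight`), `edges`
#'   (data.frame `type1`, `type2`, `weight`).
#' @export
build_celltype_network <- function(retained, min_interactions = 500) {
  if (nrow(retained) == 0) {
    warning("no retained interactions; empty network")
    return(structure(list(graph = igraph::make_empty_graph(directed = FALSE),
                          edges = data.frame(type1 = character(0),
                                             type2 = character(0),
                                             weight = integer(0))),
                     class = "celltype_network"))
  }
  a <- pmin(retained$sender, retained$receiver)
  b <- pmax(retained$sender, retained$receiver)
  tab <- stats::aggregate(list(weight = rep(1L, length(a))),
                          by = list(type1 = a, type2 = b), FUN = sum)
  g <- igraph::graph_from_data_frame(tab, directed = FALSE)
  total <- igraph::strength(g, weights = igraph::E(g)$weight)
  # self-loop weights count twice in strength; correct to plain totals
  for (v in igraph::V(g)$name) {
    self <- tab$weight[tab$type1 == v & tab$type2 == v]
    if (length(self)) total[v] <- total[v] - sum(self)
  }
  drop <- names(total)[total < min_interactions]
  if (length(drop)) g <- igraph::delete_vertices(g, drop)
  if (igraph::vcount(g) == 0) warning("all cell types fall below the node filter")
  keep <- !(tab$type1 %in% drop) & !(tab$type2 %in% drop)
  structure(list(graph = g, edges = tab[keep, , drop = FALSE]),
            class = "celltype_network")
}

#' Gene-only interaction network
#'
#' Builds the master graph containing cell-type nodes (linked to the genes
#' they express above `expr_floor`, when expression is supplied) and gene
#' nodes linked by the retained ligand-receptor pairs, then deletes the
#' cell-type nodes and returns the four largest connected components of the
#' gene-only graph. Components are ranked by node count, ties broken by
#' edge count and then by lexicographically smallest member gene. Fewer
#' than four components are all returned, with a note.
#'
#' @param retained output of [aggregate_lr()].
#' @param type_means optional genes x types matrix of mean expression used
#'   for the type-gene edges of the master graph.
#' @param expr_floor mean-expression floor for a type-gene edge.
#' @param n_components number of components to report.
#' @return List of class `gene_network`: `components` (list of character
#'   vectors of gene names, largest first), `graph` (the gene-only
#'   \pkg{igraph} object), `note`.
#' @export
build_gene_network <- function(retained, type_means = NULL, expr_floor = 0.1,
                               n_components = 4) {
  if (nrow(retained) == 0)
    return(structure(list(components = list(),
                          graph = igraph::make_empty_graph(directed = FALSE),
                          note = "empty retained set"),
                     class = "gene_network"))
  gene_edges <- unique(data.frame(from = retained$ligand, to = retained$receptor))
  types <- unique(c(retained$sender, retained$receiver))
  edges <- gene_edges
  if (!is.null(type_means)) {
    tm <- as.matrix(type_means)
    tg <- which(tm > expr_floor, arr.ind = TRUE)
    tg <- tg[rownames(tm)[tg[, 1]] %in% unique(c(retained$ligand, retained$receptor)) &
               colnames(tm)[tg[, 2]] %in% types, , drop = FALSE]
    if (nrow(tg))
      edges <- rbind(edges, data.frame(from = paste0("type:", colnames(tm)[tg[, 2]]),
                                       to = rownames(tm)[tg[, 1]]))
  } else {
    # without expression, link each type to the genes of its retained triples
    edges <- rbind(edges,
                   data.frame(from = paste0("type:", retained$sender),
                              to = retained$ligand),
                   data.frame(from = paste0("type:", retained$receiver),
                              to = retained$receptor))
  }
  g <- igraph::graph_from_data_frame(unique(edges), directed = FALSE)
  g <- igraph::delete_vertices(g, igraph::V(g)$name[startsWith(igraph::V(g)$name, "type:")])
  comp <- igraph::components(g)
  members <- split(igraph::V(g)$name, comp$membership)
  n_edges <- vapply(members, function(m)
    as.numeric(igraph::ecount(igraph::induced_subgraph(g, m))), numeric(1))
  key_member <- vapply(members, function(m) min(m), character(1))
  ord <- order(-lengths(members), -n_edges, key_member)
  members <- lapply(members[ord], sort)
  note <- if (length(members) < n_components)
    sprintf("only %d connected component(s) present", length(members)) else NA_character_
  structure(list(components = utils::head(members, n_components),
                 graph = g, note = note),
            class = "gene_network")
}
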