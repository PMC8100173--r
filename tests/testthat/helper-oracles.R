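# Independent brute-force oracles used to check the package's computations.
# Each is written from the definition, not from the implementation.

# IQR by explicit sort + linear interpolation (quantile type 7 definition)
oracle_iqr <- function(v) {
  s <- sort(v)
  n <- length(s)
  q <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }
  q(0.75) - q(0.25)
}

# Pearson correlation from the covariance formula, one pair at a time
oracle_pearson_pairs <- function(m) {
  n <- ncol(m)
  out <- c()
  for (j in 2:n) for (i in 1:(j - 1)) {
    x <- m[, i]; y <- m[, j]
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    sxx <- sum((x - mean(x))^2)
    syy <- sum((y - mean(y))^2)
    out <- c(out, sxy / sqrt(sxx * syy))
  }
  out
}

# knee of a descending curve: max perpendicular distance to the endpoint chord
oracle_knee_rank <- function(sorted_totals) {
  x <- log10(seq_along(sorted_totals))
  y <- log10(sorted_totals)
  p1 <- c(x[1], y[1]); p2 <- c(x[length(x)], y[length(y)])
  v <- p2 - p1
  d <- abs(v[2] * x - v[1] * y + v[1] * p1[2] - v[2] * p1[1]) / sqrt(sum(v^2))
  which.max(d)
}

# AUROC from the rank-sum identity
oracle_auroc <- function(scores_pos, scores_neg) {
  r <- rank(c(scores_pos, scores_neg))
  n1 <- length(scores_pos); n2 <- length(scores_neg)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

# truncated running mean along a vector (window never crosses the ends)
oracle_window_mean <- function(v, window) {
  h <- (window - 1) / 2
  sapply(seq_along(v), function(i) {
    lo <- max(1, i - h); hi <- min(length(v), i + h)
    mean(v[lo:hi])
  })
}

# connected components by union-find over an edge list
oracle_components <- function(edges) {
  nodes <- unique(c(edges$from, edges$to))
  parent <- stats::setNames(nodes, nodes)
  find <- function(a) { while (parent[[a]] != a) a <- parent[[a]]; a }
  for (i in seq_len(nrow(edges))) {
    ra <- find(edges$from[i]); rb <- find(edges$to[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(nodes, find, character(1))
  unname(lapply(split(nodes, roots), sort))
}

# brute-force patient-recurrence filter over an interaction test table
oracle_aggregate <- function(tests, min_patients) {
  keys <- unique(tests[c("pair_id", "sender", "receiver")])
  keep <- list()
  for (i in seq_len(nrow(keys))) {
    rows <- tests$pair_id == keys$pair_id[i] &
      tests$sender == keys$sender[i] & tests$receiver == keys$receiver[i] &
      tests$retained
    n <- length(unique(tests$patient[rows]))
    if (n >= min_patients) keep[[length(keep) + 1]] <- cbind(keys[i, ], n_patients = n)
  }
  if (length(keep) == 0) return(NULL)
  out <- do.call(rbind, keep)
  out[order(out$pair_id, out$sender, out$receiver), ]
}
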