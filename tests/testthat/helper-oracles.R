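# Independent brute-force oracles used across the suite. These deliberately
# re-derive quantities with naive algorithms, separate from the package's
# implementation paths.

# Exhaustive LSOSS split: try every contiguous split of the sorted vector and
# compute each side's sum of squared deviations directly.
oracle_lsoss_split <- function(values) {
  s <- sort(values)
  n <- length(s)
  best_k <- NA_integer_
  best_cost <- Inf
  for (k in 1:(n - 1)) {
    a <- s[1:k]
    b <- s[(k + 1):n]
    cost <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (cost < best_cost - 1e-12) { # strict improvement, ties keep smallest k
      best_cost <- cost
      best_k <- k
    }
  }
  list(k = best_k, cost = best_cost)
}

# O(n^2) AUC: count concordant case-control pairs, ties worth 1/2.
oracle_auc <- function(scores, labels) {
  ca <- scores[labels == "case"]
  co <- scores[labels == "control"]
  tot <- 0
  for (x in ca) for (y in co)
    tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(ca) * length(co))
}

# Exact Spearman permutation p-value by explicit enumeration, built on a
# different permutation generator (iterative heap-style) than the package's.
oracle_perms <- function(n) {
  out <- matrix(1L, 1L, 1L)
  if (n == 1L) return(out)
  for (m in 2:n) {
    blocks <- lapply(seq_len(m), function(pos) {
      left <- out[, seq_len(pos - 1L), drop = FALSE]
      right <- if (pos <= m - 1L) out[, pos:(m - 1L), drop = FALSE]
               else matrix(0L, nrow(out), 0L)
      cbind(left, matrix(m, nrow(out), 1L), right, deparse.level = 0L)
    })
    out <- do.call(rbind, blocks)
  }
  out
}

oracle_spearman_exact_p <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  obs <- abs(stats::cor(rx, ry))
  pm <- oracle_perms(length(x))
  hits <- 0L
  for (i in seq_len(nrow(pm))) {
    if (abs(stats::cor(rx, ry[pm[i, ]])) >= obs - 1e-12) hits <- hits + 1L
  }
  hits / nrow(pm)
}

# Random directed bipartite edge set with unique edges.
random_bipartite_edges <- function(n_mirna, n_gene, n_edge) {
  all_pairs <- expand.grid(m = seq_len(n_mirna), g = seq_len(n_gene))
  n_edge <- min(n_edge, nrow(all_pairs))
  pick <- all_pairs[sample.int(nrow(all_pairs), n_edge), ]
  data.frame(mirna_id = sprintf("M%02d", pick$m),
             gene_id = sprintf("g%03d", pick$g),
             stringsAsFactors = FALSE)
}

# Classical pooled-variance two-sample t statistic (oracle baseline for the
# power comparison).
oracle_t_stat <- function(case_values, control_values) {
  n1 <- length(case_values)
  n0 <- length(control_values)
  sp2 <- ((n1 - 1) * stats::var(case_values) +
          (n0 - 1) * stats::var(control_values)) / (n1 + n0 - 2)
  (mean(case_values) - mean(control_values)) /
    sqrt(sp2 * (1 / n1 + 1 / n0))
}
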