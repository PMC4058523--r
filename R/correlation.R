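#' All permutations of 1..n
#'
#' Exhaustive enumeration used by the exact Spearman permutation test.
#' @param n Integer, 1 <= n <= 9.
#' @return Integer matrix with n! rows, one permutation per row.
#' @keywords internal
all_permutations <- function(n) {
  if (n < 1L || n > 9L)
    stop("permutation enumeration supported for 1 <= n <= 9", call. = FALSE)
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- sub
    rest[rest >= i] <- rest[rest >= i] + 1L
    cbind(rep(i, nrow(rest)), rest, deparse.level = 0L)
  }))
}

#' Spearman correlation with t-approximation or exact permutation p-value
#'
#' rho is the Pearson correlation of mid-ranks (tie-corrected). The default
#' two-sided p-value uses the t-approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 df; with `exact = TRUE`
#' (n <= 9) the p-value is the exact proportion of all n! rank permutations
#' with `|rho_perm| >= |rho_obs|`. A constant input vector leaves rho
#' undefined: `NA` is returned together with a `reason`.
#'
#' @param x,y Numeric vectors of equal length n >= 4; ties allowed.
#' @param exact Use exhaustive rank-permutation enumeration (n <= 9 only).
#' @return List with `rho`, `p_value`, `n` and, for skipped pairs, `reason`.
#' @export
spearman_test <- function(x, y, exact = FALSE) {
  n <- length(x)
  if (length(y) != n) stop("`x` and `y` must have equal length", call. = FALSE)
  if (n < 4L) stop("need at least 4 paired observations", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("values must be finite", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                reason = "constant input vector"))
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (exact) {
    if (n > 9L) stop("exact enumeration supported only for n <= 9",
                     call. = FALSE)
    pm <- all_permutations(n)
    ryp <- matrix(ry[pm], nrow(pm), n)
    rxc <- rx - mean(rx)
    rho_perm <- as.numeric(ryp %*% rxc) /
      ((n - 1) * stats::sd(rx) * stats::sd(ry))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else {
    r2 <- min(rho^2, 1)
    tstat <- rho * sqrt((n - 2) / (1 - r2)) # rho = +-1 -> Inf -> p = 0
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Screen outlier miRNA x outlier gene pairs for inverse correlation
#'
#' Tests every combination of outlier miRNAs and outlier genes for negative
#' Spearman correlation across paired samples (matched by shared `pair_key`,
#' never by column order) and retains pairs with `rho <= rho_cutoff`
#' (inclusive, default -0.6) and `p < p_cutoff` (default 0.05, raw
#' t-approximation p-values, no multiplicity correction). Pairs involving a
#' constant expression vector are skipped and counted.
#'
#' @param mirna_outliers,gene_outliers Data frames from [lsoss_scan()] /
#'   [select_outliers()] (only `feature_id` is used) or character ID vectors.
#' @param mirna_expr,gene_expr `ExpressionMatrix` objects sharing paired
#'   samples through `ann`.
#' @param ann A `SampleAnnotation` covering both matrices.
#' @param rho_cutoff Retain pairs with rho at or below this value.
#' @param p_cutoff Retain pairs with p strictly below this value.
#' @param sample_mode `"all"` correlates over all paired samples (default);
#'   `"case"` restricts to case-class pairs.
#' @return Data frame `mirna_id, gene_id, rho, p_value, n_samples` sorted by
#'   rho ascending, with attributes `n_tested` (all combinations) and
#'   `n_skipped` (pairs lost to constant vectors).
#' @export
screen_pairs <- function(mirna_outliers, gene_outliers, mirna_expr, gene_expr,
                         ann, rho_cutoff = -0.6, p_cutoff = 0.05,
                         sample_mode = c("all", "case")) {
  sample_mode <- match.arg(sample_mode)
  if (!is.finite(rho_cutoff) || !is.finite(p_cutoff))
    stop("cutoffs must be finite", call. = FALSE)
  mids <- if (is.data.frame(mirna_outliers)) mirna_outliers$feature_id
          else as.character(mirna_outliers)
  gids <- if (is.data.frame(gene_outliers)) gene_outliers$feature_id
          else as.character(gene_outliers)

  annm <- ann[match(sample_ids(mirna_expr), ann$sample_id), , drop = FALSE]
  anng <- ann[match(sample_ids(gene_expr), ann$sample_id), , drop = FALSE]
  if (anyNA(annm$sample_id) || anyNA(anng$sample_id))
    stop("expression samples without annotation", call. = FALSE)
  keys <- intersect(annm$pair_key, anng$pair_key)
  if (length(keys)) {
    clm <- annm$class_label[match(keys, annm$pair_key)]
    clg <- anng$class_label[match(keys, anng$pair_key)]
    if (any(clm != clg))
      stop("inconsistent class labels within pair(s): ",
           paste(keys[clm != clg], collapse = ", "), call. = FALSE)
    if (sample_mode == "case") keys <- keys[clm == "case"]
  }
  if (!length(keys))
    stop("no shared paired samples between the miRNA and mRNA matrices",
         call. = FALSE)
  n <- length(keys)
  if (n < 4L)
    stop("need at least 4 paired samples for correlation; got ", n,
         call. = FALSE)

  empty <- data.frame(mirna_id = character(), gene_id = character(),
                      rho = numeric(), p_value = numeric(),
                      n_samples = integer(), stringsAsFactors = FALSE)
  if (!length(mids) || !length(gids)) {
    attr(empty, "n_tested") <- length(mids) * length(gids)
    attr(empty, "n_skipped") <- 0L
    return(empty)
  }

  mcol <- match(keys, annm$pair_key)
  gcol <- match(keys, anng$pair_key)
  Xm <- mirna_expr$values[mids, mcol, drop = FALSE]
  Xg <- gene_expr$values[gids, gcol, drop = FALSE]

  const_m <- apply(Xm, 1L, function(v) stats::sd(v) == 0)
  const_g <- apply(Xg, 1L, function(v) stats::sd(v) == 0)
  n_tested <- length(mids) * length(gids)
  n_skipped <- sum(const_m) * length(gids) +
    sum(!const_m) * sum(const_g)
  if (any(const_m) || any(const_g))
    message("skipping ", n_skipped,
            " pair(s) with a constant expression vector (",
            sum(const_m), " miRNA(s), ", sum(const_g), " gene(s))")

  mk <- which(!const_m)
  gk <- which(!const_g)
  if (!length(mk) || !length(gk)) {
    attr(empty, "n_tested") <- n_tested
    attr(empty, "n_skipped") <- n_skipped
    return(empty)
  }

  Rm <- t(apply(Xm[mk, , drop = FALSE], 1L, rank))
  Rg <- t(apply(Xg[gk, , drop = FALSE], 1L, rank))
  RHO <- stats::cor(t(Rm), t(Rg))
  r2 <- pmin(RHO^2, 1)
  tstat <- RHO * sqrt((n - 2) / (1 - r2))
  P <- 2 * stats::pt(-abs(tstat), df = n - 2)

  # inclusive boundary with a tiny tolerance so an exact rho of -0.6 is
  # retained despite floating-point representation of the rank formula
  hit <- which(RHO <= rho_cutoff + 1e-12 & P < p_cutoff, arr.ind = TRUE)
  out <- data.frame(
    mirna_id = mids[mk][hit[, 1L]],
    gene_id = gids[gk][hit[, 2L]],
    rho = RHO[hit],
    p_value = P[hit],
    n_samples = rep(n, nrow(hit)),
    stringsAsFactors = FALSE)
  out <- out[order(out$rho, out$mirna_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_tested") <- n_tested
  attr(out, "n_skipped") <- n_skipped
  out
}
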