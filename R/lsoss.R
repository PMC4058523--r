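# Sentinel statistic emitted when the pooled SD (after flooring) is zero but
# the outlier-control contrast is not; keeps result tables finite.
LSOSS_SENTINEL <- 1e6

#' Optimal contiguous split of sorted case values
#'
#' Sorts the values ascending and, for each split k in 1..n-1, computes the
#' within-subset sum of squared deviations of the first k values plus that of
#' the remaining n-k. Returns the k minimising this cost; ties are broken by
#' the smallest k. A constant vector is flagged degenerate (k = 1, cost 0).
#'
#' @param values Numeric vector of case-class values, length >= 2, finite.
#' @return List with `k` (split index), `cost` (minimal summed within-subset
#'   SS) and `degenerate` (TRUE for a constant vector).
#' @export
lsoss_split <- function(values) {
  n <- length(values)
  if (n < 2L) stop("need at least 2 case values", call. = FALSE)
  if (!all(is.finite(values))) stop("values must be finite", call. = FALSE)
  s <- sort(values)
  cs <- cumsum(s)
  cs2 <- cumsum(s * s)
  k <- seq_len(n - 1L)
  ss1 <- cs2[k] - cs[k]^2 / k
  sum2 <- cs[n] - cs[k]
  ss2 <- (cs2[n] - cs2[k]) - sum2^2 / (n - k)
  cost <- pmax(ss1 + ss2, 0)
  kstar <- unname(which.min(cost)) # first minimum = smallest k
  list(k = kstar, cost = unname(cost[kstar]),
       degenerate = all(values == values[1L]))
}

#' LSOSS outlier statistic for one feature
#'
#' Implements the least sum of ordered subset square t-statistic: the case
#' values are split by [lsoss_split()]; of the two ordered subsets, the
#' outlier subset O is the one whose mean lies farther from the control mean
#' (ties prefer the upper subset, so up- and down-outliers are treated
#' symmetrically). The statistic is
#' `t_L = (mean(O) - mean(control)) / (s_p * sqrt(1/|O| + 1/n_control))`
#' with `s_p` the SD pooled over O and the controls on `|O| + n_control - 2`
#' degrees of freedom. `sp_floor` (see [lsoss_scan()]) guards against a zero
#' denominator; if the floored SD is still zero, the statistic is 0 when the
#' contrast is 0 and a large finite sentinel otherwise.
#'
#' @param case_values,control_values Numeric vectors, each of length >= 2.
#' @param sp_floor Lower bound applied to the pooled SD (default 0).
#' @return List with `statistic`, `split_index`, `outlier_idx` (indices into
#'   `case_values` forming the outlier subset), `direction` (`"up"`/`"down"`),
#'   and `degenerate` (TRUE when the denominator needed the sentinel policy
#'   or the contrast is exactly 0).
#' @export
lsoss_statistic <- function(case_values, control_values, sp_floor = 0) {
  n1 <- length(case_values)
  n0 <- length(control_values)
  if (n1 < 2L || n0 < 2L)
    stop("need at least 2 case and 2 control values", call. = FALSE)
  if (!all(is.finite(case_values)) || !all(is.finite(control_values)))
    stop("values must be finite", call. = FALSE)
  ord <- order(case_values)
  s <- case_values[ord]
  sp <- lsoss_split(s)
  k <- sp$k
  lo <- s[seq_len(k)]
  hi <- s[(k + 1L):n1]
  mc <- mean(control_values)
  if (abs(mean(hi) - mc) >= abs(mean(lo) - mc)) {
    O <- hi
    o_idx <- ord[(k + 1L):n1]
  } else {
    O <- lo
    o_idx <- ord[seq_len(k)]
  }
  num <- mean(O) - mc
  df <- length(O) + n0 - 2L
  sp2 <- (sum((O - mean(O))^2) + sum((control_values - mc)^2)) / df
  s_eff <- max(sqrt(max(sp2, 0)), sp_floor)
  degenerate <- FALSE
  if (s_eff == 0) {
    stat <- if (num == 0) 0 else sign(num) * LSOSS_SENTINEL
    degenerate <- TRUE
  } else {
    stat <- num / (s_eff * sqrt(1 / length(O) + 1 / n0))
  }
  if (num == 0) degenerate <- TRUE
  list(statistic = stat, split_index = k, outlier_idx = o_idx,
       direction = if (num < 0) "down" else "up", degenerate = degenerate)
}

#' Matrix-wide LSOSS scan with permutation significance
#'
#' Computes the LSOSS statistic for every feature of an expression matrix and
#' assigns significance by whole-vector class-label permutation: the same
#' `n_perm` random reassignments of the case labels are reused across
#' features. Because the statistic is variance-standardised, the default
#' null pools the permutation statistics of all features
#' (`null_pool = "all"`, the SAM-style pooled null):
#' `p_f = (1 + #\{(g, b): |t_perm[g, b]| >= |t_obs[f]|\}) / (1 + n_perm * F)`.
#' Pooling matters for outlier statistics: a feature's own permutation null
#' retains its outlier structure (the shifted samples stay in most permuted
#' case sets), which floors the per-feature p-value well above `1 / n_perm`
#' and destroys power; the per-feature comparison remains available as
#' `null_pool = "feature"`. Benjamini-Hochberg q-values are computed across
#' features. The pooled-SD denominator is floored at `sp_floor_frac` times
#' the median pooled SD over all features (per label assignment) to avoid
#' infinite statistics.
#'
#' @param m An `ExpressionMatrix`.
#' @param ann A `SampleAnnotation` covering all columns of `m`.
#' @param n_perm Number of label permutations (default 999); with 0, p- and
#'   q-values are reported as `NA` but statistics are still returned.
#' @param seed Integer seed for the permutation draw (mandatory for
#'   reproducibility).
#' @param sp_floor_frac Fraction of the median pooled SD used as the variance
#'   floor (default 0.01).
#' @param null_pool `"all"` (default) compares each observed statistic with
#'   the permutation statistics pooled over all features; `"feature"`
#'   compares only against the feature's own permutations.
#' @return Data frame with one row per feature: `feature_id`, `statistic`,
#'   `split_index`, `outlier_subset` (comma-joined case sample IDs),
#'   `direction`, `p_value`, `q_value`.
#' @export
lsoss_scan <- function(m, ann, n_perm = 999L, seed = 1L,
                       sp_floor_frac = 0.01,
                       null_pool = c("all", "feature")) {
  null_pool <- match.arg(null_pool)
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (n_perm < 0L) stop("`n_perm` must be >= 0", call. = FALSE)
  cls <- check_annotation(ann, m)
  X <- m$values
  N <- ncol(X)
  case_cols <- which(cls == "case")
  n1 <- length(case_cols)
  n0 <- N - n1

  set.seed(seed)
  P <- n_perm + 1L
  caseIdx <- matrix(0L, n1, P)
  caseIdx[, 1L] <- case_cols
  if (n_perm > 0L)
    for (j in seq_len(n_perm))
      caseIdx[, j + 1L] <- sample.int(N, n1)

  core <- lsoss_core(X, caseIdx)
  Fn <- nrow(X)
  floorv <- sp_floor_frac * apply(core$sd, 2L, stats::median)
  sdm <- pmax(core$sd, matrix(floorv, Fn, P, byrow = TRUE))
  se <- sdm * sqrt(1 / core$osize + 1 / n0)
  tmat <- ifelse(se > 0, core$num / se,
                 ifelse(core$num == 0, 0, sign(core$num) * LSOSS_SENTINEL))
  tobs <- tmat[, 1L]

  if (n_perm > 0L) {
    aperm_mat <- abs(tmat[, -1L, drop = FALSE])
    if (null_pool == "feature") {
      exceed <- rowSums(aperm_mat >= abs(tobs))
      p <- (1 + exceed) / (1 + n_perm)
    } else {
      pool <- sort(as.numeric(aperm_mat))
      # count of pooled null values >= |t_obs| via binary search
      exceed <- length(pool) - findInterval(abs(tobs) - 1e-12, pool)
      p <- (1 + exceed) / (1 + length(pool))
    }
    q <- stats::p.adjust(p, method = "BH")
  } else {
    p <- q <- rep(NA_real_, Fn)
  }

  # Observed-label outlier subsets: replicate the side selection (the ordered
  # subset whose mean is farther from the control mean; ties take the upper).
  case_ids <- sample_ids(m)[case_cols]
  ctrl_cols <- setdiff(seq_len(N), case_cols)
  subsets <- character(Fn)
  for (f in seq_len(Fn)) {
    cv <- X[f, case_cols]
    ord <- order(cv)
    s <- cv[ord]
    k <- core$ksplit[f, 1L]
    mc <- mean(X[f, ctrl_cols])
    mlo <- mean(s[seq_len(k)])
    mhi <- mean(s[(k + 1L):n1])
    idx <- if (abs(mhi - mc) >= abs(mlo - mc)) ord[(k + 1L):n1] else ord[seq_len(k)]
    subsets[f] <- paste(case_ids[sort(idx)], collapse = ",")
  }

  data.frame(
    feature_id = feature_ids(m),
    statistic = tobs,
    split_index = core$ksplit[, 1L],
    outlier_subset = subsets,
    direction = ifelse(core$num[, 1L] < 0, "down", "up"),
    p_value = p,
    q_value = q,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Select outlier features from an LSOSS scan
#'
#' Default selection keeps features with BH q-value below `q_cutoff`
#' (strict). Alternatively, `top_n` keeps the features with the largest
#' absolute statistic.
#'
#' @param results Data frame from [lsoss_scan()].
#' @param q_cutoff FDR threshold (default 0.05), ignored when `top_n` given.
#' @param top_n Optional number of top features by `|statistic|`.
#' @return The selected rows of `results`.
#' @export
select_outliers <- function(results, q_cutoff = 0.05, top_n = NULL) {
  if (!is.null(top_n)) {
    ord <- order(-abs(results$statistic), results$feature_id)
    out <- results[utils::head(ord, top_n), , drop = FALSE]
  } else {
    if (all(is.na(results$q_value)))
      stop("q-values are missing (n_perm = 0); use `top_n` selection",
           call. = FALSE)
    out <- results[!is.na(results$q_value) & results$q_value < q_cutoff, ,
                   drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
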