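#' ROC curve, AUC and Youden-optimal operating point for one marker
#'
#' AUC is computed by the rank (Mann-Whitney) formulation with midrank tie
#' handling, after orienting scores by the marker's differential-expression
#' direction: for an up-regulated marker higher expression indicates case,
#' for a down-regulated one lower expression does. The operating threshold
#' maximises Youden's J = sensitivity + specificity - 1 (first maximum, i.e.
#' the most stringent threshold, on ties); sensitivity, specificity and
#' accuracy are reported at that threshold. The curve starts at (0,0), ends
#' at (1,1) and is monotone nondecreasing in both coordinates.
#'
#' @param scores Numeric expression values, one per sample.
#' @param labels `"case"`/`"control"` per sample; both classes required.
#' @param direction `"up"` or `"down"`: the marker's direction in cases.
#' @return An object of class `RocResult`: list with `auc`, `threshold` (on
#'   the original score scale; a sample is called case when its score is
#'   >= threshold for direction `"up"`, <= threshold for `"down"`),
#'   `sensitivity`, `specificity`, `accuracy`, `direction` and `curve`
#'   (data frame `threshold, fpr, tpr`).
#' @export
roc_curve <- function(scores, labels, direction = c("up", "down")) {
  direction <- match.arg(direction)
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("case", "control"))
  if (length(bad))
    stop("labels must be 'case' or 'control'", call. = FALSE)
  case <- labels == "case"
  n1 <- sum(case)
  n0 <- sum(!case)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present", call. = FALSE)
  if (length(scores) != length(labels))
    stop("`scores` and `labels` must have equal length", call. = FALSE)

  s <- if (direction == "up") scores else -scores
  r <- rank(s)
  auc <- (sum(r[case]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  th <- c(Inf, sort(unique(s), decreasing = TRUE))
  tpr <- vapply(th, function(t) sum(s[case] >= t), 0) / n1
  fpr <- vapply(th, function(t) sum(s[!case] >= t), 0) / n0
  i <- which.max(tpr - fpr)
  sens <- tpr[i]
  spec <- 1 - fpr[i]
  acc <- (tpr[i] * n1 + (1 - fpr[i]) * n0) / (n1 + n0)
  orient <- function(v) if (direction == "up") v else -v
  structure(list(auc = auc, threshold = orient(th[i]), sensitivity = sens,
                 specificity = spec, accuracy = acc, direction = direction,
                 curve = data.frame(threshold = orient(th), fpr = fpr,
                                    tpr = tpr)),
            class = "RocResult")
}

#' @export
print.RocResult <- function(x, ...) {
  cat(sprintf(
    "RocResult: AUC %.3f | sens %.3f spec %.3f acc %.3f @ threshold %.4g (%s)\n",
    x$auc, x$sensitivity, x$specificity, x$accuracy, x$threshold,
    x$direction))
  invisible(x)
}

#' Hierarchical clustering of samples on candidate-marker expression
#'
#' Rows (features) are standardised to z-scores (constant rows map to 0),
#' samples are clustered on Euclidean distance with complete linkage and the
#' dendrogram is cut into `k = 2` groups. Agreement with the case/control
#' labels is the accuracy under the better of the two cluster-to-class
#' assignments, so it always lies in [0.5, 1].
#'
#' @param m An `ExpressionMatrix` restricted to the markers of interest
#'   (>= 2 features, >= 3 samples).
#' @param ann A `SampleAnnotation` covering the samples of `m`.
#' @param k Number of groups to cut (default 2).
#' @return A `ClusteringResult` (list with `dendrogram` (hclust object),
#'   `assignment`, `agreement`), or `NULL` with a warning when fewer than 2
#'   features are available.
#' @export
cluster_samples <- function(m, ann, k = 2L) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  X <- m$values
  if (nrow(X) < 2L) {
    warning("fewer than 2 features; clustering skipped", call. = FALSE)
    return(NULL)
  }
  if (ncol(X) < 3L) stop("need at least 3 samples", call. = FALSE)
  cls <- check_annotation(ann, m, min_per_class = 1L)
  Z <- t(apply(X, 1L, function(v) {
    s <- stats::sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
  h <- stats::hclust(stats::dist(t(Z)), method = "complete")
  grp <- stats::cutree(h, k = k)
  acc1 <- mean((grp == 1L) == (cls == "case"))
  structure(list(dendrogram = h, assignment = grp,
                 agreement = max(acc1, 1 - acc1)),
            class = "ClusteringResult")
}

#' @export
print.ClusteringResult <- function(x, ...) {
  cat(sprintf("ClusteringResult: %d samples in %d groups, label agreement %.3f\n",
              length(x$assignment), length(unique(x$assignment)),
              x$agreement))
  invisible(x)
}

#' Evaluate nominated candidate miRNAs as single-marker classifiers
#'
#' For every candidate, builds its ROC curve over the annotated samples of
#' the miRNA matrix (orientation from the candidate's LSOSS direction) and
#' clusters the samples on the joint candidate expression.
#'
#' @param nominated Data frame from [nominate()].
#' @param outliers Data frame from [lsoss_scan()] supplying per-miRNA
#'   `direction`.
#' @param mirna_expr The miRNA `ExpressionMatrix`.
#' @param ann A `SampleAnnotation`.
#' @return An `EvaluationReport`: list with `summary` (data frame `mirna_id,
#'   auc, sensitivity, specificity, accuracy`), `roc` (named list of
#'   `RocResult`) and `clustering` (a `ClusteringResult` or `NULL`).
#' @export
evaluate_candidates <- function(nominated, outliers, mirna_expr, ann) {
  cand <- nominated$mirna_id[nominated$is_candidate]
  empty <- data.frame(mirna_id = character(), auc = numeric(),
                      sensitivity = numeric(), specificity = numeric(),
                      accuracy = numeric(), stringsAsFactors = FALSE)
  if (!length(cand))
    return(structure(list(summary = empty, roc = list(), clustering = NULL),
                     class = "EvaluationReport"))
  cls <- check_annotation(ann, mirna_expr, min_per_class = 1L)
  roc <- list()
  for (id in cand) {
    dir <- outliers$direction[match(id, outliers$feature_id)]
    if (is.na(dir))
      stop("candidate '", id, "' has no outlier-scan direction",
           call. = FALSE)
    roc[[id]] <- roc_curve(mirna_expr$values[id, ], cls, direction = dir)
  }
  summary <- data.frame(
    mirna_id = cand,
    auc = vapply(roc, `[[`, 0, "auc"),
    sensitivity = vapply(roc, `[[`, 0, "sensitivity"),
    specificity = vapply(roc, `[[`, 0, "specificity"),
    accuracy = vapply(roc, `[[`, 0, "accuracy"),
    stringsAsFactors = FALSE, row.names = NULL)
  clustering <- if (length(cand) >= 2L)
    cluster_samples(subset_features(mirna_expr, cand), ann)
  else {
    warning("fewer than 2 candidates; clustering skipped", call. = FALSE)
    NULL
  }
  structure(list(summary = summary, roc = roc, clustering = clustering),
            class = "EvaluationReport")
}

#' Write evaluation artifacts to disk
#'
#' Writes the candidate table, the per-candidate evaluation summary, one
#' `roc_<miRNA>.tsv` (`threshold, fpr, tpr`) per candidate and, when
#' requested, a clustered heatmap and an overlay ROC plot as PNGs.
#'
#' @param report An `EvaluationReport`.
#' @param nominated Data frame from [nominate()].
#' @param mirna_expr The miRNA `ExpressionMatrix` (for the heatmap).
#' @param ann A `SampleAnnotation`.
#' @param dir Output directory (created if needed).
#' @param plots Render PNG figures (default TRUE).
#' @return `dir`, invisibly.
#' @export
write_evaluation <- function(report, nominated, mirna_expr, ann, dir,
                             plots = TRUE) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory '", dir, "'", call. = FALSE)
  utils::write.table(nominated, file.path(dir, "mirna_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$summary, file.path(dir, "evaluation_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (id in names(report$roc)) {
    safe <- gsub("[^A-Za-z0-9._-]", "_", id)
    utils::write.table(report$roc[[id]]$curve,
                       file.path(dir, paste0("roc_", safe, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cand <- nominated$mirna_id[nominated$is_candidate]
  if (plots && length(cand) >= 1L) {
    grDevices::png(file.path(dir, "roc_curves.png"), width = 800,
                   height = 800)
    graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 2, col = "grey",
                   xlab = "False positive rate", ylab = "True positive rate",
                   main = "Candidate miRNA ROC curves")
    for (i in seq_along(report$roc)) {
      cv <- report$roc[[i]]$curve
      graphics::lines(cv$fpr, cv$tpr, col = i)
    }
    graphics::legend("bottomright", legend = names(report$roc),
                     col = seq_along(report$roc), lty = 1, cex = 0.8)
    grDevices::dev.off()
  }
  if (plots && length(cand) >= 2L) {
    cls <- ann$class_label[match(sample_ids(mirna_expr), ann$sample_id)]
    anno <- data.frame(class = cls,
                       row.names = sample_ids(mirna_expr))
    grDevices::png(file.path(dir, "heatmap.png"), width = 900, height = 600)
    pheatmap::pheatmap(mirna_expr$values[cand, , drop = FALSE],
                       scale = "row", clustering_method = "complete",
                       annotation_col = anno, main = "Candidate miRNAs")
    grDevices::dev.off()
  }
  invisible(dir)
}
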