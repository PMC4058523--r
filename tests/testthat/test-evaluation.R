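test_that("ROC handles separation, ties and direction correctly", {
  labels <- rep(c("control", "case"), c(4, 6))
  r <- roc_curve(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10), labels, "up")
  expect_equal(r$auc, 1)
  expect_equal(r$accuracy, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  # identical scores: midrank convention gives AUC 0.5
  r <- roc_curve(rep(4, 10), labels, "up")
  expect_equal(r$auc, 0.5)
  # single-class labels are a hard error
  expect_error(roc_curve(1:4, rep("case", 4), "up"), "both classes")
})

test_that("rank AUC equals the pair-counting oracle, ties included", {
  set.seed(91)
  for (i in 1:60) {
    n1 <- sample(3:10, 1)
    n0 <- sample(3:10, 1)
    labels <- rep(c("case", "control"), c(n1, n0))
    scores <- sample(1:6, n1 + n0, replace = TRUE) + # heavy ties
      round(rnorm(n1 + n0), 1)
    r <- roc_curve(scores, labels, "up")
    expect_identical(r$auc, oracle_auc(scores, labels))
  }
})

test_that("AUC is monotone-invariant and direction-flip maps to 1 - AUC", {
  set.seed(92)
  labels <- rep(c("control", "case"), c(6, 9))
  s <- rnorm(15)
  a <- roc_curve(s, labels, "up")$auc
  expect_equal(roc_curve(exp(s), labels, "up")$auc, a)
  expect_equal(roc_curve(s^3 + s, labels, "up")$auc, a)
  expect_equal(roc_curve(s, labels, "down")$auc, 1 - a)
})

test_that("ROC curves are proper monotone staircases", {
  set.seed(93)
  labels <- rep(c("control", "case"), c(5, 8))
  for (dir in c("up", "down")) {
    r <- roc_curve(rnorm(13), labels, dir)
    cv <- r$curve
    expect_equal(cv$fpr[1], 0)
    expect_equal(cv$tpr[1], 0)
    expect_equal(cv$fpr[nrow(cv)], 1)
    expect_equal(cv$tpr[nrow(cv)], 1)
    expect_true(all(diff(cv$fpr) >= 0))
    expect_true(all(diff(cv$tpr) >= 0))
    # accuracy consistent with sens/spec at the operating point
    n1 <- 8; n0 <- 5
    expect_equal(r$accuracy,
                 (r$sensitivity * n1 + r$specificity * n0) / (n1 + n0))
  }
})

test_that("rank AUC agrees with pROC on a random instance", {
  set.seed(94)
  labels <- rep(c("control", "case"), c(8, 12))
  scores <- rnorm(20)
  a <- roc_curve(scores, labels, "up")$auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores, levels = c("control", "case"),
    direction = "<", quiet = TRUE)))
  expect_equal(a, ref)
})

test_that("clustering separates well-separated groups and scores agreement", {
  set.seed(95)
  # two clean blobs: 5 features shifted by 6 SD in all case samples
  n0 <- 6; n1 <- 19
  X <- matrix(rnorm(5 * (n0 + n1)), 5, n0 + n1)
  X[, (n0 + 1):(n0 + n1)] <- X[, (n0 + 1):(n0 + n1)] + 6
  dimnames(X) <- list(paste0("f", 1:5), paste0("s", 1:(n0 + n1)))
  ann <- sample_annotation(data.frame(
    sample_id = colnames(X),
    class_label = rep(c("control", "case"), c(n0, n1)),
    pair_key = paste0("p", 1:(n0 + n1))))
  cl <- cluster_samples(expression_matrix(X, "miRNA", TRUE), ann)
  expect_equal(cl$agreement, 1)
  expect_true(all(table(cl$assignment) %in% c(n0, n1)))
  # label-free random data: agreement hovers near the chance level given the
  # 6/19 imbalance (majority-vote floor 0.76), far from the separable case
  ag <- replicate(20, {
    Y <- matrix(rnorm(5 * 25), 5, 25,
                dimnames = list(paste0("f", 1:5), paste0("s", 1:25)))
    cluster_samples(expression_matrix(Y, "miRNA", TRUE), ann)$agreement
  })
  expect_gt(mean(ag), 0.5)
  expect_lt(mean(ag), 0.95)
  # fewer than 2 features: skipped with a warning
  expect_warning(
    out <- cluster_samples(expression_matrix(X[1, , drop = FALSE],
                                             "miRNA", TRUE), ann),
    "skipped")
  expect_null(out)
})

test_that("3-sample dendrogram matches the hand-worked merge order", {
  # f2 = 2 * f1, so both rows standardise to the same profile; all pairwise
  # sample distances follow by direct arithmetic
  X <- rbind(f1 = c(0, 1, 10), f2 = c(0, 2, 20))
  colnames(X) <- c("sA", "sB", "sC")
  ann <- sample_annotation(data.frame(
    sample_id = c("sA", "sB", "sC"),
    class_label = c("control", "control", "case"),
    pair_key = c("p1", "p2", "p3")))
  cl <- cluster_samples(expression_matrix(X, "miRNA", TRUE), ann)
  z1 <- (c(0, 1, 10) - mean(c(0, 1, 10))) / stats::sd(c(0, 1, 10))
  d_ab <- sqrt(2) * abs(z1[1] - z1[2])
  d_ac <- sqrt(2) * abs(z1[1] - z1[3])
  h <- cl$dendrogram
  expect_equal(h$merge, rbind(c(-1L, -2L), c(-3L, 1L)))
  expect_equal(h$height, c(d_ab, d_ac)) # complete linkage: max of d_ac, d_bc
})

test_that("candidate evaluation ties ROC direction to the outlier scan", {
  coh <- small_cohort(seed = 96)
  outliers <- lsoss_scan(coh$mirna, coh$annotation, n_perm = 49, seed = 1)
  nominated <- data.frame(
    mirna_id = coh$truth$regulators[1:2],
    alpha = 3L, beta = 4L, z = 0.75, p_alpha = 0.01, is_candidate = TRUE)
  rep <- evaluate_candidates(nominated, outliers, coh$mirna, coh$annotation)
  expect_equal(nrow(rep$summary), 2L)
  expect_true(all(rep$summary$auc > 0.5)) # direction-aware, planted signal
  expect_s3_class(rep$clustering, "ClusteringResult")
  # empty candidate set: empty report, no clustering
  none <- nominated[0, ]
  rep0 <- evaluate_candidates(none, outliers, coh$mirna, coh$annotation)
  expect_equal(nrow(rep0$summary), 0L)
  expect_null(rep0$clustering)
})

test_that("evaluation artifacts are written and reruns are byte-identical", {
  coh <- small_cohort(seed = 97)
  outliers <- lsoss_scan(coh$mirna, coh$annotation, n_perm = 49, seed = 1)
  nominated <- data.frame(
    mirna_id = coh$truth$regulators[1:2],
    alpha = 3L, beta = 4L, z = 0.75, p_alpha = 0.01, is_candidate = TRUE)
  rep <- evaluate_candidates(nominated, outliers, coh$mirna, coh$annotation)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_evaluation(rep, nominated, coh$mirna, coh$annotation, d1,
                   plots = FALSE)
  write_evaluation(rep, nominated, coh$mirna, coh$annotation, d2,
                   plots = FALSE)
  for (f in c("mirna_scores.tsv", "evaluation_summary.tsv")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  expect_length(list.files(d1, pattern = "^roc_.*tsv$"), 2L)
})
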