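test_that("lsoss_split finds the least-SS contiguous split", {
  # two internally constant subsets -> zero cost at the boundary
  s <- lsoss_split(c(1, 1, 1, 9))
  expect_equal(s$k, 3L)
  expect_equal(s$cost, 0)
  s <- lsoss_split(c(0, 10))
  expect_equal(s$k, 1L)
  expect_equal(s$cost, 0)
  # constant vector is degenerate
  s <- lsoss_split(rep(2, 5))
  expect_equal(s$k, 1L)
  expect_equal(s$cost, 0)
  expect_true(s$degenerate)
  expect_error(lsoss_split(3), "at least 2")
  # oracle equivalence on random instances
  set.seed(101)
  for (i in 1:50) {
    v <- rnorm(sample(5:12, 1))
    got <- lsoss_split(v)
    want <- oracle_lsoss_split(v)
    expect_equal(got$k, want$k)
    expect_equal(got$cost, want$cost, tolerance = 1e-10)
  }
})

test_that("lsoss_statistic picks the subset farther from controls", {
  r <- lsoss_statistic(c(5, 5, 5, 5), c(5, 5, 5))
  expect_equal(r$statistic, 0)
  expect_true(r$degenerate)
  r <- lsoss_statistic(c(0, 0, 0, 8, 9), c(0, 0, 0, 0))
  expect_setequal(r$outlier_idx, c(4L, 5L))
  expect_equal(r$direction, "up")
  expect_true(r$statistic > 0)
  # down-outliers detected symmetrically
  r <- lsoss_statistic(c(10, 10, 10, 2, 1), c(10, 10, 10, 10))
  expect_setequal(r$outlier_idx, c(4L, 5L))
  expect_equal(r$direction, "down")
  # location and positive-scale equivariance
  set.seed(7)
  ca <- rnorm(12); co <- rnorm(6)
  t0 <- lsoss_statistic(ca, co)$statistic
  expect_equal(lsoss_statistic(ca + 5, co + 5)$statistic, t0)
  expect_equal(lsoss_statistic(ca * 3.7, co * 3.7)$statistic, t0)
  expect_equal(lsoss_statistic(-ca, -co)$statistic, -t0)
})

test_that("planted subset shifts raise |t_L| above null features", {
  set.seed(21)
  n_case <- 19; n_ctrl <- 6
  stats_shift <- stats_null <- numeric(100)
  for (i in 1:100) {
    ca <- rnorm(n_case); co <- rnorm(n_ctrl)
    shift_idx <- sample(n_case, 8)
    ca_s <- ca; ca_s[shift_idx] <- ca_s[shift_idx] + 3
    stats_shift[i] <- abs(lsoss_statistic(ca_s, co)$statistic)
    stats_null[i] <- abs(lsoss_statistic(ca, co)$statistic)
  }
  expect_gt(mean(stats_shift), mean(stats_null))
  expect_gt(stats::wilcox.test(stats_shift, stats_null,
                               alternative = "greater")$statistic,
            100 * 100 * 0.75) # clear rank separation, not a fluke
})

test_that("lsoss_scan agrees with the per-feature statistic and is deterministic", {
  coh <- small_cohort(seed = 5, n_mirna = 12, n_gene = 30)
  m <- coh$mirna
  sc1 <- lsoss_scan(m, coh$annotation, n_perm = 99, seed = 3)
  sc2 <- lsoss_scan(m, coh$annotation, n_perm = 99, seed = 3)
  expect_identical(sc1, sc2)
  # R-level statistic (same floor) matches the compiled scan
  cls <- coh$annotation$class_label[match(sample_ids(m),
                                          coh$annotation$sample_id)]
  ca <- m$values[, cls == "case", drop = FALSE]
  co <- m$values[, cls == "control", drop = FALSE]
  for (f in c(1, 5, 12)) {
    r <- lsoss_statistic(ca[f, ], co[f, ])
    expect_equal(sc1$statistic[f], r$statistic, tolerance = 1e-8)
    expect_equal(sc1$split_index[f], r$split_index)
    expect_equal(sc1$direction[f], r$direction)
  }
})

test_that("a deterministic class indicator attains the smallest p-value", {
  # 4 + 4 samples so that label permutations can be reasoned about exactly:
  # only case sets equal to the true set (or its complement) reproduce |t|.
  v <- matrix(rnorm(8 * 8, 5, 0.3), 8, 8,
              dimnames = list(paste0("f", 1:8), paste0("s", 1:8)))
  v[1, ] <- c(0, 0, 0, 0, 10, 10, 10, 10)
  m <- expression_matrix(v, "miRNA", log_scale = TRUE)
  ann <- sample_annotation(data.frame(
    sample_id = paste0("s", 1:8),
    class_label = rep(c("control", "case"), each = 4),
    pair_key = paste0("p", 1:8)))
  sc <- lsoss_scan(m, ann, n_perm = 999, seed = 9, null_pool = "feature")
  expect_equal(which.min(sc$p_value), 1L)
  # 2 of the 70 possible case sets tie the indicator's |t|; with 999 draws
  # the per-feature p stays near (1 + 999 * 2/70) / 1000
  expect_lt(sc$p_value[1], 0.06)
  expect_gte(sc$p_value[1], 1 / 1000)
})

test_that("an all-constant matrix yields p = 1 everywhere", {
  v <- matrix(3, 4, 10,
              dimnames = list(paste0("f", 1:4), paste0("s", 1:10)))
  ann <- sample_annotation(data.frame(
    sample_id = paste0("s", 1:10),
    class_label = rep(c("control", "case"), c(4, 6)),
    pair_key = paste0("p", 1:10)))
  m <- expression_matrix(v, "miRNA", log_scale = TRUE)
  for (pool in c("feature", "all")) {
    sc <- lsoss_scan(m, ann, n_perm = 49, seed = 1, null_pool = pool)
    expect_true(all(sc$statistic == 0))
    expect_true(all(sc$p_value == 1))
  }
  # n_perm = 0: statistics still returned, p/q missing
  sc <- lsoss_scan(m, ann, n_perm = 0, seed = 1)
  expect_true(all(is.na(sc$p_value)))
  expect_true(all(is.na(sc$q_value)))
  expect_equal(nrow(sc), 4L)
})

test_that("permutation p-values are super-uniform under the null", {
  # label-exchangeable data: fraction of p < 0.05 stays within binomial
  # sampling bounds of 0.05 for both null schemes
  set.seed(33)
  v <- matrix(rnorm(400 * 25), 400, 25,
              dimnames = list(paste0("f", 1:400), paste0("s", 1:25)))
  ann <- sample_annotation(data.frame(
    sample_id = paste0("s", 1:25),
    class_label = rep(c("control", "case"), c(6, 19)),
    pair_key = paste0("p", 1:25)))
  m <- expression_matrix(v, "miRNA", log_scale = TRUE)
  for (pool in c("feature", "all")) {
    sc <- lsoss_scan(m, ann, n_perm = 199, seed = 17, null_pool = pool)
    frac <- mean(sc$p_value < 0.05)
    se <- sqrt(0.05 * 0.95 / 400)
    expect_lt(frac, 0.05 + 3 * se)
    expect_gt(frac, 0.05 - 3 * se)
  }
})

test_that("LSOSS beats the classical t-test on subset-outlier signal", {
  # 3-SD shift in 40% of case samples; detection rate at a matched
  # permutation-p cutoff, using the same label permutations for both
  set.seed(55)
  n_case <- 19; n_ctrl <- 6; n_feat <- 60; n_perm <- 120
  labels <- rep(c("control", "case"), c(n_ctrl, n_case))
  X <- matrix(rnorm(n_feat * 25), n_feat, 25)
  k_shift <- round(0.4 * n_case)
  for (f in 1:n_feat) {
    idx <- n_ctrl + sample(n_case, k_shift)
    X[f, idx] <- X[f, idx] + 3
  }
  perms <- replicate(n_perm, sample(25))
  detect <- function(stat_fun) {
    hits <- 0
    for (f in 1:n_feat) {
      obs <- abs(stat_fun(X[f, labels == "case"], X[f, labels == "control"]))
      null <- apply(perms, 2, function(pp) {
        lp <- labels[pp]
        abs(stat_fun(X[f, lp == "case"], X[f, lp == "control"]))
      })
      p <- (1 + sum(null >= obs)) / (1 + n_perm)
      if (p < 0.05) hits <- hits + 1
    }
    hits / n_feat
  }
  rate_lsoss <- detect(function(a, b) lsoss_statistic(a, b)$statistic)
  rate_t <- detect(oracle_t_stat)
  expect_gt(rate_lsoss, rate_t)
})

test_that("outlier selection supports FDR and top-N rules", {
  res <- data.frame(feature_id = paste0("f", 1:5),
                    statistic = c(8, -6, 1, 0.5, 3),
                    q_value = c(0.001, 0.01, 0.9, 0.8, 0.2))
  expect_equal(select_outliers(res)$feature_id, c("f1", "f2"))
  expect_equal(select_outliers(res, top_n = 3)$feature_id,
               c("f1", "f2", "f5"))
  res$q_value <- NA_real_
  expect_error(select_outliers(res), "top_n")
})
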