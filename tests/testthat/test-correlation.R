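test_that("spearman rho is exact on monotone vectors and tie-corrected", {
  expect_equal(spearman_test(1:5, 5:1)$rho, -1)
  expect_equal(spearman_test(1:5, 1:5)$rho, 1)
  expect_equal(spearman_test(1:5, 5:1)$p_value, 0)
  # tie-corrected: Pearson of midranks
  x <- c(1, 2, 2, 3, 4)
  y <- c(9, 7, 7, 4, 1)
  expect_equal(spearman_test(x, y)$rho,
               suppressWarnings(stats::cor(x, y, method = "spearman")))
  # constant vector is skipped with a reason, not an error
  r <- spearman_test(c(1, 1, 1, 1), c(1, 2, 3, 4))
  expect_true(is.na(r$rho))
  expect_match(r$reason, "constant")
})

test_that("t-approximation p is close to exhaustive permutation enumeration", {
  set.seed(61)
  for (i in 1:12) {
    n <- sample(5:7, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    exact_pkg <- spearman_test(x, y, exact = TRUE)$p_value
    exact_orc <- oracle_spearman_exact_p(x, y)
    expect_equal(exact_pkg, exact_orc, tolerance = 1e-12)
    # the t-approximation tracks the enumeration from n = 6 up; at n = 5 its
    # worst-case deviation is ~0.08 (a property of the approximation itself)
    if (n >= 6)
      expect_lt(abs(spearman_test(x, y)$p_value - exact_orc), 0.05)
  }
})

test_that("rho is invariant under strictly monotone transforms", {
  set.seed(62)
  x <- rnorm(10)
  y <- rnorm(10)
  r0 <- spearman_test(x, y)$rho
  expect_equal(spearman_test(exp(x), y)$rho, r0)
  expect_equal(spearman_test(x, y^3 + 2 * y)$rho, r0)
  expect_equal(spearman_test(x, -exp(-y))$rho, r0)
})

make_screen_fixture <- function() {
  # 6 paired samples; mirna M1 is an exact anti-monotone function of gene g1
  n <- 6
  keys <- sprintf("P%d", 1:n)
  ann <- sample_annotation(data.frame(
    sample_id = c(paste0(keys, ".m"), paste0(keys, ".g")),
    class_label = rep(rep(c("control", "case"), c(2, 4)), 2),
    pair_key = rep(keys, 2)))
  Xm <- rbind(M1 = 1:6, M2 = c(2, 1, 4, 3, 6, 5), M3 = rep(1, 6))
  colnames(Xm) <- paste0(keys, ".m")
  Xg <- rbind(g1 = 6:1, g2 = c(5, 6, 3, 4, 1, 2))
  colnames(Xg) <- paste0(keys, ".g")
  list(mirna = expression_matrix(Xm + 0.0, "miRNA", log_scale = TRUE),
       genes = expression_matrix(Xg + 0.0, "mRNA", log_scale = TRUE),
       ann = ann)
}

test_that("screen_pairs retains exactly the inverse pairs at the cutoffs", {
  fx <- make_screen_fixture()
  pairs <- screen_pairs(c("M1", "M2", "M3"), c("g1", "g2"),
                        fx$mirna, fx$genes, fx$ann)
  # M1-g1 is rho = -1, retained; the constant M3 is skipped
  expect_true(any(pairs$mirna_id == "M1" & pairs$gene_id == "g1"))
  expect_equal(pairs$rho[pairs$mirna_id == "M1" & pairs$gene_id == "g1"], -1)
  expect_false(any(pairs$mirna_id == "M3"))
  expect_equal(attr(pairs, "n_tested"), 6L)
  expect_equal(attr(pairs, "n_skipped"), 2L)
  expect_equal(pairs$n_samples[1], 6L)
  # sorted by rho ascending
  expect_true(!is.unsorted(pairs$rho))
})

test_that("the rho cutoff is inclusive at -0.6 and excludes weaker pairs", {
  # rank patterns engineered to exact rho values on n = 5:
  # sum d^2 = 32 -> rho = -0.6 ; sum d^2 = 30 -> rho = -0.5
  n <- 5
  keys <- sprintf("P%d", 1:n)
  ann <- sample_annotation(data.frame(
    sample_id = c(paste0(keys, ".m"), paste0(keys, ".g")),
    class_label = rep(rep(c("control", "case"), c(2, 3)), 2),
    pair_key = rep(keys, 2)))
  Xm <- rbind(M1 = 1:5 + 0.0)
  colnames(Xm) <- paste0(keys, ".m")
  Xg <- rbind(g_at = c(3, 5, 4, 1, 2) + 0.0,  # rho exactly -0.6
              g_off = c(3, 4, 5, 1, 2) + 0.0) # rho exactly -0.5
  colnames(Xg) <- paste0(keys, ".g")
  me <- expression_matrix(Xm, "miRNA", log_scale = TRUE)
  ge <- expression_matrix(Xg, "mRNA", log_scale = TRUE)
  expect_equal(spearman_test(Xm[1, ], Xg[1, ])$rho, -0.6)
  expect_equal(spearman_test(Xm[1, ], Xg[2, ])$rho, -0.5)
  pairs <- screen_pairs("M1", c("g_at", "g_off"), me, ge, ann,
                        p_cutoff = 1) # isolate the rho boundary
  expect_equal(pairs$gene_id, "g_at")
})

test_that("retained set shrinks monotonically in the cutoffs", {
  set.seed(63)
  coh <- small_cohort(seed = 63)
  mids <- feature_ids(coh$mirna)[1:8]
  gids <- feature_ids(coh$genes)[1:20]
  loose <- screen_pairs(mids, gids, coh$mirna, coh$genes, coh$annotation,
                        rho_cutoff = -0.3, p_cutoff = 0.2)
  tight_rho <- screen_pairs(mids, gids, coh$mirna, coh$genes,
                            coh$annotation, rho_cutoff = -0.7, p_cutoff = 0.2)
  tight_p <- screen_pairs(mids, gids, coh$mirna, coh$genes, coh$annotation,
                          rho_cutoff = -0.3, p_cutoff = 0.01)
  key <- function(df) paste(df$mirna_id, df$gene_id)
  expect_true(all(key(tight_rho) %in% key(loose)))
  expect_true(all(key(tight_p) %in% key(loose)))
  expect_equal(attr(loose, "n_tested"), length(mids) * length(gids))
})

test_that("planted regulator-target pairs are recovered, decoys at chance", {
  coh <- small_cohort(seed = 64, n_regulators = 4, n_mirna = 20, n_gene = 60)
  truth <- coh$truth
  # screen all planted regulators against all their exclusive targets plus
  # decoy genes, using known ground truth rather than the outlier scan
  excl <- truth$edges[truth$edges$exclusive, ]
  decoy_genes <- setdiff(feature_ids(coh$genes), truth$edges$gene_id)[1:30]
  pairs <- screen_pairs(truth$regulators,
                        c(excl$gene_id, decoy_genes),
                        coh$mirna, coh$genes, coh$annotation)
  key <- paste(pairs$mirna_id, pairs$gene_id)
  planted_key <- paste(excl$mirna_id, excl$gene_id)
  expect_true(all(planted_key %in% key)) # generative |rho| ~ 0.89 pairs
  decoy_hits <- sum(pairs$gene_id %in% decoy_genes)
  n_decoy_tests <- length(truth$regulators) * length(decoy_genes)
  expect_lt(decoy_hits / n_decoy_tests, 0.05 + 0.03)
  expect_error(screen_pairs("M1", "g1", coh$mirna, coh$genes,
                            sample_annotation(data.frame(
                              sample_id = c("q.m", "q.g", "w.m", "w.g"),
                              class_label = c("case", "case", "control", "control"),
                              pair_key = c("q1", "q2", "w1", "w2")))),
               "annotation|shared")
})
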