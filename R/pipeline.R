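#' Default pipeline configuration
#'
#' Flat, human-editable configuration (YAML on disk). Thresholds default to
#' the standard settings of the method: Spearman cutoff rho <= -0.6 with
#' p < 0.05 for the inverse screen, Z >= 0.3 with alpha > 1 and
#' p_alpha < 0.05 for nomination, BH q < 0.05 for outlier selection, 999
#' permutations, log2 with pseudocount 1 for input transformation. The
#' `simulate` block describes the synthetic cohort used when no input paths
#' are given; setting any of `mirna_path`, `gene_path`, `annotation_path`,
#' `network_path` switches to file inputs (all four are then required).
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    mirna_path = NULL,
    gene_path = NULL,
    annotation_path = NULL,
    network_path = NULL,
    apply_log = FALSE,        # log2-transform file inputs
    pseudocount = 1,
    outlier_q_cutoff = 0.05,
    outlier_top_n = NULL,     # overrides the q cutoff when set
    rho_cutoff = -0.6,
    corr_p_cutoff = 0.05,
    sample_mode = "all",      # or "case"
    z_cutoff = 0.3,
    alpha_min = 1,
    alpha_p_cutoff = 0.05,
    n_perm = 999,
    seed = 1,
    plots = TRUE,
    simulate = list(
      n_control = 6, n_case = 19,
      n_mirna = 100, n_gene = 500,
      n_regulators = 10, targets_per_regulator = 4,
      exclusive_per_regulator = 3,
      planted_effect = 3, outlier_fraction = 0.6,
      slope = 1, target_noise_frac = 0.5,
      noise_sd = 1, n_extra_edges = 300
    )
  )
}

# Fill unset keys with defaults and validate ranges before any computation.
validate_config <- function(cfg) {
  def <- default_config()
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), names(def))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(cfg$seed))
    stop("config: seed must be given explicitly", call. = FALSE)
  for (k in names(def))
    if (is.null(cfg[[k]]) && !k %in% c("outlier_top_n", "mirna_path",
                                       "gene_path", "annotation_path",
                                       "network_path"))
      cfg[[k]] <- def[[k]]
  if (is.list(cfg$simulate))
    for (k in names(def$simulate))
      if (is.null(cfg$simulate[[k]])) cfg$simulate[[k]] <- def$simulate[[k]]
  chk <- function(cond, msg) if (!cond) stop("config: ", msg, call. = FALSE)
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1L && is.finite(cfg$seed),
      "seed must be a single integer")
  chk(cfg$rho_cutoff >= -1 && cfg$rho_cutoff <= 0,
      "rho_cutoff must lie in [-1, 0]")
  chk(cfg$corr_p_cutoff > 0 && cfg$corr_p_cutoff <= 1,
      "corr_p_cutoff must lie in (0, 1]")
  chk(cfg$outlier_q_cutoff > 0 && cfg$outlier_q_cutoff <= 1,
      "outlier_q_cutoff must lie in (0, 1]")
  chk(cfg$z_cutoff >= 0 && cfg$z_cutoff <= 1, "z_cutoff must lie in [0, 1]")
  chk(cfg$alpha_p_cutoff > 0 && cfg$alpha_p_cutoff <= 1,
      "alpha_p_cutoff must lie in (0, 1]")
  chk(cfg$alpha_min >= 0, "alpha_min must be >= 0")
  chk(cfg$n_perm >= 1, "n_perm must be >= 1")
  chk(cfg$pseudocount >= 0, "pseudocount must be >= 0")
  chk(cfg$sample_mode %in% c("all", "case"),
      "sample_mode must be 'all' or 'case'")
  paths <- c(cfg$mirna_path, cfg$gene_path, cfg$annotation_path,
             cfg$network_path)
  chk(length(paths) %in% c(0L, 4L),
      "either all four input paths or none (simulate) must be given")
  cfg
}

# Stage seeds derive from the master seed by fixed offsets so that each stage
# is independently reproducible; kept below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% 2147483647)
}

#' Run the full biomarker-discovery pipeline
#'
#' Stage order: data loading (or synthetic simulation) -> LSOSS outlier
#' detection on both matrices -> Spearman inverse-correlation screen ->
#' subnetwork construction against the reference network -> exclusive-target
#' Z-scoring and candidate nomination -> ROC / clustering evaluation. With
#' an output directory, every stage writes its TSV artifact plus a run
#' summary with stage-by-stage counts and the verbatim configuration; runs
#' with the same configuration and seed are byte-identical. Per-stage seeds
#' derive from `cfg$seed` by fixed offsets (cohort +101, network +202, miRNA
#' scan +303, gene scan +404, rewiring +505).
#'
#' @param cfg Configuration list (see [default_config()]) or path to a YAML
#'   file of the same shape.
#' @param out_dir Output directory; `NULL` runs in memory without writing.
#' @return Invisibly, a list with all stage results (`outliers_mirna`,
#'   `outliers_gene`, `pairs`, `network`, `scores`, `evaluation`, `truth`
#'   when simulated) and `counts`, the stage-by-stage accounting.
#' @export
run_pipeline <- function(cfg = default_config(), out_dir = NULL) {
  if (is.character(cfg) && length(cfg) == 1L) cfg <- yaml::read_yaml(cfg)
  cfg <- validate_config(cfg)
  seed <- as.integer(cfg$seed)

  simulated <- is.null(cfg$mirna_path)
  if (simulated) {
    s <- cfg$simulate
    truth <- ground_truth(
      n_regulators = s$n_regulators,
      targets_per_regulator = s$targets_per_regulator,
      exclusive_per_regulator = s$exclusive_per_regulator,
      planted_effect = s$planted_effect,
      outlier_fraction = s$outlier_fraction,
      slope = s$slope, target_noise_frac = s$target_noise_frac)
    cohort <- generate_cohort(truth, n_control = s$n_control,
                              n_case = s$n_case, n_mirna = s$n_mirna,
                              n_gene = s$n_gene, noise_sd = s$noise_sd,
                              seed = derive_seed(seed, 101L))
    mirna <- cohort$mirna
    genes <- cohort$genes
    ann <- cohort$annotation
    reference <- generate_reference_network(
      truth, n_mirna = s$n_mirna, n_gene = s$n_gene,
      n_extra_edges = s$n_extra_edges, seed = derive_seed(seed, 202L))
  } else {
    truth <- NULL
    mirna <- read_expression(cfg$mirna_path, "miRNA",
                             log_scale = !cfg$apply_log)
    genes <- read_expression(cfg$gene_path, "mRNA",
                             log_scale = !cfg$apply_log)
    ann <- read_annotation(cfg$annotation_path)
    reference <- read_edge_list(cfg$network_path)
    if (cfg$apply_log) {
      mirna <- log_transform(mirna, cfg$pseudocount)
      genes <- log_transform(genes, cfg$pseudocount)
    }
  }

  out_m <- lsoss_scan(mirna, ann, n_perm = cfg$n_perm,
                      seed = derive_seed(seed, 303L))
  out_g <- lsoss_scan(genes, ann, n_perm = cfg$n_perm,
                      seed = derive_seed(seed, 404L))
  sel_m <- select_outliers(out_m, q_cutoff = cfg$outlier_q_cutoff,
                           top_n = cfg$outlier_top_n)
  sel_g <- select_outliers(out_g, q_cutoff = cfg$outlier_q_cutoff,
                           top_n = cfg$outlier_top_n)

  pairs <- screen_pairs(sel_m, sel_g, mirna, genes, ann,
                        rho_cutoff = cfg$rho_cutoff,
                        p_cutoff = cfg$corr_p_cutoff,
                        sample_mode = cfg$sample_mode)
  net <- build_subnetwork(pairs, reference)

  if (nrow(net$edges) > 0L) {
    scores <- poma_scores(net, n_perm = cfg$n_perm,
                          seed = derive_seed(seed, 505L))
    nominated <- nominate(scores, z_cutoff = cfg$z_cutoff,
                          alpha_min = cfg$alpha_min,
                          p_cutoff = cfg$alpha_p_cutoff)
  } else {
    nominated <- data.frame(mirna_id = character(), alpha = integer(),
                            beta = integer(), z = numeric(),
                            p_alpha = numeric(), is_candidate = logical(),
                            stringsAsFactors = FALSE)
  }
  evaluation <- evaluate_candidates(nominated, out_m, mirna, ann)

  # Stage-count monotonicity: candidates within subnetwork miRNAs within
  # outlier miRNAs.
  cand <- nominated$mirna_id[nominated$is_candidate]
  stopifnot(all(net$mirnas %in% sel_m$feature_id),
            all(cand %in% net$mirnas))

  ns <- subnetwork_summary(net)
  counts <- c(
    n_mirna_features = nrow(out_m),
    n_gene_features = nrow(out_g),
    n_mirna_outliers = nrow(sel_m),
    n_gene_outliers = nrow(sel_g),
    n_pairs_tested = attr(pairs, "n_tested"),
    n_pairs_retained = nrow(pairs),
    net_nodes = unname(ns[["nodes"]]),
    net_mirnas = unname(ns[["mirnas"]]),
    net_genes = unname(ns[["genes"]]),
    net_edges = unname(ns[["edges"]]),
    n_candidates = length(cand))

  result <- list(config = cfg, counts = counts, mirna = mirna, genes = genes,
                 annotation = ann, reference = reference,
                 outliers_mirna = out_m, outliers_gene = out_g,
                 selected_mirna = sel_m, selected_gene = sel_g,
                 pairs = pairs, network = net, nominated = nominated,
                 evaluation = evaluation, truth = truth)

  if (!is.null(out_dir)) write_run(result, out_dir)
  invisible(result)
}

# Persist every stage artifact plus run summary and config echo.
write_run <- function(result, out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory '", out_dir, "'", call. = FALSE)
  wt <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  wt(result$outliers_mirna, "mirna_outlier_scan.tsv")
  wt(result$outliers_gene, "gene_outlier_scan.tsv")
  wt(result$selected_mirna, "mirna_outliers.tsv")
  wt(result$selected_gene, "gene_outliers.tsv")
  wt(result$pairs, "inverse_pairs.tsv")
  write_subnetwork(result$network, file.path(out_dir, "subnetwork_edges.tsv"))
  if (!is.null(result$truth))
    write_truth(result$truth, file.path(out_dir, "truth.tsv"))
  write_evaluation(result$evaluation, result$nominated, result$mirna,
                   result$annotation, out_dir,
                   plots = isTRUE(result$config$plots))
  ev <- result$evaluation$summary
  summary <- data.frame(
    key = c(names(result$counts), "auc_min", "auc_max", "accuracy_min",
            "accuracy_max", "clustering_agreement"),
    value = c(unname(result$counts),
              if (nrow(ev)) round(min(ev$auc), 4) else NA,
              if (nrow(ev)) round(max(ev$auc), 4) else NA,
              if (nrow(ev)) round(min(ev$accuracy), 4) else NA,
              if (nrow(ev)) round(max(ev$accuracy), 4) else NA,
              if (!is.null(result$evaluation$clustering))
                round(result$evaluation$clustering$agreement, 4) else NA),
    stringsAsFactors = FALSE)
  wt(summary, "run_summary.tsv")
  writeLines(run_banner(result), file.path(out_dir, "run_summary.txt"))
  yaml::write_yaml(result$config, file.path(out_dir, "run_config.yaml"))
  invisible(out_dir)
}

# Human-readable accounting, mirroring the usual node/edge and AUC-range
# reporting of this kind of study.
run_banner <- function(result) {
  cnt <- result$counts
  ev <- result$evaluation$summary
  lines <- c(
    sprintf("features: %d miRNAs, %d genes",
            cnt[["n_mirna_features"]], cnt[["n_gene_features"]]),
    sprintf("outliers: %d miRNAs, %d genes",
            cnt[["n_mirna_outliers"]], cnt[["n_gene_outliers"]]),
    sprintf("inverse pairs retained: %d of %d tested",
            cnt[["n_pairs_retained"]], cnt[["n_pairs_tested"]]),
    sprintf("subnetwork: %d nodes, %d miRNAs, %d genes, %d interactions",
            cnt[["net_nodes"]], cnt[["net_mirnas"]], cnt[["net_genes"]],
            cnt[["net_edges"]]),
    sprintf("candidates: %d", cnt[["n_candidates"]]))
  if (nrow(ev)) {
    lines <- c(lines,
      sprintf("AUC range: %.3f-%.3f", min(ev$auc), max(ev$auc)),
      sprintf("accuracy range: %.1f%%-%.1f%%", 100 * min(ev$accuracy),
              100 * max(ev$accuracy)))
    if (!is.null(result$evaluation$clustering))
      lines <- c(lines, sprintf("clustering agreement: %.3f",
                                result$evaluation$clustering$agreement))
  } else {
    lines <- c(lines, "0 candidates: no evaluation performed")
  }
  lines
}

#' Benchmark the pipeline over simulated cohorts
#'
#' Runs the end-to-end pipeline on freshly simulated cohorts for several
#' seeds and aggregates recovery and calibration metrics against the planted
#' ground truth. With `planted = FALSE` the cohort has zero planted
#' regulators (a pure null).
#'
#' @param seeds Integer vector of master seeds, one run per seed.
#' @param cfg Base configuration (see [default_config()]).
#' @param planted Plant regulators (`TRUE`) or run the null (`FALSE`).
#' @return List with `per_seed` (data frame of per-run counts and metrics)
#'   and `pooled` (sensitivity / precision pooled over runs, mean candidate
#'   count, fraction of scan permutation p-values below 0.05, mean
#'   clustering agreement, and the min over runs of the per-run minimum
#'   candidate AUC).
#' @export
benchmark_pipeline <- function(seeds, cfg = default_config(),
                               planted = TRUE) {
  cfg <- validate_config(cfg)
  if (!planted) cfg$simulate$n_regulators <- 0L
  rows <- list()
  p_lt <- 0; p_tot <- 0
  for (s in seeds) {
    cfg$seed <- as.integer(s)
    cfg$plots <- FALSE
    res <- suppressWarnings(suppressMessages(run_pipeline(cfg)))
    rec <- recovery_metrics(res$nominated, if (planted) res$truth
                            else ground_truth(n_regulators = 0L))
    pv <- c(res$outliers_mirna$p_value, res$outliers_gene$p_value)
    p_lt <- p_lt + sum(pv < 0.05)
    p_tot <- p_tot + length(pv)
    ev <- res$evaluation$summary
    planted_auc <- if (planted && nrow(ev)) {
      keep <- ev$mirna_id %in% res$truth$regulators
      if (any(keep)) min(ev$auc[keep]) else NA_real_
    } else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      seed = s,
      n_mirna_outliers = res$counts[["n_mirna_outliers"]],
      n_gene_outliers = res$counts[["n_gene_outliers"]],
      n_pairs = res$counts[["n_pairs_retained"]],
      net_edges = res$counts[["net_edges"]],
      n_candidates = rec$n_candidates,
      n_true = rec$n_true,
      n_rich = rec$n_rich,
      min_planted_auc = planted_auc,
      mean_auc = if (nrow(ev)) mean(ev$auc) else NA_real_,
      agreement = if (!is.null(res$evaluation$clustering))
        res$evaluation$clustering$agreement else NA_real_,
      stringsAsFactors = FALSE)
  }
  per_seed <- do.call(rbind, rows)
  pooled <- list(
    sensitivity = if (sum(per_seed$n_rich) > 0)
      sum(per_seed$n_true) / sum(per_seed$n_rich) else NA_real_,
    precision = if (sum(per_seed$n_candidates) > 0)
      sum(per_seed$n_true) / sum(per_seed$n_candidates) else NA_real_,
    mean_candidates = mean(per_seed$n_candidates),
    frac_p_lt_05 = p_lt / p_tot,
    mean_agreement = mean(per_seed$agreement, na.rm = TRUE),
    min_planted_auc = if (all(is.na(per_seed$min_planted_auc))) NA_real_
      else min(per_seed$min_planted_auc, na.rm = TRUE))
  list(per_seed = per_seed, pooled = pooled)
}
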