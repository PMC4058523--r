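#' Ground-truth plan for a synthetic cohort
#'
#' Defines the planted regulatory structure of a synthetic study: a set of
#' regulator miRNAs, each with a target set split into exclusively-owned
#' targets (in-degree 1 in the planted edge structure) and targets shared
#' with a partner regulator (regulators are paired 1-2, 3-4, ...; with an odd
#' count the last regulator shares with the first). Each regulator carries a
#' subset-outlier expression shift of `planted_effect` within-class SDs in a
#' random `outlier_fraction` of case samples, alternating up/down direction,
#' and each planted target is anticorrelated with its regulator(s) through a
#' linear repression term of strength `slope` (see [generate_cohort()]).
#'
#' @param n_regulators Number of planted regulator miRNAs (0 gives a pure
#'   null cohort).
#' @param targets_per_regulator Total targets per regulator.
#' @param exclusive_per_regulator How many of those targets are exclusive.
#' @param planted_effect Outlier shift in units of the within-class SD.
#' @param outlier_fraction Fraction of case samples carrying the shift.
#' @param slope Linear repression coefficient linking target to regulator.
#' @param target_noise_frac Residual target noise, as a fraction of the
#'   global noise SD; with the defaults the generative regulator-target
#'   anticorrelation magnitude is at least 0.89 for exclusive targets.
#' @return An object of class `GroundTruth`.
#' @export
ground_truth <- function(n_regulators = 10L, targets_per_regulator = 4L,
                         exclusive_per_regulator = 3L, planted_effect = 3,
                         outlier_fraction = 0.6, slope = 1,
                         target_noise_frac = 0.5) {
  if (exclusive_per_regulator > targets_per_regulator)
    stop("exclusivity plan infeasible: more exclusive targets than targets",
         call. = FALSE)
  n_shared <- targets_per_regulator - exclusive_per_regulator
  if (n_regulators == 1L && n_shared > 0L)
    stop("exclusivity plan infeasible: shared targets need >= 2 regulators",
         call. = FALSE)
  if (outlier_fraction <= 0 || outlier_fraction > 1)
    stop("`outlier_fraction` must be in (0, 1]", call. = FALSE)

  regulators <- if (n_regulators > 0L)
    sprintf("mir-P%02d", seq_len(n_regulators)) else character()
  edges <- data.frame(mirna_id = character(), gene_id = character(),
                      exclusive = logical(), stringsAsFactors = FALSE)
  gene_counter <- 0L
  new_genes <- function(k, tag) {
    ids <- sprintf("gene-%s%03d", tag, gene_counter + seq_len(k))
    gene_counter <<- gene_counter + k
    ids
  }
  if (n_regulators > 0L) {
    for (i in seq_len(n_regulators)) {
      ex <- new_genes(exclusive_per_regulator, "X")
      if (length(ex))
        edges <- rbind(edges, data.frame(mirna_id = regulators[i],
                                         gene_id = ex, exclusive = TRUE,
                                         stringsAsFactors = FALSE))
    }
    if (n_shared > 0L) {
      for (i in seq(1L, n_regulators, by = 2L)) {
        j <- if (i + 1L <= n_regulators) i + 1L else 1L
        if (j == i) break
        sh <- new_genes(n_shared, "S")
        edges <- rbind(edges,
          data.frame(mirna_id = rep(regulators[c(i, j)], each = n_shared),
                     gene_id = rep(sh, 2L), exclusive = FALSE,
                     stringsAsFactors = FALSE))
      }
    }
  }
  directions <- if (n_regulators > 0L)
    stats::setNames(rep(c("up", "down"), length.out = n_regulators),
                    regulators) else character()
  structure(list(regulators = regulators, edges = edges,
                 directions = directions, planted_effect = planted_effect,
                 outlier_fraction = outlier_fraction, slope = slope,
                 target_noise_frac = target_noise_frac),
            class = "GroundTruth")
}

#' Per-regulator alpha/beta/Z implied by a ground-truth plan
#' @param truth A `GroundTruth`.
#' @return Data frame `mirna_id, alpha, beta, z` computed on the planted
#'   edge structure alone.
#' @export
planned_scores <- function(truth) {
  stopifnot(inherits(truth, "GroundTruth"))
  if (nrow(truth$edges) == 0L)
    return(data.frame(mirna_id = character(), alpha = integer(),
                      beta = integer(), z = numeric(),
                      stringsAsFactors = FALSE))
  score_mirnas(regulatory_subnetwork(truth$edges))
}

# Deterministic feature-ID universes shared by cohort and reference network.
mirna_universe <- function(truth, n_mirna) {
  k <- length(truth$regulators)
  if (n_mirna < k) stop("`n_mirna` smaller than the planted regulator count",
                        call. = FALSE)
  c(truth$regulators, sprintf("mir-D%03d", seq_len(n_mirna - k)))
}

gene_universe <- function(truth, n_gene) {
  planted <- unique(truth$edges$gene_id)
  if (n_gene < length(planted))
    stop("`n_gene` smaller than the planted target count", call. = FALSE)
  c(planted, sprintf("gene-D%04d", seq_len(n_gene - length(planted))))
}

#' Generate a paired synthetic miRNA/mRNA cohort with planted signal
#'
#' Baseline expression is i.i.d. Normal on the log scale: each feature draws
#' a mean from `mu_range` and per-sample noise with SD `noise_sd`. Each
#' planted regulator is shifted by `planted_effect * noise_sd` (sign per its
#' direction) in a random `outlier_fraction` of the case samples -- the
#' subset-outlier regime the LSOSS statistic targets. Each planted target
#' equals its baseline minus `slope` times the mean deviation of its
#' regulator(s) from their baseline mean, plus residual noise of SD
#' `target_noise_frac * noise_sd`, which yields generative anticorrelation
#' (magnitude >= slope / sqrt(slope^2 + target_noise_frac^2) for exclusive
#' targets, about 0.89 at the defaults). Decoy miRNAs and genes are pure
#' noise. All randomness flows from the single `seed`; the draw order is
#' miRNA means, miRNA noise, per-regulator outlier subsets, gene means, gene
#' noise.
#'
#' @param truth A `GroundTruth`.
#' @param n_control,n_case Samples per class (defaults 6 and 19).
#' @param n_mirna,n_gene Total feature counts (defaults 100 and 500).
#' @param noise_sd Within-class SD on the log scale (default 1).
#' @param mu_range Range for per-feature baseline means (default 4-10).
#' @param seed Integer seed (mandatory).
#' @return List with `mirna` and `genes` (`ExpressionMatrix`, log scale),
#'   `annotation` (`SampleAnnotation`; miRNA and mRNA profiles of the same
#'   subject share a `pair_key`) and `truth`.
#' @export
generate_cohort <- function(truth, n_control = 6L, n_case = 19L,
                            n_mirna = 100L, n_gene = 500L, noise_sd = 1,
                            mu_range = c(4, 10), seed = 1L) {
  stopifnot(inherits(truth, "GroundTruth"))
  if (n_control < 2L || n_case < 2L)
    stop("need at least 2 samples per class", call. = FALSE)
  n_out <- round(truth$outlier_fraction * n_case)
  if (length(truth$regulators) > 0L && n_out < 2L)
    stop("outlier_fraction * n_case < 2: the ordered-subset split is ",
         "undefined", call. = FALSE)
  mids <- mirna_universe(truth, n_mirna)
  gids <- gene_universe(truth, n_gene)
  n <- n_control + n_case
  keys <- sprintf("P%02d", seq_len(n))
  cls <- rep(c("control", "case"), c(n_control, n_case))
  ann <- sample_annotation(data.frame(
    sample_id = c(paste0(keys, ".mir"), paste0(keys, ".rna")),
    class_label = rep(cls, 2L),
    pair_key = rep(keys, 2L),
    stringsAsFactors = FALSE))

  set.seed(seed)
  mu_m <- stats::runif(n_mirna, mu_range[1L], mu_range[2L])
  M <- mu_m + matrix(stats::rnorm(n_mirna * n, sd = noise_sd), n_mirna, n)
  case_cols <- which(cls == "case")
  for (r in truth$regulators) {
    i <- match(r, mids)
    subset <- sample(case_cols, n_out)
    sgn <- if (truth$directions[[r]] == "down") -1 else 1
    M[i, subset] <- M[i, subset] + sgn * truth$planted_effect * noise_sd
  }
  mu_g <- stats::runif(n_gene, mu_range[1L], mu_range[2L])
  G <- matrix(0, n_gene, n)
  planted <- unique(truth$edges$gene_id)
  for (j in seq_len(n_gene)) {
    gid <- gids[j]
    if (gid %in% planted) {
      regs <- truth$edges$mirna_id[truth$edges$gene_id == gid]
      ridx <- match(regs, mids)
      dev <- M[ridx, , drop = FALSE] - mu_m[ridx]
      G[j, ] <- mu_g[j] - truth$slope * colMeans(dev) +
        stats::rnorm(n, sd = truth$target_noise_frac * noise_sd)
    } else {
      G[j, ] <- mu_g[j] + stats::rnorm(n, sd = noise_sd)
    }
  }
  rownames(M) <- mids
  colnames(M) <- paste0(keys, ".mir")
  rownames(G) <- gids
  colnames(G) <- paste0(keys, ".rna")
  list(mirna = expression_matrix(M, "miRNA", log_scale = TRUE),
       genes = expression_matrix(G, "mRNA", log_scale = TRUE),
       annotation = ann, truth = truth)
}

#' Generate a reference interaction network realising a ground-truth plan
#'
#' Contains every planted (regulator, target) edge -- so the exclusivity
#' plan's in-degrees are realised exactly -- plus `n_extra_edges` random
#' decoy edges from any miRNA to decoy genes only, which cannot disturb the
#' planted in-degree structure.
#'
#' @param truth A `GroundTruth`.
#' @param n_mirna,n_gene Feature-universe sizes (must match
#'   [generate_cohort()]).
#' @param n_extra_edges Number of decoy edges (default 300).
#' @param seed Integer seed.
#' @return An `InteractionEdgeList` with a `source` column
#'   (`planted`/`decoy`).
#' @export
generate_reference_network <- function(truth, n_mirna = 100L, n_gene = 500L,
                                       n_extra_edges = 300L, seed = 1L) {
  stopifnot(inherits(truth, "GroundTruth"))
  mids <- mirna_universe(truth, n_mirna)
  gids <- gene_universe(truth, n_gene)
  planted <- truth$edges
  if (nrow(planted)) {
    indeg <- table(planted$gene_id)
    excl_plan <- unique(planted$gene_id[planted$exclusive])
    bad <- excl_plan[indeg[excl_plan] != 1L]
    if (length(bad))
      stop("exclusivity plan infeasible: planned-exclusive gene(s) with ",
           "in-degree > 1: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  decoy_genes <- setdiff(gids, unique(planted$gene_id))
  if (n_extra_edges > 0L && !length(decoy_genes))
    stop("no decoy genes available for extra edges", call. = FALSE)
  edges <- if (nrow(planted))
    data.frame(mirna_id = planted$mirna_id, gene_id = planted$gene_id,
               source = "planted", stringsAsFactors = FALSE)
  else
    data.frame(mirna_id = character(), gene_id = character(),
               source = character(), stringsAsFactors = FALSE)
  set.seed(seed)
  have <- character(0)
  while (length(have) < n_extra_edges) {
    k <- n_extra_edges - length(have)
    cand <- paste(sample(mids, 2L * k, replace = TRUE),
                  sample(decoy_genes, 2L * k, replace = TRUE), sep = "\t")
    have <- unique(c(have, cand))[seq_len(min(n_extra_edges,
                                              length(unique(c(have, cand)))))]
  }
  if (n_extra_edges > 0L) {
    parts <- strsplit(have, "\t", fixed = TRUE)
    edges <- rbind(edges, data.frame(
      mirna_id = vapply(parts, `[`, "", 1L),
      gene_id = vapply(parts, `[`, "", 2L),
      source = "decoy", stringsAsFactors = FALSE))
  }
  interaction_edge_list(edges)
}

#' Write the planted ground truth as TSV
#' @param truth A `GroundTruth`.
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  df <- truth$edges
  df$direction <- unname(truth$directions[df$mirna_id])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Recovery of planted regulators by a nomination run
#'
#' Compares the nominated candidate set with the exclusivity-rich planted
#' regulators -- those whose planned structure alone satisfies the default
#' nomination thresholds (Z >= 0.3 and alpha >= 2).
#'
#' @param nominated Data frame from [nominate()].
#' @param truth A `GroundTruth`.
#' @return List with `n_rich`, `n_candidates`, `n_true`, `sensitivity` and
#'   `precision` (`NA` when there are no candidates).
#' @export
recovery_metrics <- function(nominated, truth) {
  ps <- planned_scores(truth)
  rich <- ps$mirna_id[ps$z >= 0.3 & ps$alpha >= 2L]
  cand <- nominated$mirna_id[nominated$is_candidate]
  n_true <- length(intersect(cand, rich))
  list(n_rich = length(rich), n_candidates = length(cand), n_true = n_true,
       sensitivity = if (length(rich)) n_true / length(rich) else NA_real_,
       precision = if (length(cand)) n_true / length(cand) else NA_real_)
}
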