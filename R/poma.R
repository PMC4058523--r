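#' Exclusive-regulation Z-scores for every miRNA in a subnetwork
#'
#' For each miRNA m in the condition-specific subnetwork: `beta` is its
#' out-degree (all genes it targets there), `alpha` the number of those
#' targets whose in-degree within the subnetwork is exactly 1 (genes targeted
#' exclusively by m), and `Z = alpha / beta`. A high Z marks a miRNA with
#' independent regulatory power over its deregulated targets. Two exact
#' accounting identities hold on any instance: the alphas sum to the number
#' of in-degree-1 genes and the betas sum to the edge count.
#'
#' @param net A nonempty `RegulatorySubnetwork`.
#' @return Data frame `mirna_id, alpha, beta, z`, one row per miRNA, sorted
#'   by `mirna_id`.
#' @export
score_mirnas <- function(net) {
  stopifnot(inherits(net, "RegulatorySubnetwork"))
  e <- net$edges
  if (nrow(e) == 0L) stop("subnetwork is empty", call. = FALSE)
  indeg <- table(e$gene_id)
  exclusive <- names(indeg)[indeg == 1L]
  beta <- table(factor(e$mirna_id, levels = net$mirnas))
  alpha <- table(factor(e$mirna_id[e$gene_id %in% exclusive],
                        levels = net$mirnas))
  data.frame(mirna_id = net$mirnas,
             alpha = as.integer(alpha),
             beta = as.integer(beta),
             z = as.integer(alpha) / as.integer(beta),
             stringsAsFactors = FALSE)
}

#' Permutation significance of the exclusive-target count alpha
#'
#' Null model: degree-preserving rewiring of the bipartite subnetwork by
#' checkerboard swaps (two edges exchange their gene endpoints whenever the
#' swap creates no duplicate edge), which fixes every miRNA out-degree and
#' every gene in-degree while randomising which targets are exclusive. A
#' single chain makes `swap_factor * n_edges` attempts between consecutive
#' samples; per miRNA,
#' `p_alpha = (1 + #\{alpha_perm >= alpha_obs\}) / (1 + n_perm)`.
#' When no admissible swap exists (e.g. a complete bipartite graph) the null
#' is degenerate, every p is 1 and a warning is raised.
#'
#' @param net A nonempty `RegulatorySubnetwork`.
#' @param n_perm Number of null samples (default 999).
#' @param seed Integer seed.
#' @param swap_factor Swap attempts per sample, as a multiple of the edge
#'   count (default 10).
#' @param return_gene_ends Keep the rewired gene endpoints per sample (for
#'   degree audits) as attribute `gene_ends`.
#' @return Named numeric vector of p-values, one per miRNA (names =
#'   `mirna_id`).
#' @export
alpha_significance <- function(net, n_perm = 999L, seed = 1L,
                               swap_factor = 10L, return_gene_ends = FALSE) {
  stopifnot(inherits(net, "RegulatorySubnetwork"))
  if (n_perm < 1L) stop("`n_perm` must be >= 1", call. = FALSE)
  e <- net$edges
  if (nrow(e) == 0L) stop("subnetwork is empty", call. = FALSE)
  mi <- match(e$mirna_id, net$mirnas)
  gi <- match(e$gene_id, net$genes)
  set.seed(seed)
  res <- rewire_alpha_null(mi, gi, length(net$mirnas), length(net$genes),
                           as.integer(n_perm),
                           as.integer(swap_factor * nrow(e)),
                           isTRUE(return_gene_ends))
  if (res$accepted == 0)
    warning("degree-preserving rewiring found no admissible swap; ",
            "the null is degenerate and all p-values are 1", call. = FALSE)
  obs <- score_mirnas(net) # sorted by mirna_id = net$mirnas
  p <- (1 + rowSums(res$alpha >= obs$alpha)) / (1 + n_perm)
  names(p) <- net$mirnas
  if (isTRUE(return_gene_ends)) attr(p, "gene_ends") <- res$gene_ends
  p
}

#' Attach alpha p-values to a score table
#' @param net A nonempty `RegulatorySubnetwork`.
#' @param n_perm,seed,swap_factor Passed to [alpha_significance()].
#' @return The [score_mirnas()] table with a `p_alpha` column.
#' @export
poma_scores <- function(net, n_perm = 999L, seed = 1L, swap_factor = 10L) {
  scores <- score_mirnas(net)
  p <- alpha_significance(net, n_perm = n_perm, seed = seed,
                          swap_factor = swap_factor)
  scores$p_alpha <- unname(p[scores$mirna_id])
  scores
}

#' Nominate candidate miRNAs by Z-score thresholds
#'
#' A miRNA is a candidate when `Z >= z_cutoff` (inclusive, default 0.3), its
#' exclusive-target count is significantly large (`alpha > alpha_min`,
#' strict, default `alpha_min = 1` i.e. alpha >= 2) and
#' `p_alpha < p_cutoff` (default 0.05). Candidates are sorted by Z
#' descending, ties by alpha descending then lexical miRNA ID.
#'
#' @param scores Data frame from [poma_scores()] (must carry `p_alpha`).
#' @param z_cutoff,alpha_min,p_cutoff Nomination thresholds.
#' @return `scores` with an `is_candidate` flag, candidates first.
#' @export
nominate <- function(scores, z_cutoff = 0.3, alpha_min = 1L,
                     p_cutoff = 0.05) {
  if (!"p_alpha" %in% colnames(scores))
    stop("`scores` must carry a p_alpha column (see poma_scores())",
         call. = FALSE)
  scores$is_candidate <- scores$z >= z_cutoff &
    scores$alpha > alpha_min &
    scores$p_alpha < p_cutoff
  ord <- order(!scores$is_candidate, -scores$z, -scores$alpha,
               scores$mirna_id)
  out <- scores[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
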