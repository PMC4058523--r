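#' Construct a regulatory subnetwork from a validated edge table
#'
#' Low-level constructor: takes a data frame of directed miRNA -> gene edges
#' (optionally with `rho` / `p_value` provenance) and derives the node
#' partitions. Node sets are exactly the endpoints of the edges, so the
#' network has no isolated nodes.
#'
#' @param edges Data frame with columns `mirna_id`, `gene_id` and optionally
#'   `rho`, `p_value`.
#' @return An object of class `RegulatorySubnetwork`.
#' @export
regulatory_subnetwork <- function(edges) {
  need <- c("mirna_id", "gene_id")
  missing <- setdiff(need, colnames(edges))
  if (length(missing))
    stop("edges lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  keep <- intersect(c(need, "rho", "p_value"), colnames(edges))
  edges <- as.data.frame(edges)[, keep, drop = FALSE]
  edges$mirna_id <- as.character(edges$mirna_id)
  edges$gene_id <- as.character(edges$gene_id)
  if (anyDuplicated(edges[, need]))
    stop("duplicate edges in subnetwork", call. = FALSE)
  clash <- intersect(unique(edges$mirna_id), unique(edges$gene_id))
  if (length(clash))
    stop("miRNA and gene namespaces overlap: ",
         paste(utils::head(clash, 5L), collapse = ", "), call. = FALSE)
  edges <- edges[order(edges$mirna_id, edges$gene_id), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges,
                 mirnas = sort(unique(edges$mirna_id)),
                 genes = sort(unique(edges$gene_id))),
            class = "RegulatorySubnetwork")
}

#' Build the condition-specific miRNA-mRNA subnetwork
#'
#' Intersects the inverse-correlated pairs with the reference interaction
#' edge list: the subnetwork edge set is exactly the screened pairs that are
#' supported by the reference network, keeping each pair's rho and p-value as
#' edge provenance. Set semantics: the result is independent of input order
#' and idempotent. An empty intersection yields an empty subnetwork with a
#' warning (not an error); if none of the pair miRNAs occurs in the reference
#' at all, a loud ID-namespace warning is raised.
#'
#' @param pairs Data frame from [screen_pairs()].
#' @param reference An `InteractionEdgeList`.
#' @return A `RegulatorySubnetwork`.
#' @export
build_subnetwork <- function(pairs, reference) {
  stopifnot(is.data.frame(pairs), inherits(reference, "InteractionEdgeList"))
  pkey <- paste(pairs$mirna_id, pairs$gene_id, sep = "\r")
  rkey <- paste(reference$mirna_id, reference$gene_id, sep = "\r")
  keep <- pkey %in% rkey
  cols <- intersect(c("mirna_id", "gene_id", "rho", "p_value"),
                    colnames(pairs))
  edges <- pairs[keep, cols, drop = FALSE]
  edges <- edges[!duplicated(paste(edges$mirna_id, edges$gene_id, sep = "\r")), ,
                 drop = FALSE]
  if (nrow(pairs) > 0L && nrow(edges) == 0L) {
    if (!any(pairs$mirna_id %in% reference$mirna_id))
      warning("none of the pair miRNA IDs occurs in the reference network; ",
              "check for an ID-scheme mismatch", call. = FALSE)
    else
      warning("no inverse-correlated pair is supported by the reference ",
              "network; subnetwork is empty", call. = FALSE)
  }
  net <- regulatory_subnetwork(edges)
  message(sprintf("subnetwork: %d nodes (%d miRNAs + %d genes), %d edges",
                  length(net$mirnas) + length(net$genes),
                  length(net$mirnas), length(net$genes), nrow(net$edges)))
  net
}

#' @export
print.RegulatorySubnetwork <- function(x, ...) {
  s <- subnetwork_summary(x)
  cat(sprintf(
    "RegulatorySubnetwork: %d nodes, %d miRNAs, %d genes, %d interactions\n",
    s[["nodes"]], s[["mirnas"]], s[["genes"]], s[["edges"]]))
  invisible(x)
}

#' One-line node/edge accounting of a subnetwork
#' @param net A `RegulatorySubnetwork`.
#' @return Named integer vector `nodes, mirnas, genes, edges`; nodes is
#'   always the sum of the two partitions.
#' @export
subnetwork_summary <- function(net) {
  stopifnot(inherits(net, "RegulatorySubnetwork"))
  c(nodes = length(net$mirnas) + length(net$genes),
    mirnas = length(net$mirnas),
    genes = length(net$genes),
    edges = nrow(net$edges))
}

#' Write subnetwork edges as TSV
#' @param net A `RegulatorySubnetwork`.
#' @param path Output path.
#' @export
write_subnetwork <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Convert a subnetwork to an igraph object
#' @param net A nonempty `RegulatorySubnetwork`.
#' @return A directed bipartite `igraph` graph with a logical `type` vertex
#'   attribute (TRUE for genes).
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "RegulatorySubnetwork"))
  if (nrow(net$edges) == 0L) stop("subnetwork is empty", call. = FALSE)
  verts <- data.frame(
    name = c(net$mirnas, net$genes),
    type = c(rep(FALSE, length(net$mirnas)), rep(TRUE, length(net$genes))),
    stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(net$edges, directed = TRUE, vertices = verts)
}

#' Export a subnetwork as GraphML for external viewers
#' @param net A nonempty `RegulatorySubnetwork`.
#' @param path Output path.
#' @export
export_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}
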