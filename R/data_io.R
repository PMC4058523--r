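#' Construct an expression matrix
#'
#' Container for a features-by-samples expression table. Row names are
#' feature IDs, column names are sample IDs; both must be unique and all
#' values finite. The `log_scale` flag records whether values have already
#' been log-transformed, so that [log_transform()] cannot be applied twice.
#'
#' @param values Numeric matrix (features in rows, samples in columns) with
#'   row and column names.
#' @param feature_kind `"miRNA"` or `"mRNA"`.
#' @param log_scale Logical; `TRUE` if values are on the log scale.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, feature_kind = c("miRNA", "mRNA"),
                              log_scale = FALSE) {
  feature_kind <- match.arg(feature_kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid))
    stop("`values` must carry feature (row) and sample (column) names",
         call. = FALSE)
  if (anyDuplicated(fid))
    stop("duplicate feature ID(s): ",
         paste(unique(fid[duplicated(fid)]), collapse = ", "), call. = FALSE)
  if (anyDuplicated(sid))
    stop("duplicate sample ID(s): ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "), call. = FALSE)
  if (!all(is.finite(values)))
    stop("expression values must be finite", call. = FALSE)
  structure(list(values = values, feature_kind = feature_kind,
                 log_scale = isTRUE(log_scale)),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix (%s, %s scale): %d features x %d samples\n",
              x$feature_kind, if (x$log_scale) "log" else "raw",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Feature and sample identifiers of an expression matrix
#' @param x An `ExpressionMatrix`.
#' @return Character vector of IDs.
#' @export
feature_ids <- function(x) rownames(x$values)

#' @rdname feature_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Restrict an expression matrix to a set of features
#' @param x An `ExpressionMatrix`.
#' @param ids Feature IDs to keep (all must be present).
#' @return An `ExpressionMatrix` with the selected rows, in `ids` order.
#' @export
subset_features <- function(x, ids) {
  missing <- setdiff(ids, feature_ids(x))
  if (length(missing))
    stop("feature(s) not present: ", paste(missing, collapse = ", "),
         call. = FALSE)
  expression_matrix(x$values[ids, , drop = FALSE], x$feature_kind,
                    x$log_scale)
}

#' Read an expression matrix from a tab-separated file
#'
#' Expects a header line of sample IDs, a first column of feature IDs and a
#' numeric body. Duplicated IDs and non-numeric cells are hard errors that
#' name the offending feature / coordinates.
#'
#' @param path Path to a TSV file.
#' @param feature_kind `"miRNA"` or `"mRNA"`.
#' @param log_scale Logical; set `TRUE` if the stored values are already
#'   log-transformed.
#' @return An `ExpressionMatrix`.
#' @export
read_expression <- function(path, feature_kind = c("miRNA", "mRNA"),
                            log_scale = FALSE) {
  feature_kind <- match.arg(feature_kind)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, colClasses = "character")
  if (nrow(raw) == 0L)
    stop("no features: '", path, "' has a header but an empty body",
         call. = FALSE)
  if (ncol(raw) < 2L)
    stop("expected a feature-ID column plus at least one sample column in '",
         path, "'", call. = FALSE)
  ids <- raw[[1L]]
  samples <- colnames(raw)[-1L]
  body <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(!is.finite(num), arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    stop(sprintf(
      "non-numeric value '%s' at feature '%s' (row %d), sample '%s' (column %d) in '%s'",
      body[i, j], ids[i], i, samples[j], j + 1L, path), call. = FALSE)
  }
  rownames(num) <- ids
  colnames(num) <- samples
  expression_matrix(num, feature_kind, log_scale)
}

#' Write an expression matrix as TSV
#' @param x An `ExpressionMatrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  df <- data.frame(feature_id = feature_ids(x), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct / validate a sample annotation table
#'
#' One row per sample: `sample_id`, `class_label` (`case` / `control`) and a
#' `pair_key` linking a sample's miRNA and mRNA profiles. Pairing between
#' the two expression matrices is by shared `pair_key`, never by column
#' order.
#'
#' @param df Data frame with columns `sample_id`, `class_label`, `pair_key`.
#' @return A `SampleAnnotation` data frame.
#' @export
sample_annotation <- function(df) {
  need <- c("sample_id", "class_label", "pair_key")
  missing <- setdiff(need, colnames(df))
  if (length(missing))
    stop("annotation lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(df)[, need]
  df[] <- lapply(df, as.character)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample annotation for: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "),
         call. = FALSE)
  badcls <- setdiff(unique(df$class_label), c("case", "control"))
  if (length(badcls))
    stop("class_label must be 'case' or 'control'; found: ",
         paste(badcls, collapse = ", "), call. = FALSE)
  class(df) <- c("SampleAnnotation", "data.frame")
  df
}

#' Read / write a sample annotation TSV
#' @param path Path to a TSV with columns `sample_id`, `class_label`,
#'   `pair_key`.
#' @return A `SampleAnnotation` data frame.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, colClasses = "character")
  sample_annotation(df)
}

#' @rdname read_annotation
#' @param ann A `SampleAnnotation`.
#' @export
write_annotation <- function(ann, path) {
  utils::write.table(as.data.frame(ann), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Check that every column of an expression matrix is annotated and that each
# class keeps at least `min_per_class` samples.
check_annotation <- function(ann, m, min_per_class = 2L) {
  idx <- match(sample_ids(m), ann$sample_id)
  if (anyNA(idx))
    stop("samples without annotation: ",
         paste(sample_ids(m)[is.na(idx)], collapse = ", "), call. = FALSE)
  cls <- ann$class_label[idx]
  cnt <- table(factor(cls, levels = c("case", "control")))
  if (any(cnt < min_per_class))
    stop("need at least ", min_per_class, " samples per class; got ",
         cnt[["case"]], " case / ", cnt[["control"]], " control",
         call. = FALSE)
  cls
}

#' Construct a miRNA-mRNA interaction edge list
#'
#' Deduplicated set of directed (miRNA, gene) interactions. The two ID
#' namespaces must be disjoint so the edge set is bipartite by construction.
#'
#' @param df Data frame with columns `mirna_id`, `gene_id` and optionally
#'   `source`.
#' @return An `InteractionEdgeList` data frame.
#' @export
interaction_edge_list <- function(df) {
  need <- c("mirna_id", "gene_id")
  missing <- setdiff(need, colnames(df))
  if (length(missing))
    stop("edge list lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  keep <- intersect(c(need, "source"), colnames(df))
  df <- as.data.frame(df)[, keep, drop = FALSE]
  df$mirna_id <- as.character(df$mirna_id)
  df$gene_id <- as.character(df$gene_id)
  df <- df[!duplicated(df[, need]), , drop = FALSE]
  if (nrow(df) == 0L) stop("no edges", call. = FALSE)
  clash <- intersect(unique(df$mirna_id), unique(df$gene_id))
  if (length(clash))
    stop("miRNA and gene namespaces overlap (not bipartite): ",
         paste(utils::head(clash, 5L), collapse = ", "), call. = FALSE)
  rownames(df) <- NULL
  class(df) <- c("InteractionEdgeList", "data.frame")
  df
}

#' Read a reference miRNA-mRNA interaction edge list
#'
#' Tab-separated, one interaction per row, columns `mirna_id<TAB>gene_id`
#' with an optional third provenance column. Duplicate pairs are collapsed;
#' unique miRNA / gene / edge counts are reported via [message()].
#'
#' @param path Path to the TSV.
#' @return An `InteractionEdgeList` data frame.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("no edges in '", path, "'", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  body <- fields[-1L]
  nf <- lengths(body)
  bad <- which(nf < 2L | vapply(body, function(f) !nzchar(f[1L]) || !nzchar(f[2L]), TRUE))
  if (length(bad))
    stop("malformed edge row at line ", bad[1L] + 1L, " of '", path,
         "' (need at least mirna_id<TAB>gene_id)", call. = FALSE)
  df <- data.frame(
    mirna_id = vapply(body, `[`, "", 1L),
    gene_id = vapply(body, `[`, "", 2L),
    stringsAsFactors = FALSE)
  if (length(header) >= 3L && any(nf >= 3L))
    df$source <- vapply(body, function(f) if (length(f) >= 3L) f[3L] else "", "")
  el <- interaction_edge_list(df)
  message(sprintf("edge list '%s': %d unique miRNAs, %d unique genes, %d edges",
                  path, length(unique(el$mirna_id)),
                  length(unique(el$gene_id)), nrow(el)))
  el
}

#' @rdname read_edge_list
#' @param el An `InteractionEdgeList`.
#' @export
write_edge_list <- function(el, path) {
  utils::write.table(as.data.frame(el), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Log-transform an expression matrix
#'
#' Replaces each value x by `log(x + pseudocount, base)`; log2 with
#' pseudocount 1 by default. Negative inputs are hard errors, as is a zero
#' value with pseudocount 0, and a matrix already flagged as log scale is
#' refused.
#'
#' @param m An `ExpressionMatrix` on the raw scale with nonnegative values.
#' @param pseudocount Nonnegative offset added before taking logs; must be
#'   positive if any value is exactly 0.
#' @param base Logarithm base (default 2).
#' @return The transformed `ExpressionMatrix` with `log_scale = TRUE`.
#' @export
log_transform <- function(m, pseudocount = 1, base = 2) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$log_scale)
    stop("matrix is already on the log scale", call. = FALSE)
  if (length(pseudocount) != 1L || !is.finite(pseudocount) || pseudocount < 0)
    stop("`pseudocount` must be a single nonnegative number", call. = FALSE)
  v <- m$values
  if (any(v < 0)) {
    bad <- which(v < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative expression value at feature '%s', sample '%s'",
                 rownames(v)[bad[1L]], colnames(v)[bad[2L]]), call. = FALSE)
  }
  if (pseudocount == 0 && any(v == 0))
    stop("zero values require a positive pseudocount", call. = FALSE)
  m$values <- log(v + pseudocount, base = base)
  m$log_scale <- TRUE
  m
}
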