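#' Construct a validated expression matrix
#'
#' Expression data throughout this package is a plain numeric matrix with
#' genes in rows and samples in columns, on the log2 scale, carrying unique
#' gene identifiers as rownames and unique sample identifiers as colnames.
#' This constructor attaches identifiers and enforces the invariants; most
#' functions accept any matrix that passes [validate_expression_matrix()].
#'
#' @param values numeric matrix, genes in rows, samples in columns (log2
#'   expression units).
#' @param gene_ids character vector of unique gene identifiers; defaults to
#'   existing rownames.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to existing colnames.
#' @return a numeric matrix with rownames and colnames set.
#' @examples
#' x <- expression_matrix(matrix(rnorm(12), 3, 4),
#'                        gene_ids = c("g1", "g2", "g3"),
#'                        sample_ids = paste0("s", 1:4))
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("gene_ids and sample_ids are required (as arguments or dimnames)")
  }
  rownames(values) <- as.character(gene_ids)
  colnames(values) <- as.character(sample_ids)
  validate_expression_matrix(values)
  values
}

#' Validate an expression matrix
#'
#' Checks the invariants assumed everywhere: numeric matrix, unique non-empty
#' row (gene) and column (sample) names, all values finite.
#'
#' @param x matrix to validate.
#' @return `x`, invisibly; errors if invalid.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("expression data must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(x)) || anyDuplicated(rownames(x))) {
    stop("expression matrix must have unique gene ids as rownames")
  }
  if (is.null(colnames(x)) || anyDuplicated(colnames(x))) {
    stop("expression matrix must have unique sample ids as colnames")
  }
  if (!all(is.finite(x))) {
    stop("expression matrix contains non-finite values")
  }
  invisible(x)
}

#' Collapse probe-level rows to one row per gene
#'
#' When several probes map to the same gene, the probe with the largest row
#' mean expression is kept as the gene's representative row; unmapped probes
#' are dropped. Ties on the mean are broken by probe id (first in sorted
#' order) so the result is deterministic.
#'
#' @param probe_matrix numeric matrix keyed by probe ids (rownames).
#' @param map data.frame with columns `probe_id` and `gene_id` (many probes
#'   to one gene), or a named character vector `probe_id -> gene_id`.
#' @return expression matrix with one row per gene, rownames = gene ids.
#' @export
collapse_probes <- function(probe_matrix, map) {
  validate_expression_matrix(probe_matrix)
  if (is.character(map) && !is.null(names(map))) {
    map <- data.frame(probe_id = names(map), gene_id = unname(map),
                      stringsAsFactors = FALSE)
  }
  if (!all(c("probe_id", "gene_id") %in% names(map))) {
    stop("map must have columns probe_id and gene_id")
  }
  if (anyDuplicated(map$probe_id)) {
    stop("probe ids in the map must be unique")
  }
  map <- map[map$probe_id %in% rownames(probe_matrix), , drop = FALSE]
  if (nrow(map) == 0L) {
    stop("no mappable probes")
  }
  means <- rowMeans(probe_matrix)[map$probe_id]
  # stable: sort by gene, then mean descending, then probe id
  ord <- order(map$gene_id, -means, map$probe_id)
  map <- map[ord, , drop = FALSE]
  keep <- map[!duplicated(map$gene_id), , drop = FALSE]
  out <- probe_matrix[keep$probe_id, , drop = FALSE]
  rownames(out) <- keep$gene_id
  out[order(rownames(out)), , drop = FALSE]
}

#' Remove low-expression / low-variance genes
#'
#' Drops the union of the genes in the lowest `fraction` quantile of row
#' means and the lowest `fraction` quantile of row variances, both ranked on
#' the full input universe. Each criterion cuts exactly
#' `floor(fraction * n_genes)` genes, with ties broken by gene id so the
#' result is deterministic; the retained fraction therefore lies in
#' `[1 - 2*fraction, 1 - fraction]`. On real microarray data low-mean and
#' low-variance genes largely coincide, so roughly 25% of genes are removed
#' at the default 20% cut.
#'
#' @param x expression matrix (log2 scale; statistics are computed on the
#'   values as stored).
#' @param fraction quantile cut per criterion, in (0, 0.5]; default 0.2.
#' @return the filtered expression matrix (row order preserved).
#' @export
filter_genes <- function(x, fraction = 0.2) {
  validate_expression_matrix(x)
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 0.5) {
    stop("fraction must be a single value in (0, 0.5]")
  }
  if (nrow(x) < 10L) {
    stop("filter_genes requires at least 10 genes")
  }
  n_cut <- floor(fraction * nrow(x))
  if (n_cut == 0L) return(x)
  mu <- rowMeans(x)
  v <- apply(x, 1L, stats::var)
  low_mean <- rownames(x)[order(mu, rownames(x))][seq_len(n_cut)]
  low_var <- rownames(x)[order(v, rownames(x))][seq_len(n_cut)]
  drop <- union(low_mean, low_var)
  x[!(rownames(x) %in% drop), , drop = FALSE]
}

#' Shared gene universe of two datasets
#'
#' Intersection of the gene id sets of two (typically already filtered)
#' expression matrices; symmetric in its arguments. An empty intersection is
#' returned as-is — downstream overlap scoring rejects it.
#'
#' @param x1,x2 expression matrices or character vectors of gene ids.
#' @return character vector of shared gene ids.
#' @export
common_universe <- function(x1, x2) {
  ids <- function(x) if (is.character(x)) x else rownames(x)
  intersect(ids(x1), ids(x2))
}
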