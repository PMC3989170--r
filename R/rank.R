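#' Rank genes for differential expression, optionally with SVA correction
#'
#' The full per-dataset pipeline: build the covariate-only (reduced) and
#' covariate+primary (full) designs; if an SVA method is requested, estimate
#' the latent dimensionality (unless `k` is given), estimate surrogate
#' variables, and append them to both designs; test the primary effect with
#' the nested F-test; rank genes by increasing p-value with deterministic
#' tie-breaking (p, then |F| descending, then gene id). For a two-level
#' primary factor the F-test is the square of the equal-variance t-test, so
#' this is also the package's "T-test with SV covariates".
#'
#' @param x expression matrix (already probe-collapsed / filtered as
#'   desired).
#' @param pheno phenotype table; samples must match `x` columns as a set.
#' @param method `"none"`, `"orthogonal"`, `"leek_storey"` or `"sva_star"`.
#' @param k number of surrogate variables; NULL (default) estimates it with
#'   [estimate_k()]. Ignored for `method = "none"`.
#' @param n_iter reweighting iterations for the iterative methods.
#' @param n_perm_sva permutations for the SVA* primary-effect p-values.
#' @param n_perm_k permutations for [estimate_k()].
#' @param seed RNG seed for every stochastic step.
#' @param sv optional precomputed [surrogate_variables] (rows in `x` column
#'   order); when given, SV estimation is skipped.
#' @return data.frame of class `ranked_genes`, ordered: gene_id, statistic,
#'   p_value, rank; attributes `method` and `k`.
#' @export
rank_differential_expression <- function(x, pheno,
                                         method = c("none", "orthogonal",
                                                    "leek_storey", "sva_star"),
                                         k = NULL, n_iter = 5,
                                         n_perm_sva = 200, n_perm_k = 20,
                                         seed = 1, sv = NULL) {
  method <- match.arg(method)
  validate_expression_matrix(x)
  validate_phenotype(pheno, colnames(x))
  pheno <- pheno[match(colnames(x), pheno$sample_id), , drop = FALSE]
  full <- build_design(pheno, include_primary = TRUE)
  if (method != "none" && is.null(sv)) {
    if (is.null(k)) k <- estimate_k(x, full, n_perm = n_perm_k, seed = seed)
    if (k >= 1L) {
      sv <- switch(method,
        orthogonal = residual_svd_sv(x, full, k),
        leek_storey = sva_leek_storey(x, full, k, n_iter = n_iter),
        sva_star = sva_star(x, full, k, n_iter = n_iter,
                            n_perm = n_perm_sva, seed = seed))
    }
  }
  if (method == "none") sv <- NULL
  full_sv <- build_design(pheno, include_primary = TRUE, sv = sv)
  roles <- attr(full_sv, "col_roles")
  reduced_sv <- full_sv[, names(roles)[roles != "primary"], drop = FALSE]
  res <- f_test(x, full_sv, reduced_sv)
  ranked <- rank_genes(res)
  attr(ranked, "method") <- method
  attr(ranked, "k") <- if (is.null(sv)) 0L else sv$k
  ranked
}

#' Order a gene p-value table into a ranked gene list
#'
#' Sorts by increasing p-value, breaking ties by decreasing |statistic| and
#' then by gene id, so rankings are reproducible.
#'
#' @param pvals a `gene_pvalues` data.frame (gene_id, statistic, p_value).
#' @return `ranked_genes` data.frame with an added `rank` column.
#' @export
rank_genes <- function(pvals) {
  ord <- order(pvals$p_value, -abs(pvals$statistic), pvals$gene_id)
  out <- pvals[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("ranked_genes", "data.frame")
  out
}

#' Top fraction of a ranked gene list
#'
#' The first `ceiling(fraction * n)` genes — the dataset's differential
#' expression candidate list (default: top 5%).
#'
#' @param ranked a `ranked_genes` data.frame or an ordered character vector
#'   of gene ids.
#' @param fraction fraction of the list to keep, in (0, 1).
#' @return character vector of gene ids.
#' @export
top_fraction <- function(ranked, fraction = 0.05) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  ids <- if (is.character(ranked)) ranked else ranked$gene_id
  if (length(ids) == 0L) stop("empty ranked gene list")
  ids[seq_len(ceiling(fraction * length(ids)))]
}
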