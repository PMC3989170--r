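#' AUC for discriminating gene classes by differential-expression evidence
#'
#' Area under the ROC curve for ranking `positives` above `negatives` by
#' increasing p-value: the probability that a random positive gene receives
#' a smaller p-value than a random negative gene, with ties counted one
#' half (the normalised Mann-Whitney U statistic).
#'
#' @param pvals a `gene_pvalues`/`ranked_genes` data.frame or a named
#'   numeric vector of p-values.
#' @param positives,negatives disjoint nonempty gene id sets, all present in
#'   `pvals`.
#' @return AUC in [0, 1].
#' @export
auc_gene_discrimination <- function(pvals, positives, negatives) {
  p <- if (is.data.frame(pvals)) {
    stats::setNames(pvals$p_value, pvals$gene_id)
  } else {
    pvals
  }
  if (length(positives) == 0L || length(negatives) == 0L) {
    stop("positive and negative sets must be nonempty")
  }
  if (length(intersect(positives, negatives)) > 0L) {
    stop("positive and negative gene sets overlap")
  }
  if (!all(c(positives, negatives) %in% names(p))) {
    stop("all genes must have a p-value")
  }
  n_pos <- length(positives)
  n_neg <- length(negatives)
  r <- rank(c(p[positives], p[negatives]))
  u <- n_pos * n_neg + n_pos * (n_pos + 1) / 2 - sum(r[seq_len(n_pos)])
  u / (n_pos * n_neg)
}

#' Benchmark SVA variants on repeated mixture simulations
#'
#' For each repeat, simulates a fresh mixture dataset (seed =
#' `base_seed + repeat index`), runs each requested correction method
#' through the differential-expression pipeline, and scores how well the
#' resulting p-values discriminate the `both`-class genes (group effect
#' masked by the latent variable) from the `latent` and `noise` classes.
#' Also records the number of surrogate variables and the strongest
#' group-heterogeneity among them.
#'
#' @param config a [simulation_config()]; the defaults are the benchmark
#'   conditions (1000 genes, 4 classes of 250, 20+20 samples).
#' @param n_repeats simulation repeats (default 20).
#' @param methods subset of `c("none", "orthogonal", "leek_storey",
#'   "sva_star")`.
#' @param base_seed base RNG seed; repeat `i` uses `base_seed + i`.
#' @param ... passed to [rank_differential_expression()].
#' @return data.frame of class `benchmark_result`: seed, method, auc, n_sv,
#'   min_sv_heterogeneity_p (NA when no SVs).
#' @export
run_benchmark <- function(config = simulation_config(), n_repeats = 20,
                          methods = c("none", "leek_storey", "sva_star"),
                          base_seed = 1, ...) {
  methods <- match.arg(methods,
                       c("none", "orthogonal", "leek_storey", "sva_star"),
                       several.ok = TRUE)
  rows <- list()
  for (i in seq_len(n_repeats)) {
    cfg <- config
    cfg$seed <- as.integer(base_seed + i)
    sim <- simulate_mixture_dataset(cfg)
    pos <- names(sim$gene_class)[sim$gene_class == "both"]
    neg <- names(sim$gene_class)[sim$gene_class %in% c("latent", "noise")]
    full <- build_design(sim$pheno)
    k_hat <- estimate_k(sim$x, full, seed = cfg$seed)
    for (m in methods) {
      sv <- NULL
      het <- NA_real_
      if (m != "none" && k_hat >= 1L) {
        sv <- switch(m,
          orthogonal = residual_svd_sv(sim$x, full, k_hat),
          leek_storey = sva_leek_storey(sim$x, full, k_hat),
          sva_star = sva_star(sim$x, full, k_hat, seed = cfg$seed))
        het <- min(sv_heterogeneity(sv, sim$pheno))
      }
      ranked <- rank_differential_expression(sim$x, sim$pheno, method = m,
                                             sv = sv, seed = cfg$seed, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        seed = cfg$seed, method = m,
        auc = auc_gene_discrimination(ranked, pos, neg),
        n_sv = if (is.null(sv)) 0L else sv$k,
        min_sv_heterogeneity_p = het,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("benchmark_result", "data.frame")
  out
}
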