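#' Hypergeometric overlap score for two candidate gene lists
#'
#' Restricts both sets to the shared universe, counts the overlap `k_ov`,
#' and returns the upper-tail hypergeometric probability
#' `P(K >= k_ov)` for `K ~ Hypergeometric(N, m, n)` in log space, where `m`
#' and `n` are the post-restriction candidate-list sizes and `N` the
#' universe size. An overlap of 0 scores log_p = 0 (probability 1).
#'
#' @param set_a,set_b character vectors of candidate gene ids.
#' @param universe character vector: genes present in both datasets after
#'   filtering.
#' @return list of class `overlap_score`: `k_ov`, `m`, `n`, `N`, `log_p`.
#' @export
hypergeom_overlap <- function(set_a, set_b, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty gene universe")
  a <- intersect(set_a, universe)
  b <- intersect(set_b, universe)
  k_ov <- length(intersect(a, b))
  m <- length(a)
  n <- length(b)
  nn <- length(universe)
  log_p <- stats::phyper(k_ov - 1, m, nn - m, n,
                         lower.tail = FALSE, log.p = TRUE)
  structure(list(k_ov = k_ov, m = m, n = n, N = nn,
                 log_p = min(log_p, 0)),
            class = "overlap_score")
}

#' @export
print.overlap_score <- function(x, ...) {
  cat(sprintf("overlap: k = %d of m = %d, n = %d in N = %d; log p = %.4g\n",
              x$k_ov, x$m, x$n, x$N, x$log_p))
  invisible(x)
}

#' Gene rankings under permuted phenotype labels
#'
#' Re-runs the complete differential-expression pipeline (including SVA
#' re-estimation when a method is given) on `n_perm` independent
#' permutations of the primary labels, keeping covariates attached to their
#' samples. These permuted rankings feed the dataset-pair-specific null
#' distribution of overlap scores.
#'
#' @inheritParams rank_differential_expression
#' @param n_perm number of permuted rankings (default 20).
#' @param ... passed to [rank_differential_expression()].
#' @return list of `n_perm` `ranked_genes` data.frames.
#' @export
permuted_rankings <- function(x, pheno, method = "none", n_perm = 20,
                              seed = 1, ...) {
  validate_phenotype(pheno)
  perms <- with_seed(seed, {
    lapply(seq_len(n_perm), function(b) sample.int(nrow(pheno)))
  })
  lapply(seq_len(n_perm), function(b) {
    ph <- pheno
    ph$primary <- ph$primary[perms[[b]]]
    rank_differential_expression(x, ph, method = method,
                                 seed = seed + b, ...)
  })
}

#' Empirical p-value of an observed overlap against its permutation null
#'
#' `p = (1 + #{null log_p <= observed log_p}) / (1 + n_null)`: a smaller
#' log_p is a more extreme overlap, ties count against the observation, and
#' the add-one correction keeps p in (0, 1] so it can be log-transformed.
#'
#' @param observed an `overlap_score` or a single log_p value.
#' @param null_log_p numeric vector of null log_p scores (nonempty).
#' @return empirical p-value in (0, 1].
#' @export
empirical_pvalue <- function(observed, null_log_p) {
  obs <- if (inherits(observed, "overlap_score")) observed$log_p else observed
  if (length(null_log_p) == 0L) stop("null sample is empty")
  (1 + sum(null_log_p <= obs)) / (1 + length(null_log_p))
}

#' All unordered pairs of dataset ids
#'
#' @param ids character vector of dataset ids (>= 2).
#' @return data.frame with columns `dataset_a`, `dataset_b`; `choose(D, 2)`
#'   rows.
#' @export
dataset_pairs <- function(ids) {
  if (length(ids) < 2L) stop("need at least two datasets")
  idx <- utils::combn(length(ids), 2L)
  data.frame(dataset_a = ids[idx[1L, ]], dataset_b = ids[idx[2L, ]],
             stringsAsFactors = FALSE)
}

#' Pairwise cross-study concordance with permutation-calibrated p-values
#'
#' For every unordered pair of datasets: genes are ranked in each dataset
#' (after low-expression/low-variance filtering), the top `fraction` of each
#' list is scored with [hypergeom_overlap()] on the pair's shared post-filter
#' universe, and the observed score is compared against a pair-specific null
#' of `n_perm^2` scores obtained by crossing `n_perm` label-permuted
#' rankings from each dataset. Candidate lists are cut on each dataset's own
#' universe first, then restricted to the shared universe (so `m`, `n` count
#' candidates also present in the other dataset).
#'
#' @param datasets named list; each element a list with `x` (expression
#'   matrix) and `pheno` (phenotype table).
#' @param method SVA correction applied inside the pipeline: `"none"`,
#'   `"orthogonal"`, `"leek_storey"` or `"sva_star"`.
#' @param fraction top fraction per candidate list (default 0.05).
#' @param n_perm permuted rankings per dataset (default 20, i.e. 400 null
#'   scores per pair).
#' @param seed RNG seed.
#' @param filter_fraction per-criterion quantile for [filter_genes()]
#'   applied to each dataset first; NULL skips filtering.
#' @param ... passed to [rank_differential_expression()].
#' @return data.frame of class `pairwise_concordance`: dataset_a, dataset_b,
#'   k_ov, m, n, N, log_p, empirical_p, n_null, plus a list column
#'   `null_log_p` with each pair's null sample. Pairs with an empty shared
#'   universe are recorded with NA scores.
#' @export
concordance_matrix <- function(datasets, method = "none", fraction = 0.05,
                               n_perm = 20, seed = 1,
                               filter_fraction = 0.2, ...) {
  if (length(datasets) < 2L) stop("need at least two datasets")
  ids <- names(datasets)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("datasets must be a uniquely named list")
  }
  per <- lapply(seq_along(datasets), function(d) {
    ds <- datasets[[d]]
    x <- ds$x
    if (!is.null(filter_fraction)) x <- filter_genes(x, filter_fraction)
    seed_d <- seed + (d - 1L) * 1000L
    truth <- rank_differential_expression(x, ds$pheno, method = method,
                                          seed = seed_d, ...)
    perms <- permuted_rankings(x, ds$pheno, method = method, n_perm = n_perm,
                               seed = seed_d + 1L, ...)
    list(genes = truth$gene_id,
         top = top_fraction(truth, fraction),
         perm_tops = lapply(perms, top_fraction, fraction = fraction))
  })
  names(per) <- ids
  pairs <- dataset_pairs(ids)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- per[[pairs$dataset_a[i]]]
    b <- per[[pairs$dataset_b[i]]]
    universe <- common_universe(a$genes, b$genes)
    if (length(universe) == 0L) {
      return(list(k_ov = NA_integer_, m = NA_integer_, n = NA_integer_,
                  N = 0L, log_p = NA_real_, empirical_p = NA_real_,
                  null_log_p = numeric(0)))
    }
    obs <- hypergeom_overlap(a$top, b$top, universe)
    null_lp <- as.vector(vapply(a$perm_tops, function(ta) {
      vapply(b$perm_tops, function(tb) {
        hypergeom_overlap(ta, tb, universe)$log_p
      }, numeric(1))
    }, numeric(n_perm)))
    c(obs[c("k_ov", "m", "n", "N", "log_p")],
      list(empirical_p = empirical_pvalue(obs, null_lp),
           null_log_p = null_lp))
  })
  out <- data.frame(
    dataset_a = pairs$dataset_a,
    dataset_b = pairs$dataset_b,
    k_ov = vapply(rows, function(r) as.integer(r$k_ov), integer(1)),
    m = vapply(rows, function(r) as.integer(r$m), integer(1)),
    n = vapply(rows, function(r) as.integer(r$n), integer(1)),
    N = vapply(rows, function(r) as.integer(r$N), integer(1)),
    log_p = vapply(rows, function(r) as.numeric(r$log_p), numeric(1)),
    empirical_p = vapply(rows, function(r) as.numeric(r$empirical_p),
                         numeric(1)),
    n_null = vapply(rows, function(r) length(r$null_log_p), integer(1)),
    stringsAsFactors = FALSE)
  out$null_log_p <- lapply(rows, function(r) r$null_log_p)
  attr(out, "method") <- method
  attr(out, "fraction") <- fraction
  class(out) <- c("pairwise_concordance", "data.frame")
  out
}

#' Agreement curve: pairs significant at each threshold
#'
#' Counts, for each p-value threshold, how many dataset pairs reach that
#' level of empirical significance; the counts are monotone nondecreasing in
#' the threshold.
#'
#' @param concordances a `pairwise_concordance` data.frame or a numeric
#'   vector of empirical p-values.
#' @param thresholds numeric thresholds; default 50 log-spaced values from
#'   the smallest attainable p (add-one floor of the null size, 1/401 at the
#'   default 400) to 1.
#' @return data.frame: threshold, count.
#' @export
agreement_curve <- function(concordances, thresholds = NULL) {
  p <- if (is.data.frame(concordances)) concordances$empirical_p
       else as.numeric(concordances)
  if (is.null(thresholds)) {
    floor_p <- if (is.data.frame(concordances) &&
                   any(concordances$n_null > 0)) {
      1 / (1 + max(concordances$n_null))
    } else {
      1 / 401
    }
    thresholds <- exp(seq(log(floor_p), 0, length.out = 50))
  }
  thresholds <- sort(thresholds)
  data.frame(threshold = thresholds,
             count = vapply(thresholds,
                            function(t) sum(p <= t, na.rm = TRUE),
                            numeric(1)))
}

#' One-sided signed-rank comparison of two concordance runs
#'
#' Wilcoxon signed-rank test on `log(p_a) - log(p_b)` over the same dataset
#' pairs, testing the alternative that method `a` yields smaller empirical
#' p-values (better agreement). Zero differences are dropped; if all
#' differences are zero the test is undefined and 1 is returned by
#' convention.
#'
#' @param emp_p_a,emp_p_b per-pair empirical p-values in identical pair
#'   order (numeric vectors or `pairwise_concordance` data.frames).
#' @return one-sided p-value.
#' @export
compare_methods_signed_rank <- function(emp_p_a, emp_p_b) {
  pa <- if (is.data.frame(emp_p_a)) emp_p_a$empirical_p else emp_p_a
  pb <- if (is.data.frame(emp_p_b)) emp_p_b$empirical_p else emp_p_b
  if (length(pa) != length(pb)) stop("inputs must cover the same pairs")
  d <- log(pa) - log(pb)
  d <- d[is.finite(d)]
  if (length(d) > 0L && all(d == 0)) return(1)
  d <- d[d != 0]
  if (length(d) < 6L) stop("insufficient pairs: need >= 6 non-zero differences")
  suppressWarnings(
    stats::wilcox.test(d, alternative = "less", mu = 0)$p.value
  )
}
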