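#' Surrogate variable container
#'
#' @param sv numeric matrix (n_samples x k) of surrogate variables, unit-norm
#'   columns, sign-fixed so each column's largest-magnitude entry is positive.
#' @param method estimation method tag: `"orthogonal"`, `"leek_storey"` or
#'   `"sva_star"`.
#' @param n_iter iterations used (0 for the orthogonal variant).
#' @return object of class `surrogate_variables`: list with `sv`, `method`,
#'   `k`, `n_iter`.
#' @export
surrogate_variables <- function(sv, method, n_iter = 0L) {
  sv <- as.matrix(sv)
  structure(list(sv = fix_sv_signs(sv), method = method,
                 k = ncol(sv), n_iter = as.integer(n_iter)),
            class = "surrogate_variables")
}

#' @export
print.surrogate_variables <- function(x, ...) {
  cat(sprintf("surrogate_variables: k = %d, method = %s, iterations = %d\n",
              x$k, x$method, x$n_iter))
  invisible(x)
}

# Flip each column so its largest-magnitude entry is positive; normalise to
# unit Euclidean norm. Makes SVD output reproducible across backends.
fix_sv_signs <- function(g) {
  for (j in seq_len(ncol(g))) {
    nrm <- sqrt(sum(g[, j]^2))
    if (nrm > 0) g[, j] <- g[, j] / nrm
    i <- which.max(abs(g[, j]))
    if (g[i, j] < 0) g[, j] <- -g[, j]
  }
  g
}

design_roles <- function(design) {
  roles <- attr(design, "col_roles")
  if (is.null(roles)) {
    stop("design must carry a col_roles attribute (use build_design())")
  }
  roles
}

reduced_design <- function(design) {
  roles <- design_roles(design)
  if (!any(roles == "primary")) {
    stop("design has no primary-effect columns")
  }
  design[, names(roles)[roles != "primary"], drop = FALSE]
}

max_k <- function(x, design) {
  min(ncol(x), nrow(x)) - qr(design)$rank
}

# Singular values via the small-side Gram matrix (fast when one dimension
# is much smaller than the other).
singular_values <- function(m) {
  cp <- if (nrow(m) >= ncol(m)) crossprod(m) else tcrossprod(m)
  ev <- eigen(cp, symmetric = TRUE, only.values = TRUE)$values
  sqrt(pmax(ev, 0))
}

#' Estimate the latent-space dimensionality
#'
#' Parallel-analysis style estimate: singular values of the residual matrix
#' (expression regressed on the full design) are compared with the
#' per-component 95th percentile of singular values from `n_perm` null
#' matrices, each obtained by independently permuting every gene's row of
#' the data (destroying inter-gene correlation while keeping row
#' distributions) and re-residualising on the same design, so the null
#' carries the same projection geometry as the observed residual. k is the
#' number of leading components exceeding their null percentile; 0 is
#' allowed.
#'
#' @param x expression matrix.
#' @param design full design matrix (primary effect + covariates).
#' @param n_perm number of permuted null matrices (default 20).
#' @param seed RNG seed.
#' @param quantile null percentile (default 0.95).
#' @return integer k >= 0.
#' @export
estimate_k <- function(x, design, n_perm = 20, seed = 1, quantile = 0.95) {
  validate_expression_matrix(x)
  if (nrow(x) < 2L) return(0L)
  if (ncol(x) < 6L) stop("estimate_k requires at least 6 samples")
  kmax <- max_k(x, design)
  if (kmax < 1L) return(0L)
  qr_d <- qr(design)
  q_d <- qr.Q(qr_d)[, seq_len(qr_d$rank), drop = FALSE]
  residualise <- function(m) m - tcrossprod(m %*% q_d, q_d)
  d_obs <- singular_values(residualise(x))[seq_len(kmax)]
  g <- nrow(x)
  n <- ncol(x)
  d_null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      # row-wise independent permutation, vectorised: order random keys
      # within each row of the column-major grid
      ord <- order(rep.int(seq_len(g), n), stats::runif(g * n))
      xp <- matrix(x[ord], nrow = g, byrow = TRUE)
      singular_values(residualise(xp))[seq_len(kmax)]
    }, numeric(kmax))
  })
  thresh <- apply(matrix(d_null, nrow = kmax), 1L, stats::quantile,
                  probs = quantile, names = FALSE)
  exceeds <- d_obs > thresh
  k <- if (all(exceeds)) length(exceeds) else which.min(exceeds) - 1L
  as.integer(k)
}

#' Orthogonal surrogate variables from the residual SVD
#'
#' The first k right singular vectors of the residual matrix. By
#' construction these are exactly orthogonal to every design column, so they
#' can only capture latent structure that is balanced across the
#' experimental groups.
#'
#' @param x expression matrix.
#' @param design full design matrix.
#' @param k number of surrogate variables (>= 1).
#' @return [surrogate_variables] with method `"orthogonal"`.
#' @export
residual_svd_sv <- function(x, design, k) {
  if (k < 1L) stop("k must be >= 1")
  if (k > max_k(x, design)) {
    stop("k exceeds the available residual dimensionality")
  }
  e <- fit_linear(x, design)$residuals
  v <- svd(e, nu = 0, nv = k)$v
  surrogate_variables(v, "orthogonal", 0L)
}

#' Posterior-probability gene weights (Leek-Storey scheme)
#'
#' `w = (1 - lfdr(p_G)) * lfdr(p_S)`: the estimated posterior probability
#' that a gene is associated with the latent structure and not with the
#' primary effect.
#'
#' @param p_s per-gene p-values for the primary effect (given current SVs).
#' @param p_g per-gene p-values for association with the current SVs.
#' @return weights in [0, 1].
#' @export
weights_lfdr_posterior <- function(p_s, p_g) {
  pmin(pmax((1 - estimate_lfdr(p_g)) * estimate_lfdr(p_s), 0), 1)
}

#' Raw p-value gene weights (SVA* scheme)
#'
#' `w = p_S * (1 - p_G)`: genes with strong primary-effect evidence are
#' down-weighted in proportion to their raw p-value, which bounds how
#' strongly surrogate variables can associate with the experimental groups —
#' no stronger than expected by chance in a randomized study.
#'
#' @inheritParams weights_lfdr_posterior
#' @return weights in [0, 1].
#' @export
weights_raw_pvalue <- function(p_s, p_g) {
  pmin(pmax(p_s * (1 - p_g), 0), 1)
}

# Shared iteration skeleton for the reweighted variants. p_s_fun(x, full,
# reduced, iter) returns the primary-effect p-values given the current SVs.
iterate_sva <- function(x, design, k, n_iter, p_s_fun, weight_fun, method) {
  validate_expression_matrix(x)
  if (k < 1L) stop("k must be >= 1")
  if (n_iter < 1L) stop("n_iter must be >= 1")
  if (k > max_k(x, design)) {
    stop("k exceeds the available residual dimensionality")
  }
  red <- reduced_design(design)
  e <- fit_linear(x, design)$residuals
  g <- svd(e, nu = 0, nv = k)$v
  for (i in seq_len(n_iter)) {
    colnames(g) <- paste0("sv", seq_len(k))
    mod_g <- cbind(red, g)
    p_g <- f_test(x, mod_g, red)$p_value
    p_s <- p_s_fun(x, cbind(design, g), mod_g, i)
    w <- tryCatch(weight_fun(p_s, p_g), error = function(e) {
      warning("gene weighting failed (", conditionMessage(e),
              "); using uniform weights", call. = FALSE)
      rep(1, nrow(x))
    })
    if (max(w) < 1e-8) {
      warning("all gene weights ~0; using uniform weights", call. = FALSE)
      w <- rep(1, nrow(x))
    }
    xw <- x * w
    xw <- xw - rowMeans(xw)
    g <- svd(xw, nu = 0, nv = k)$v
  }
  surrogate_variables(g, method, n_iter)
}

#' Leek-Storey iteratively reweighted surrogate variables
#'
#' Starts from the orthogonal residual-SVD estimate and iterates: per-gene
#' parametric F-tests for association with the current surrogate variables
#' (p_G, adjusting for covariates) and for the primary effect (p_S,
#' adjusting for covariates and current SVs); local-FDR posterior weights
#' `(1 - lfdr(p_G)) * lfdr(p_S)`; SVD of the row-weighted, row-centred data
#' matrix; the first k right singular vectors become the new SVs. On
#' cell-type-mixture data this weighting tends towards uniform weights and
#' yields surrogate variables that differ between the experimental groups.
#'
#' @param x expression matrix.
#' @param design full design from [build_design()] (primary + covariates).
#' @param k number of surrogate variables (>= 1); see [estimate_k()].
#' @param n_iter number of reweighting iterations (default 5).
#' @param weight_fun weighting scheme, a `function(p_s, p_g)`; default
#'   [weights_lfdr_posterior()]. If it errors (degenerate p-value histogram)
#'   uniform weights are used with a warning.
#' @return [surrogate_variables] with method `"leek_storey"`.
#' @export
sva_leek_storey <- function(x, design, k, n_iter = 5,
                            weight_fun = weights_lfdr_posterior) {
  p_s_fun <- function(x, full, reduced, iter) f_test(x, full, reduced)$p_value
  iterate_sva(x, design, k, n_iter, p_s_fun, weight_fun, "leek_storey")
}

#' Modified surrogate variable analysis (SVA*)
#'
#' Identical iteration skeleton to [sva_leek_storey()], but the gene weights
#' use raw p-values instead of local-FDR posteriors:
#' `w = p_S * (1 - p_G)`, with p_S computed by a covariate-preserving
#' permutation test ([permutation_pvalues()]) because real expression data
#' contain genes far from normality. This less aggressive weighting keeps
#' genes with primary-effect evidence down-weighted throughout, so surrogate
#' variables may be non-orthogonal to the groups but never significantly
#' heterogeneous beyond chance.
#'
#' @inheritParams sva_leek_storey
#' @param n_perm permutations for the primary-effect p-value (default 200).
#' @param seed RNG seed; output is deterministic given the seed.
#' @param weight_fun weighting scheme; default [weights_raw_pvalue()].
#' @return [surrogate_variables] with method `"sva_star"`.
#' @export
sva_star <- function(x, design, k, n_iter = 5, n_perm = 200, seed = 1,
                     weight_fun = weights_raw_pvalue) {
  p_s_fun <- function(x, full, reduced, iter) {
    permutation_pvalues(x, full, reduced, n_perm = n_perm,
                        seed = seed + iter)$p_value
  }
  iterate_sva(x, design, k, n_iter, p_s_fun, weight_fun, "sva_star")
}

#' Surrogate-variable heterogeneity across the primary groups
#'
#' One-way ANOVA p-value of each surrogate variable across the levels of the
#' primary factor. A "heterogeneous" SV (small p) has significantly
#' different group means; using it as a covariate absorbs true group signal.
#' Constant SVs get p = 1 by convention.
#'
#' @param sv [surrogate_variables] or numeric matrix (samples x k).
#' @param pheno phenotype table aligned with the SV rows.
#' @return numeric vector of per-SV p-values.
#' @export
sv_heterogeneity <- function(sv, pheno) {
  validate_phenotype(pheno)
  g <- if (inherits(sv, "surrogate_variables")) sv$sv else as.matrix(sv)
  if (nrow(g) != nrow(pheno)) stop("SV rows must match phenotype rows")
  f <- factor(pheno$primary)
  if (nlevels(f) < 2L) stop("primary factor has a single level")
  apply(g, 2L, function(col) {
    if (stats::sd(col) < 1e-12) return(1)
    stats::oneway.test(col ~ f, var.equal = TRUE)$p.value
  })
}
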