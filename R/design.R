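#' Validate a phenotype table
#'
#' A phenotype table is a data.frame with a `sample_id` column, a `primary`
#' column (the factor of interest, e.g. disease status) and zero or more
#' additional columns treated as known covariates. The primary factor must
#' have at least two levels, each represented by at least two samples.
#'
#' @param pheno data.frame with columns `sample_id`, `primary`, covariates.
#' @param sample_ids optional character vector (e.g. colnames of an
#'   expression matrix) the table must match as a set.
#' @return `pheno`, invisibly; errors if invalid.
#' @export
validate_phenotype <- function(pheno, sample_ids = NULL) {
  if (!is.data.frame(pheno) || !all(c("sample_id", "primary") %in% names(pheno))) {
    stop("phenotype table must be a data.frame with columns sample_id and primary")
  }
  if (anyDuplicated(pheno$sample_id)) {
    stop("duplicate sample ids in phenotype table")
  }
  tab <- table(as.character(pheno$primary))
  if (length(tab) < 2L || any(tab < 2L)) {
    stop("primary factor needs >= 2 levels with >= 2 samples each")
  }
  if (!is.null(sample_ids)) {
    missing_x <- setdiff(sample_ids, pheno$sample_id)
    missing_p <- setdiff(pheno$sample_id, sample_ids)
    if (length(missing_x) || length(missing_p)) {
      stop("sample id mismatch; missing from phenotype: ",
           paste(missing_x, collapse = ", "),
           "; missing from expression: ", paste(missing_p, collapse = ", "))
    }
  }
  invisible(pheno)
}

covariate_names <- function(pheno) {
  setdiff(names(pheno), c("sample_id", "primary"))
}

# Treatment-contrast indicator columns for a categorical vector, reference =
# first level in sorted label order (deterministic across platforms).
contrast_columns <- function(x, name) {
  lev <- sort(unique(as.character(x)))
  out <- sapply(lev[-1], function(l) as.numeric(as.character(x) == l))
  out <- matrix(out, nrow = length(x),
                dimnames = list(NULL, paste0(name, lev[-1])))
  out
}

#' Build a design matrix from a phenotype table
#'
#' Columns are: intercept; covariate columns (categorical covariates coded as
#' treatment contrasts with the first sorted label as reference, numeric
#' covariates as given); primary-effect indicator columns (if
#' `include_primary`); surrogate-variable columns `sv1..svk` (if `sv` given).
#' The partition is recorded in the `"col_roles"` attribute. A rank-deficient
#' result is an error naming the collinear columns.
#'
#' @param pheno phenotype table (see [validate_phenotype()]); row order
#'   defines the sample order of the design.
#' @param include_primary include indicator columns for the primary factor?
#' @param sv optional surrogate variables: a [surrogate_variables] object or
#'   a numeric matrix (samples x k, rows in `pheno` sample order).
#' @return numeric design matrix (n_samples x p) with attribute `col_roles`
#'   (named character vector: intercept/covariate/primary/surrogate).
#' @export
build_design <- function(pheno, include_primary = TRUE, sv = NULL) {
  validate_phenotype(pheno)
  n <- nrow(pheno)
  mat <- matrix(1, n, 1, dimnames = list(pheno$sample_id, "(Intercept)"))
  roles <- c("(Intercept)" = "intercept")
  for (cn in covariate_names(pheno)) {
    v <- pheno[[cn]]
    if (is.numeric(v)) {
      block <- matrix(as.numeric(v), ncol = 1, dimnames = list(NULL, cn))
    } else {
      block <- contrast_columns(v, cn)
    }
    mat <- cbind(mat, block)
    roles <- c(roles, stats::setNames(rep("covariate", ncol(block)), colnames(block)))
  }
  if (include_primary) {
    block <- contrast_columns(pheno$primary, "primary")
    mat <- cbind(mat, block)
    roles <- c(roles, stats::setNames(rep("primary", ncol(block)), colnames(block)))
  }
  if (!is.null(sv)) {
    g <- if (inherits(sv, "surrogate_variables")) sv$sv else as.matrix(sv)
    if (nrow(g) != n) stop("surrogate variable rows must match phenotype rows")
    if (ncol(g) > 0L) {
      colnames(g) <- paste0("sv", seq_len(ncol(g)))
      mat <- cbind(mat, g)
      roles <- c(roles, stats::setNames(rep("surrogate", ncol(g)), colnames(g)))
    }
  }
  qr_d <- qr(mat)
  if (qr_d$rank < ncol(mat)) {
    bad <- colnames(mat)[qr_d$pivot[-seq_len(qr_d$rank)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  attr(mat, "col_roles") <- roles
  mat
}

#' Fit per-gene ordinary least squares
#'
#' Fits `X = B S' + E` where `X` is genes x samples and `S` is the
#' samples x p design matrix: each gene's expression profile is regressed on
#' the design. Residual rows are orthogonal to the design column space.
#'
#' @param x expression matrix (genes x samples).
#' @param design design matrix from [build_design()] (samples x p).
#' @return list with `coefficients` (genes x p), `residuals`
#'   (genes x samples), `df_residual`, `rss` (per-gene residual sum of
#'   squares) and `design`.
#' @export
fit_linear <- function(x, design) {
  validate_expression_matrix(x)
  design <- as.matrix(design)
  n <- ncol(x)
  p <- ncol(design)
  if (nrow(design) != n) stop("design rows must match expression columns")
  if (n <= p) stop("saturated design: n_samples must exceed n_columns")
  qr_d <- qr(design)
  coef <- t(qr.coef(qr_d, t(x)))
  resid <- t(qr.resid(qr_d, t(x)))
  list(coefficients = coef,
       residuals = resid,
       df_residual = n - p,
       rss = rowSums(resid * resid),
       design = design)
}

check_nested <- function(full, reduced) {
  if (!all(colnames(reduced) %in% colnames(full))) {
    stop("designs are not nested: reduced columns must be a subset of full")
  }
  shared <- reduced[, colnames(reduced), drop = FALSE]
  if (!isTRUE(all.equal(unname(shared),
                        unname(full[, colnames(reduced), drop = FALSE]),
                        tolerance = 1e-10))) {
    stop("designs are not nested: shared columns differ in value")
  }
  if (ncol(full) <= ncol(reduced)) stop("full design adds no columns")
  invisible(setdiff(colnames(full), colnames(reduced)))
}

new_gene_pvalues <- function(gene_ids, statistic, p_value, method) {
  out <- data.frame(gene_id = gene_ids, statistic = statistic,
                    p_value = p_value, stringsAsFactors = FALSE)
  attr(out, "method") <- method
  class(out) <- c("gene_pvalues", "data.frame")
  out
}

#' Per-gene nested F-test
#'
#' For each gene, compares the full model against the reduced (nested) model
#' with the usual F statistic
#' `F = ((RSS0 - RSS1)/(df1 - df0)) / (RSS1/(n - df1))` and an upper-tail
#' parametric p-value. Genes with (numerically) zero residual variance under
#' the reduced model get p = 1 by convention.
#'
#' @param x expression matrix.
#' @param full,reduced nested design matrices (reduced columns a strict
#'   subset of full columns).
#' @return data.frame (`gene_pvalues`): gene_id, statistic, p_value; method
#'   attribute `"parametric-F"`.
#' @export
f_test <- function(x, full, reduced) {
  check_nested(full, reduced)
  fit1 <- fit_linear(x, full)
  fit0 <- fit_linear(x, reduced)
  df_num <- ncol(full) - ncol(reduced)
  fstat <- ((fit0$rss - fit1$rss) / df_num) / (fit1$rss / fit1$df_residual)
  p <- stats::pf(fstat, df_num, fit1$df_residual, lower.tail = FALSE)
  degenerate <- fit0$rss < 1e-12 * ncol(x)
  fstat[degenerate] <- 0
  p[degenerate] <- 1
  new_gene_pvalues(rownames(x), fstat, p, "parametric-F")
}

# Run code with a locally set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# F statistics for adding column block Z (samples x q) to a reduced design
# whose thin-Q factor is q_red; r_x is X residualised on the reduced design,
# rss_red its per-gene RSS. Returns per-gene F.
f_stat_added <- function(r_x, rss_red, q_red, z, df2) {
  z_t <- z - q_red %*% crossprod(q_red, z)
  qz <- qr(z_t)
  rk <- qz$rank
  if (rk == 0L) return(rep(0, nrow(r_x)))
  qzq <- qr.Q(qz)[, seq_len(rk), drop = FALSE]
  proj <- r_x %*% qzq
  num <- rowSums(proj * proj)
  rss_full <- pmax(rss_red - num, 0)
  (num / rk) / (rss_full / df2)
}

#' Per-gene permutation p-values for the added effect
#'
#' Same nested comparison as [f_test()], but the p-value is obtained by
#' permuting the rows of the tested columns (full minus reduced) jointly
#' while the reduced-model columns stay fixed — a covariate-preserving null.
#' The add-one (Phipson–Smyth) correction keeps p strictly positive:
#' `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)`. Genes with zero residual
#' variance under the reduced model get p = 1.
#'
#' @param x expression matrix.
#' @param full,reduced nested design matrices.
#' @param n_perm number of permutations (>= 50).
#' @param seed RNG seed; identical seed gives identical output.
#' @return `gene_pvalues` data.frame with method `"permutation"`; the
#'   statistic column holds the observed F.
#' @export
permutation_pvalues <- function(x, full, reduced, n_perm = 200, seed = 1) {
  if (n_perm < 50) stop("insufficient permutations: n_perm must be >= 50")
  tested <- check_nested(full, reduced)
  validate_expression_matrix(x)
  n <- ncol(x)
  qr_red <- qr(reduced)
  q_red <- qr.Q(qr_red)[, seq_len(qr_red$rank), drop = FALSE]
  r_x <- x - tcrossprod(x %*% q_red, q_red)
  rss_red <- rowSums(r_x * r_x)
  z <- full[, tested, drop = FALSE]
  df2 <- n - ncol(full)
  if (df2 <= 0) stop("saturated design: n_samples must exceed n_columns")
  f_obs <- f_stat_added(r_x, rss_red, q_red, z, df2)
  q <- ncol(z)
  count <- with_seed(seed, {
    if (q == 1L) {
      # batch all permutations in one multiply
      zp <- vapply(seq_len(n_perm), function(b) z[sample.int(n), 1L],
                   numeric(n))
      zp_t <- zp - q_red %*% crossprod(q_red, zp)
      nrm2 <- colSums(zp_t * zp_t)
      proj <- r_x %*% zp_t
      num <- sweep(proj * proj, 2L, pmax(nrm2, 1e-300), "/")
      fperm <- num / ((rss_red - num) / df2)
      fperm[, nrm2 < 1e-12] <- 0
      rowSums(fperm >= f_obs - 1e-12)
    } else {
      cnt <- numeric(nrow(x))
      for (b in seq_len(n_perm)) {
        zb <- z[sample.int(n), , drop = FALSE]
        fb <- f_stat_added(r_x, rss_red, q_red, zb, df2)
        cnt <- cnt + (fb >= f_obs - 1e-12)
      }
      cnt
    }
  })
  p <- (1 + count) / (1 + n_perm)
  degenerate <- rss_red < 1e-12 * n
  f_obs[degenerate] <- 0
  p[degenerate] <- 1
  new_gene_pvalues(rownames(x), f_obs, p, "permutation")
}
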