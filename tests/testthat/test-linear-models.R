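test_that("build_design produces the documented column layout", {
  ph <- two_group_pheno(3, 3)
  d <- build_design(ph)
  expect_equal(ncol(d), 2)
  expect_equal(unname(attr(d, "col_roles")), c("intercept", "primary"))

  ph4 <- data.frame(sample_id = sprintf("s%02d", 1:16),
                    primary = rep(c("w", "x", "y", "z"), each = 4),
                    gender = rep(c("F", "M"), 8))
  sv <- matrix(rnorm(48), 16, 3)
  d4 <- build_design(ph4, sv = sv)
  expect_equal(ncol(d4), 1 + 1 + 3 + 3)
  expect_equal(sum(attr(d4, "col_roles") == "surrogate"), 3)

  d0 <- build_design(ph, include_primary = FALSE)
  expect_equal(colnames(d0), "(Intercept)")
})

test_that("build_design rejects collinear columns by name", {
  ph <- two_group_pheno(3, 3)
  ph$copy <- ph$primary
  expect_error(build_design(ph), "rank deficient")
})

test_that("fit_linear matches the per-gene normal-equation oracle", {
  x <- tiny_expr(50, 20, seed = 7)
  ph <- two_group_pheno(10, 10)
  ph$age <- rnorm(20)
  s <- build_design(ph)
  fit <- fit_linear(x, s)
  # brute force: solve each gene's normal equations independently
  for (i in c(1, 17, 50)) {
    beta <- solve(crossprod(s), crossprod(s, x[i, ]))
    expect_equal(unname(fit$coefficients[i, ]), as.vector(beta),
                 tolerance = 1e-8)
  }
  # residual orthogonality to the design space
  expect_lt(max(abs(fit$residuals %*% s)), 1e-8)
  # exact fit when x lies in the design space
  b <- matrix(rnorm(50 * 2), 50, 2)
  x0 <- expression_matrix(b %*% t(s[, 1:2]), rownames(x), colnames(x))
  expect_lt(max(abs(fit_linear(x0, s[, 1:2])$residuals)), 1e-8)
  # intercept-only design centres each row
  ph0 <- two_group_pheno(10, 10)
  fi <- fit_linear(x, build_design(ph0, include_primary = FALSE))
  expect_equal(fi$residuals, x - rowMeans(x), ignore_attr = TRUE)
  expect_error(fit_linear(x[, 1:2], s[1:2, ]), "saturated")
})

test_that("two-group F equals the squared pooled t statistic", {
  x <- tiny_expr(40, 14, seed = 2)
  ph <- two_group_pheno(7, 7)
  res <- f_test(x, build_design(ph), build_design(ph, include_primary = FALSE))
  tsq <- apply(x, 1, function(row) {
    t.test(row[1:7], row[8:14], var.equal = TRUE)$statistic^2
  })
  expect_equal(res$statistic, unname(tsq), tolerance = 1e-10)
})

test_that("F-test p-values are uniform under the null and tiny under saturation", {
  x <- tiny_expr(2000, 20, seed = 5)
  ph <- two_group_pheno(10, 10)
  res <- f_test(x, build_design(ph), build_design(ph, include_primary = FALSE))
  expect_gt(ks.test(res$p_value, "punif")$p.value, 0.01)
  # RSS nesting holds for every gene
  full <- fit_linear(x, build_design(ph))
  red <- fit_linear(x, build_design(ph, include_primary = FALSE))
  expect_true(all(full$rss <= red$rss + 1e-10))
  # gene equal to the group indicator plus tiny noise
  set.seed(1)
  xs <- expression_matrix(rbind(g1 = rep(c(0, 1), each = 10) + rnorm(20, sd = 1e-4)),
                          sample_ids = ph$sample_id)
  expect_lt(f_test(xs, build_design(ph),
                   build_design(ph, include_primary = FALSE))$p_value, 1e-10)
})

test_that("f_test agrees with an independent reference implementation", {
  x <- tiny_expr(100, 16, seed = 9)
  ph <- two_group_pheno(8, 8)
  ph$age <- rnorm(16)
  full <- build_design(ph)
  red <- build_design(ph, include_primary = FALSE)
  ours <- f_test(x, full, red)
  ref <- sva::f.pvalue(x, full, red)
  expect_equal(ours$p_value, unname(ref), tolerance = 1e-8)
})

test_that("f_test requires nested designs and handles flat genes", {
  x <- tiny_expr(10, 12, seed = 1)
  ph <- two_group_pheno(6, 6)
  d1 <- build_design(ph)
  d2 <- build_design(ph, include_primary = FALSE)
  colnames(d2) <- "other"
  expect_error(f_test(x, d1, d2), "not nested")
  flat <- expression_matrix(matrix(5, 3, 12),
                            gene_ids = c("f1", "f2", "f3"),
                            sample_ids = ph$sample_id)
  res <- f_test(flat, build_design(ph), build_design(ph, include_primary = FALSE))
  expect_equal(res$p_value, rep(1, 3))
})

test_that("permutation p-values match exhaustive enumeration on 6 samples", {
  set.seed(13)
  x <- tiny_expr(12, 6, seed = 13)
  ph <- two_group_pheno(3, 3)
  full <- build_design(ph)
  red <- build_design(ph, include_primary = FALSE)
  perm <- permutation_pvalues(x, full, red, n_perm = 4000, seed = 77)
  # oracle: enumerate all 20 distinct assignments of 3 labels to 6 samples
  assigns <- utils::combn(6, 3)
  f_for <- function(idx) {
    z <- as.numeric(seq_len(6) %in% idx)
    f_test(x, build_design(transform(ph, primary = c("b", "a")[z + 1])),
           red)$statistic
  }
  f_all <- apply(assigns, 2, f_for)          # genes x 20
  f_obs <- f_test(x, full, red)$statistic
  p_exact <- rowMeans(f_all >= f_obs - 1e-12)
  expect_equal(perm$p_value, p_exact, tolerance = 0.05)
})

test_that("permutation p-values respect conventions and determinism", {
  x <- tiny_expr(30, 12, seed = 4)
  ph <- two_group_pheno(6, 6)
  full <- build_design(ph)
  red <- build_design(ph, include_primary = FALSE)
  expect_error(permutation_pvalues(x, full, red, n_perm = 20),
               "insufficient permutations")
  a <- permutation_pvalues(x, full, red, n_perm = 99, seed = 3)
  b <- permutation_pvalues(x, full, red, n_perm = 99, seed = 3)
  expect_identical(a, b)
  expect_true(all(a$p_value >= 1 / 100))
  # constant gene gets p = 1
  xc <- expression_matrix(rbind(const = rep(2, 12), x),
                          sample_ids = ph$sample_id)
  expect_equal(permutation_pvalues(xc, full, red, n_perm = 60,
                                   seed = 1)$p_value[1], 1)
  # minimum attainable p with n_perm = 199 is 1/200
  set.seed(2)
  xs <- expression_matrix(rbind(sig = rep(c(0, 5), each = 6) + rnorm(12, sd = 0.1)),
                          sample_ids = ph$sample_id)
  ps <- permutation_pvalues(xs, full, red, n_perm = 199, seed = 5)$p_value
  expect_equal(ps, 1 / 200)
})

test_that("parametric and permutation tests rank genes near-identically", {
  set.seed(21)
  x <- tiny_expr(300, 20, seed = 21)
  ph <- two_group_pheno(10, 10)
  shift <- rnorm(300, sd = 0.8)
  x[, 11:20] <- x[, 11:20] + shift
  full <- build_design(ph)
  red <- build_design(ph, include_primary = FALSE)
  pf <- f_test(x, full, red)$p_value
  pp <- permutation_pvalues(x, full, red, n_perm = 1000, seed = 8)$p_value
  expect_gt(cor(rank(pf), rank(pp), method = "spearman"), 0.95)
})
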