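test_that("estimate_k finds no structure in pure noise", {
  hits <- 0
  for (i in 1:10) {
    x <- tiny_expr(800, 30, seed = 600 + i)
    ph <- two_group_pheno(15, 15)
    hits <- hits + (estimate_k(x, build_design(ph), seed = i) == 0L)
  }
  expect_gte(hits, 9)
})

test_that("estimate_k recovers planted factor counts", {
  ph <- two_group_pheno(15, 15)
  d <- build_design(ph)
  for (kt in 1:2) {
    ks <- vapply(1:6, function(i) {
      estimate_k(planted_factor_matrix(500, 30, kt, seed = 7000 + kt * 100 + i),
                 d, seed = i)
    }, integer(1))
    expect_true(all(ks == kt))
  }
  # a single gene carries no correlation structure
  x1 <- tiny_expr(1, 30, seed = 1)
  expect_identical(estimate_k(x1, d, seed = 1), 0L)
})

test_that("residual SVD surrogate variables recover planted structure orthogonally", {
  ph <- two_group_pheno(10, 10)
  d <- build_design(ph)
  # rank-1 residual: single SV proportional to the planted vector
  set.seed(31)
  v <- rnorm(20)
  v <- residuals(lm(v ~ d - 1))          # put the factor in the residual space
  g <- rnorm(100)
  x <- expression_matrix(g %o% v, sprintf("g%03d", 1:100), ph$sample_id)
  sv <- residual_svd_sv(x, d, 1)
  expect_equal(abs(cor(sv$sv[, 1], v)), 1, tolerance = 1e-8)
  expect_lt(max(abs(crossprod(sv$sv, d))), 1e-8)
  # unit-norm, sign-fixed columns
  expect_equal(sum(sv$sv[, 1]^2), 1, tolerance = 1e-8)
  expect_gt(sv$sv[which.max(abs(sv$sv[, 1])), 1], 0)
  # balanced latent variable in a full simulation
  sim <- simulate_additive_dataset(simulation_config(seed = 11))
  dd <- build_design(sim$pheno)
  sv2 <- residual_svd_sv(sim$x, dd, 1)
  expect_gt(abs(cor(sv2$sv[, 1], sim$true_latent)), 0.9)
  expect_lt(max(abs(crossprod(sv2$sv, dd))), 1e-8)
  expect_error(residual_svd_sv(sim$x, dd, 50), "exceeds")
})

test_that("uniform weights reduce the iteration to the plain SVD", {
  sim <- simulate_mixture_dataset(small_config(seed = 3))
  d <- build_design(sim$pheno)
  unif <- function(p_s, p_g) rep(1, length(p_s))
  got <- sva_leek_storey(sim$x, d, k = 2, n_iter = 1, weight_fun = unif)
  xc <- sim$x - rowMeans(sim$x)
  want <- svd(xc, nu = 0, nv = 2)$v
  # compare up to the package sign convention
  for (j in 1:2) {
    expect_equal(abs(cor(got$sv[, j], want[, j])), 1, tolerance = 1e-6)
  }
})

test_that("Leek-Storey SVA absorbs the group effect on mixture data", {
  het <- vapply(1:4, function(i) {
    sim <- simulate_mixture_dataset(simulation_config(seed = 300 + i))
    d <- build_design(sim$pheno)
    k <- max(estimate_k(sim$x, d, seed = i), 1)
    min(sv_heterogeneity(sva_leek_storey(sim$x, d, k), sim$pheno))
  }, numeric(1))
  expect_gte(sum(het < 0.01), 3)
})

test_that("Leek-Storey iteration spans the same space as the reference implementation", {
  sim <- simulate_mixture_dataset(simulation_config(seed = 301))
  d <- build_design(sim$pheno)
  k <- 3
  mine <- sva_leek_storey(sim$x, d, k)
  mod <- cbind(1, as.numeric(sim$pheno$primary == "disease"))
  ref <- NULL
  invisible(utils::capture.output(
    ref <- sva::irwsva.build(sim$x, mod, cbind(mod[, 1]), n.sv = k, B = 5)))
  expect_true(all(cancor(mine$sv, ref$sv)$cor > 0.95))
})

test_that("SVA* weights have the documented endpoint behaviour", {
  expect_equal(weights_raw_pvalue(1, 0), 1)
  expect_equal(weights_raw_pvalue(0, 0.2), 0)
  expect_equal(weights_raw_pvalue(0.5, 1), 0)
  p_s <- c(1, 1e-8, 0.5)
  p_g <- c(1e-8, 1e-8, 0.5)
  w <- weights_raw_pvalue(p_s, p_g)
  expect_gt(w[1], 0.99)
  expect_lt(w[2], 1e-7)
})

test_that("SVA* avoids heterogeneous surrogate variables on mixture data", {
  n_het <- 0
  n_cols <- 0
  for (i in 1:4) {
    sim <- simulate_mixture_dataset(simulation_config(seed = 300 + i))
    d <- build_design(sim$pheno)
    k <- max(estimate_k(sim$x, d, seed = i), 1)
    het <- sv_heterogeneity(sva_star(sim$x, d, k, seed = i), sim$pheno)
    n_het <- n_het + sum(het < 0.01)
    n_cols <- n_cols + length(het)
  }
  expect_lt(n_het / n_cols, 0.15)
})

test_that("both iterative methods recover a balanced additive latent variable", {
  sim <- simulate_additive_dataset(simulation_config(seed = 12))
  d <- build_design(sim$pheno)
  k <- max(estimate_k(sim$x, d, seed = 12), 1)
  for (sv in list(sva_leek_storey(sim$x, d, k),
                  sva_star(sim$x, d, k, seed = 12))) {
    expect_gt(max(abs(cor(sv$sv, sim$true_latent))), 0.8)
  }
})

test_that("SVA* is deterministic given the seed", {
  sim <- simulate_mixture_dataset(small_config(seed = 9))
  d <- build_design(sim$pheno)
  a <- sva_star(sim$x, d, 2, seed = 4)
  b <- sva_star(sim$x, d, 2, seed = 4)
  expect_identical(a, b)
})

test_that("sv_heterogeneity follows the ANOVA conventions", {
  ph <- two_group_pheno(10, 10)
  ind <- as.numeric(ph$primary == "b")
  expect_lt(sv_heterogeneity(cbind(ind), ph), 1e-10)
  expect_equal(sv_heterogeneity(cbind(rep(1, 20)), ph), 1)
  # group-independent SVs give uniform p-values
  set.seed(17)
  ps <- vapply(1:500, function(i) {
    sv_heterogeneity(cbind(rnorm(20)), ph)
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  ph1 <- ph
  ph1$primary <- "a"
  expect_error(sv_heterogeneity(cbind(ind), ph1), "2 levels")
})

test_that("degenerate p-value histograms fall back to uniform weights with a warning", {
  p_bad <- rep(0.5, 100)
  expect_error(estimate_lfdr(p_bad), "degenerate")
  sim <- simulate_mixture_dataset(small_config(seed = 5))
  d <- build_design(sim$pheno)
  bad_weights <- function(p_s, p_g) stop("synthetic failure")
  expect_warning(sva_leek_storey(sim$x, d, 1, n_iter = 1,
                                 weight_fun = bad_weights),
                 "uniform weights")
})
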