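test_that("all effects off yields constant genes", {
  cfg <- simulation_config(delta = 0, sigma_gamma = 0, sigma_eps = 0,
                           profile_celltype_sd = 0, n_genes = 100L,
                           class_sizes = c(noise = 25L, group = 25L,
                                           latent = 25L, both = 25L),
                           n_per_group = c(5L, 5L), seed = 2)
  sim <- simulate_mixture_dataset(cfg)
  expect_lt(max(apply(sim$x, 1, sd)), 1e-10)
})

test_that("mixing follows the linear-space oracle exactly", {
  cfg <- small_config(seed = 4, n = 5L, n_genes = 40L,
                      sigma_gamma = 0, sigma_eps = 0)
  sim <- simulate_mixture_dataset(cfg)
  e <- sim$pure_profiles
  es <- sim$disease_profile
  p <- sim$proportions
  is_dis <- sim$pheno$primary == "disease"
  for (k in c(1, 6)) {   # one control, one disease sample
    prof <- if (is_dis[k]) es else e
    manual <- vapply(seq_len(nrow(e)), function(i) {
      sum(p[, k] * prof[i, ])   # direct summation over cell types
    }, numeric(1))
    expect_equal(unname(sim$x[, k]), log2(manual), tolerance = 1e-12)
  }
  # disease profile differs from control only in cell type 1 of affected genes
  aff <- sim$gene_class %in% c("group", "both")
  expect_true(all(es[!aff, ] == e[!aff, ]))
  expect_true(all(es[aff, -1] == e[aff, -1]))
  expect_true(all(es[aff, 1] >= e[aff, 1]))
})

test_that("proportions are simplex-valid and intermediates positive", {
  sim <- simulate_mixture_dataset(small_config(seed = 6))
  expect_equal(unname(colSums(sim$proportions)), rep(1, 20),
               tolerance = 1e-12)
  expect_true(all(sim$proportions >= 0))
  expect_true(all(sim$pure_profiles > 0))
  expect_true(all(sim$disease_profile > 0))
})

test_that("disease-specific correlation appears among group-affected genes", {
  wins <- 0
  for (i in 1:10) {
    sim <- simulate_mixture_dataset(simulation_config(seed = 200 + i))
    both <- names(sim$gene_class)[sim$gene_class == "both"]
    set.seed(i)
    gs <- sample(both, 12)
    gc <- group_specific_correlation(sim$x, sim$pheno, gs[1:6], gs[7:12])
    wins <- wins + (mean(abs(gc$r[gc$group == "disease"])) >
                    mean(abs(gc$r[gc$group == "control"])))
  }
  expect_gte(wins, 8)
})

test_that("near-equal proportions switch the group-specific correlation off", {
  diffs <- vapply(1:5, function(i) {
    sim <- simulate_mixture_dataset(
      simulation_config(seed = 500 + i, dirichlet_alpha = rep(2000, 3)))
    both <- names(sim$gene_class)[sim$gene_class == "both"]
    set.seed(i)
    gs <- sample(both, 12)
    gc <- group_specific_correlation(sim$x, sim$pheno, gs[1:6], gs[7:12])
    mean(abs(gc$r[gc$group == "disease"])) -
      mean(abs(gc$r[gc$group == "control"]))
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.05)
})

test_that("group_specific_correlation handles identical and independent pairs", {
  sim <- simulate_mixture_dataset(small_config(seed = 8))
  g <- rownames(sim$x)[1]
  same <- group_specific_correlation(sim$x, sim$pheno, g, g)
  expect_equal(same$r, rep(1, 2), tolerance = 1e-12)
  # independent noise genes: per-group mean r near 0
  x <- tiny_expr(60, 20, seed = 44)
  ph <- two_group_pheno(10, 10)
  gc <- group_specific_correlation(x, ph, rownames(x)[1:30], rownames(x)[31:60])
  for (g2 in c("a", "b")) {
    expect_lt(abs(mean(gc$r[gc$group == g2])), 0.05)
  }
  # tiny groups report r but suppress significance
  ph2 <- two_group_pheno(3, 17)
  gc2 <- group_specific_correlation(x, ph2, rownames(x)[1], rownames(x)[2])
  expect_true(is.na(gc2$p[gc2$group == "a"]))
  expect_false(is.na(gc2$r[gc2$group == "a"]))
})

test_that("a plain test ranks true group genes above noise before any correction", {
  sim <- simulate_mixture_dataset(simulation_config(seed = 42))
  ranked <- rank_differential_expression(sim$x, sim$pheno, method = "none")
  pos <- names(sim$gene_class)[sim$gene_class %in% c("group", "both")]
  neg <- names(sim$gene_class)[sim$gene_class == "noise"]
  expect_gt(auc_gene_discrimination(ranked, pos, neg), 0.6)
})

test_that("compendium studies share biology but not nuisance", {
  comp <- simulate_compendium(3, small_config(seed = 10))
  expect_named(comp, c("study1", "study2", "study3"))
  expect_identical(comp$study1$pure_profiles, comp$study2$pure_profiles)
  expect_identical(comp$study1$disease_profile, comp$study3$disease_profile)
  expect_identical(comp$study1$gene_class, comp$study2$gene_class)
  expect_false(identical(comp$study1$proportions, comp$study2$proportions))
  expect_false(identical(comp$study1$true_latent, comp$study2$true_latent))
})

test_that("simulation configuration is validated", {
  expect_error(simulation_config(n_genes = 999L), "sum to n_genes")
  expect_error(simulation_config(dirichlet_alpha = c(1, 1)), "n_cell_types")
  expect_error(simulation_config(sigma_eps = -1), "scales")
  # identical seeds reproduce identical datasets
  a <- simulate_mixture_dataset(small_config(seed = 3))
  b <- simulate_mixture_dataset(small_config(seed = 3))
  expect_identical(a$x, b$x)
})

test_that("additive simulator plants a balanced latent variable and group shifts", {
  sim <- simulate_additive_dataset(simulation_config(seed = 21))
  aff <- sim$gene_class %in% c("group", "both")
  dis <- sim$pheno$primary == "disease"
  shift <- rowMeans(sim$x[aff, dis]) - rowMeans(sim$x[aff, !dis])
  expect_gt(mean(shift), 0.5)
  unaff <- rowMeans(sim$x[!aff, dis]) - rowMeans(sim$x[!aff, !dis])
  expect_lt(abs(mean(unaff)), 0.2)
  # latent vector independent of group labels by construction
  expect_null(sim$proportions)
})
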