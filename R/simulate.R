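#' Configuration for the cell-type-mixture simulator
#'
#' Defaults reproduce the benchmark conditions: 1000 genes in four classes of
#' 250 (pure noise; group effect; latent effect; both), two groups of 20
#' samples, three cell types mixed in sample-specific Dirichlet
#' proportions, a log2 fold change of `delta` confined to cell type 1, an
#' independent uniform latent variable with normal gene loadings, and
#' additive Gaussian noise on the log scale.
#'
#' @param n_genes total genes; must equal the sum of `class_sizes`.
#' @param class_sizes named integer vector with entries `noise`, `group`,
#'   `latent`, `both`.
#' @param n_per_group samples in (control, disease).
#' @param n_cell_types number of pure cell-type profiles mixed per sample.
#' @param dirichlet_alpha Dirichlet concentration for the mixing
#'   proportions (length `n_cell_types`). Large values give near-equal
#'   proportions and switch the mixture-induced correlation off.
#' @param delta mean disease log2 fold change applied to cell type 1 of the
#'   group-affected genes. Per-gene folds are drawn Exponential with mean
#'   `delta`, giving the heavy-tailed effect-size spectrum of real disease
#'   signatures (a few strong markers, many weak ones); `delta = 0` turns
#'   the group effect off.
#' @param sigma_gamma sd of the normal per-gene latent loadings.
#' @param sigma_eps sd of the additive log-scale noise.
#' @param profile_log2_mean,profile_log2_sd log2-normal parameters of the
#'   gene-level baseline shared by all cell types (linear-scale
#'   intensities).
#' @param profile_celltype_sd log2 sd of the cell-type-specific deviation
#'   around each gene's baseline. Most genes are expressed at comparable
#'   levels in all cell types (so their control-group measurements barely
#'   depend on the mixing proportions, which sum to 1), while the deviations
#'   still impose the global mixture correlation seen in real mixed-tissue
#'   data.
#' @param seed RNG seed.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 1000L,
                              class_sizes = c(noise = 250L, group = 250L,
                                              latent = 250L, both = 250L),
                              n_per_group = c(20L, 20L),
                              n_cell_types = 3L,
                              dirichlet_alpha = c(0.5, 0.5, 0.5),
                              delta = 1.0,
                              sigma_gamma = 0.9,
                              sigma_eps = 0.35,
                              profile_log2_mean = 7,
                              profile_log2_sd = 1,
                              profile_celltype_sd = 0.5,
                              seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              class_sizes = class_sizes,
              n_per_group = as.integer(n_per_group),
              n_cell_types = as.integer(n_cell_types),
              dirichlet_alpha = dirichlet_alpha,
              delta = delta,
              sigma_gamma = sigma_gamma,
              sigma_eps = sigma_eps,
              profile_log2_mean = profile_log2_mean,
              profile_log2_sd = profile_log2_sd,
              profile_celltype_sd = profile_celltype_sd,
              seed = as.integer(seed))
  if (!all(c("noise", "group", "latent", "both") %in% names(cfg$class_sizes))) {
    stop("class_sizes needs entries noise, group, latent, both")
  }
  if (sum(cfg$class_sizes) != cfg$n_genes) {
    stop("class sizes must sum to n_genes")
  }
  if (length(cfg$dirichlet_alpha) != cfg$n_cell_types) {
    stop("dirichlet_alpha length must equal n_cell_types")
  }
  if (cfg$sigma_eps < 0 || cfg$sigma_gamma < 0) stop("scales must be >= 0")
  class(cfg) <- "simulation_config"
  cfg
}

sim_gene_classes <- function(cfg) {
  # fixed block order so datasets simulated from different seeds share the
  # same true gene sets (required when building multi-study compendia)
  rep(c("noise", "group", "latent", "both"),
      times = cfg$class_sizes[c("noise", "group", "latent", "both")])
}

# Per-gene log2 disease folds: exponential with mean delta (heavy-tailed
# effect spectrum); identically zero when delta = 0.
gene_effects <- function(n, delta) {
  if (delta == 0) return(numeric(n))
  stats::rexp(n, rate = 1 / delta)
}

rdirichlet_cols <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = length(alpha))
  sweep(g, 2L, colSums(g), "/")
}

new_simulated_dataset <- function(x, pheno, gene_class, true_latent,
                                  proportions, pure_profiles,
                                  disease_profile, config) {
  structure(list(x = x, pheno = pheno, gene_class = gene_class,
                 true_latent = true_latent, proportions = proportions,
                 pure_profiles = pure_profiles,
                 disease_profile = disease_profile, config = config),
            class = "simulated_dataset")
}

#' Simulate a cell-type-mixture expression dataset
#'
#' Construction order (all draws governed by `config$seed`):
#' 1. pure cell-type profiles `e[i, j] = 2^(mu[i] + tau[i, j])` on the
#'    linear scale: a gene-level baseline `mu` shared by all cell types plus
#'    a cell-type-specific deviation `tau`;
#' 2. a disease profile `e*` equal to `e` except that cell-type-1 entries of
#'    the group-affected genes (classes `group` and `both`) are multiplied
#'    by `2^delta`;
#' 3. per-sample mixing proportions from Dirichlet(alpha);
#' 4. linear-space mixing `x[i, k] = sum_j p[j, k] * e[i, j]` with `e*`
#'    replacing `e` for disease samples;
#' 5. log2 transform;
#' 6. latent variable `u ~ Uniform(0, 1)` per sample with loadings
#'    `gamma ~ Normal(0, sigma_gamma)` on `latent`/`both` genes, added as
#'    the outer product `gamma u'`;
#' 7. additive Normal(0, sigma_eps) noise.
#'
#' Because the group effect lives in one cell type while mixing proportions
#' vary between samples, the affected genes co-vary with the cell-type-1
#' proportion — but only in the disease group, reproducing the
#' disease-specific correlation that breaks posterior-weighted SVA.
#'
#' @param config a [simulation_config()].
#' @return object of class `simulated_dataset`: `x` (expression matrix),
#'   `pheno` (phenotype table, primary = control/disease), `gene_class`,
#'   `true_latent`, `proportions` (cell types x samples), `pure_profiles`,
#'   `disease_profile`, `config`.
#' @export
simulate_mixture_dataset <- function(config = simulation_config()) {
  cfg <- config
  n_g <- cfg$n_genes
  n_ct <- cfg$n_cell_types
  n_ctrl <- cfg$n_per_group[1]
  n_dis <- cfg$n_per_group[2]
  n_s <- n_ctrl + n_dis
  gene_class <- sim_gene_classes(cfg)
  gene_ids <- sprintf("g%04d", seq_len(n_g))
  sample_ids <- sprintf("s%03d", seq_len(n_s))
  group <- rep(c("control", "disease"), c(n_ctrl, n_dis))

  out <- with_seed(cfg$seed, {
    mu <- stats::rnorm(n_g, cfg$profile_log2_mean, cfg$profile_log2_sd)
    tau <- matrix(stats::rnorm(n_g * n_ct, 0, cfg$profile_celltype_sd),
                  n_g, n_ct)
    e <- matrix(2^(mu + tau), n_g, n_ct, dimnames = list(gene_ids, NULL))
    e_star <- e
    affected <- gene_class %in% c("group", "both")
    e_star[affected, 1L] <- e[affected, 1L] * 2^gene_effects(sum(affected),
                                                            cfg$delta)
    p <- rdirichlet_cols(n_s, cfg$dirichlet_alpha)
    colnames(p) <- sample_ids
    x_lin <- matrix(0, n_g, n_s, dimnames = list(gene_ids, sample_ids))
    is_dis <- group == "disease"
    x_lin[, !is_dis] <- e %*% p[, !is_dis, drop = FALSE]
    x_lin[, is_dis] <- e_star %*% p[, is_dis, drop = FALSE]
    x <- log2(x_lin)
    u <- stats::runif(n_s)
    gamma <- numeric(n_g)
    lat <- gene_class %in% c("latent", "both")
    gamma[lat] <- stats::rnorm(sum(lat), 0, cfg$sigma_gamma)
    x <- x + gamma %o% u
    if (cfg$sigma_eps > 0) {
      x <- x + matrix(stats::rnorm(n_g * n_s, 0, cfg$sigma_eps), n_g, n_s)
    }
    list(x = x, u = u, p = p, e = e, e_star = e_star)
  })

  pheno <- data.frame(sample_id = sample_ids, primary = group,
                      stringsAsFactors = FALSE)
  new_simulated_dataset(expression_matrix(out$x), pheno,
                        stats::setNames(gene_class, gene_ids),
                        stats::setNames(out$u, sample_ids),
                        out$p, out$e, out$e_star, cfg)
}

#' Simulate a multi-study compendium sharing one disease biology
#'
#' Draws the biology once — gene baselines, cell-type-specific deviations,
#' the disease-altered cell-type-1 profile, and the gene class labels — and
#' then simulates each study with its own mixing proportions, latent
#' variable (fresh loadings and sample vector), and measurement noise. The
#' studies therefore share the same true group-effect genes with consistent
#' effect sizes, while every nuisance source of variation is
#' study-specific: the setting in which latent-variable correction can
#' improve cross-study agreement.
#'
#' @param n_datasets number of studies (>= 2).
#' @param config a [simulation_config()] applied to every study.
#' @param seed RNG seed for the shared biology; study `d` uses derived seed
#'   `seed + d` for its nuisance draws.
#' @return named list (`study1`, `study2`, ...) of `simulated_dataset`
#'   objects.
#' @export
simulate_compendium <- function(n_datasets, config = simulation_config(),
                                seed = config$seed) {
  if (n_datasets < 2L) stop("a compendium needs at least 2 datasets")
  cfg <- config
  n_g <- cfg$n_genes
  n_ct <- cfg$n_cell_types
  gene_class <- sim_gene_classes(cfg)
  gene_ids <- sprintf("g%04d", seq_len(n_g))
  bio <- with_seed(seed, {
    mu <- stats::rnorm(n_g, cfg$profile_log2_mean, cfg$profile_log2_sd)
    tau <- matrix(stats::rnorm(n_g * n_ct, 0, cfg$profile_celltype_sd),
                  n_g, n_ct)
    e <- matrix(2^(mu + tau), n_g, n_ct, dimnames = list(gene_ids, NULL))
    e_star <- e
    affected <- gene_class %in% c("group", "both")
    e_star[affected, 1L] <- e[affected, 1L] * 2^gene_effects(sum(affected),
                                                            cfg$delta)
    list(e = e, e_star = e_star)
  })
  n_ctrl <- cfg$n_per_group[1]
  n_dis <- cfg$n_per_group[2]
  n_s <- n_ctrl + n_dis
  sample_ids <- sprintf("s%03d", seq_len(n_s))
  group <- rep(c("control", "disease"), c(n_ctrl, n_dis))
  is_dis <- group == "disease"
  lat <- gene_class %in% c("latent", "both")
  out <- lapply(seq_len(n_datasets), function(d) {
    nuis <- with_seed(seed + d, {
      p <- rdirichlet_cols(n_s, cfg$dirichlet_alpha)
      colnames(p) <- sample_ids
      x_lin <- matrix(0, n_g, n_s, dimnames = list(gene_ids, sample_ids))
      x_lin[, !is_dis] <- bio$e %*% p[, !is_dis, drop = FALSE]
      x_lin[, is_dis] <- bio$e_star %*% p[, is_dis, drop = FALSE]
      x <- log2(x_lin)
      u <- stats::runif(n_s)
      gamma <- numeric(n_g)
      gamma[lat] <- stats::rnorm(sum(lat), 0, cfg$sigma_gamma)
      x <- x + gamma %o% u
      if (cfg$sigma_eps > 0) {
        x <- x + matrix(stats::rnorm(n_g * n_s, 0, cfg$sigma_eps), n_g, n_s)
      }
      list(x = x, u = u, p = p)
    })
    pheno <- data.frame(sample_id = sample_ids, primary = group,
                        stringsAsFactors = FALSE)
    new_simulated_dataset(expression_matrix(nuis$x), pheno,
                          stats::setNames(gene_class, gene_ids),
                          stats::setNames(nuis$u, sample_ids),
                          nuis$p, bio$e, bio$e_star, cfg)
  })
  names(out) <- paste0("study", seq_len(n_datasets))
  out
}

#' Simulate an additive (non-mixture) dataset
#'
#' The favourable case for surrogate variable analysis: i.i.d. Gaussian
#' baselines, an additive balanced group effect of `delta` log2 units on the
#' `group`/`both` genes, the same uniform latent variable construction as
#' the mixture simulator, and Gaussian noise — no cell-type mixing, so no
#' disease-specific correlation. With `delta = 0` and `sigma_gamma = 0` this
#' yields pure-noise datasets for null calibration.
#'
#' @inheritParams simulate_mixture_dataset
#' @return `simulated_dataset` (with `proportions`, `pure_profiles` and
#'   `disease_profile` set to NULL).
#' @export
simulate_additive_dataset <- function(config = simulation_config()) {
  cfg <- config
  n_g <- cfg$n_genes
  n_ctrl <- cfg$n_per_group[1]
  n_dis <- cfg$n_per_group[2]
  n_s <- n_ctrl + n_dis
  gene_class <- sim_gene_classes(cfg)
  gene_ids <- sprintf("g%04d", seq_len(n_g))
  sample_ids <- sprintf("s%03d", seq_len(n_s))
  group <- rep(c("control", "disease"), c(n_ctrl, n_dis))

  out <- with_seed(cfg$seed, {
    base <- stats::rnorm(n_g, cfg$profile_log2_mean, cfg$profile_log2_sd)
    x <- matrix(base, n_g, n_s, dimnames = list(gene_ids, sample_ids))
    affected <- gene_class %in% c("group", "both")
    x[affected, group == "disease"] <- x[affected, group == "disease"] +
      gene_effects(sum(affected), cfg$delta)
    u <- stats::runif(n_s)
    gamma <- numeric(n_g)
    lat <- gene_class %in% c("latent", "both")
    gamma[lat] <- stats::rnorm(sum(lat), 0, cfg$sigma_gamma)
    x <- x + gamma %o% u
    if (cfg$sigma_eps > 0) {
      x <- x + matrix(stats::rnorm(n_g * n_s, 0, cfg$sigma_eps), n_g, n_s)
    }
    list(x = x, u = u)
  })

  pheno <- data.frame(sample_id = sample_ids, primary = group,
                      stringsAsFactors = FALSE)
  new_simulated_dataset(expression_matrix(out$x), pheno,
                        stats::setNames(gene_class, gene_ids),
                        stats::setNames(out$u, sample_ids),
                        NULL, NULL, NULL, cfg)
}

#' Within-group gene-gene correlation
#'
#' Pearson correlation of each gene pair (one from `genes_a`, one from
#' `genes_b`) computed separately within each level of the primary factor,
#' with a Fisher-z two-sided significance. Groups with fewer than 4 samples
#' report the correlation with significance suppressed (NA).
#'
#' @param x expression matrix.
#' @param pheno phenotype table matching `x` columns.
#' @param genes_a,genes_b character vectors of gene ids present in `x`.
#' @return data.frame: gene_a, gene_b, group, n, r, p.
#' @export
group_specific_correlation <- function(x, pheno, genes_a, genes_b) {
  validate_expression_matrix(x)
  validate_phenotype(pheno, colnames(x))
  if (!all(genes_a %in% rownames(x)) || !all(genes_b %in% rownames(x))) {
    stop("all genes must be present in the expression matrix")
  }
  pheno <- pheno[match(colnames(x), pheno$sample_id), , drop = FALSE]
  groups <- sort(unique(as.character(pheno$primary)))
  pairs <- expand.grid(gene_a = genes_a, gene_b = genes_b,
                       stringsAsFactors = FALSE)
  res <- lapply(groups, function(g) {
    cols <- pheno$primary == g
    n <- sum(cols)
    r <- mapply(function(a, b) {
      if (stats::sd(x[a, cols]) < 1e-12 || stats::sd(x[b, cols]) < 1e-12) {
        return(NA_real_)
      }
      stats::cor(x[a, cols], x[b, cols])
    }, pairs$gene_a, pairs$gene_b)
    p <- if (n >= 4L) {
      z <- atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
      2 * stats::pnorm(-abs(z) * sqrt(n - 3))
    } else {
      rep(NA_real_, length(r))
    }
    data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b, group = g,
               n = n, r = unname(r), p = unname(p),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
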