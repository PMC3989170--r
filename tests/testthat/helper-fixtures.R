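# Small fixtures built in code; all randomness behind explicit seeds.

tiny_expr <- function(n_genes, n_samples, seed = 1, sd = 1, mean = 0) {
  set.seed(seed)
  expression_matrix(matrix(rnorm(n_genes * n_samples, mean, sd),
                           n_genes, n_samples),
                    gene_ids = sprintf("g%04d", seq_len(n_genes)),
                    sample_ids = sprintf("s%03d", seq_len(n_samples)))
}

two_group_pheno <- function(n1, n2, labels = c("a", "b")) {
  data.frame(sample_id = sprintf("s%03d", seq_len(n1 + n2)),
             primary = rep(labels, c(n1, n2)),
             stringsAsFactors = FALSE)
}

# scaled-down simulation for cheap bookkeeping tests
small_config <- function(seed = 1, n = 10L, n_genes = 200L, ...) {
  q <- n_genes %/% 4L
  simulation_config(n_genes = n_genes,
                    class_sizes = c(noise = q, group = q, latent = q,
                                    both = n_genes - 3L * q),
                    n_per_group = c(n, n), seed = seed, ...)
}

# iid-noise matrix with kt planted rank-1 factors (loading sd `strength`)
planted_factor_matrix <- function(n_genes, n_samples, kt, seed,
                                  strength = 2.2) {
  set.seed(seed)
  x <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples)
  for (j in seq_len(kt)) {
    x <- x + (strength * rnorm(n_genes)) %o% rnorm(n_samples)
  }
  expression_matrix(x, sprintf("g%04d", seq_len(n_genes)),
                    sprintf("s%03d", seq_len(n_samples)))
}

# exhaustive hypergeometric upper tail by enumerating every n-subset of the
# universe and counting overlaps with a fixed m-set
hypergeom_enum_oracle <- function(N, m, n, k) {
  sets <- utils::combn(N, n)
  overlaps <- colSums(sets <= m)
  mean(overlaps >= k)
}

# exhaustive one-sided signed-rank p-value by enumerating all sign vectors
signed_rank_enum_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  mean(w_all <= w_obs)  # alternative "less": small positive-rank sum
}

# brute-force AUC by counting all positive/negative pairs
auc_pair_oracle <- function(p_pos, p_neg) {
  wins <- 0
  for (a in p_pos) for (b in p_neg) {
    wins <- wins + (a < b) + 0.5 * (a == b)
  }
  wins / (length(p_pos) * length(p_neg))
}
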