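#' Read an expression matrix from tab-separated text
#'
#' Expected layout: header row of sample ids, first column gene (or probe)
#' ids, numeric cells, log2 scale. Duplicate gene or sample ids and missing
#' or non-numeric cells are rejected.
#'
#' @param path file path.
#' @return expression matrix (genes x samples).
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression TSV needs a gene id column and samples")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate gene ids in ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values in ", path)
  if (anyNA(m)) stop("missing values in expression matrix ", path)
  rownames(m) <- ids
  validate_expression_matrix(m)
  m
}

#' Write an expression matrix as tab-separated text
#'
#' @param x expression matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path) {
  validate_expression_matrix(x)
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table from tab-separated text
#'
#' First column is the sample id, a `primary` column is required, remaining
#' columns are covariates. A sidecar YAML (mapping column name to
#' `"categorical"` or `"numeric"`) may fix covariate types; otherwise
#' character columns are categorical and numeric columns numeric.
#'
#' @param path file path.
#' @param types_yaml optional path to the covariate-type YAML.
#' @return phenotype data.frame (first column renamed `sample_id`).
#' @export
read_phenotype_tsv <- function(path, types_yaml = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1L] <- "sample_id"
  df$sample_id <- as.character(df$sample_id)
  if (!"primary" %in% names(df)) stop("phenotype table needs a 'primary' column")
  df$primary <- as.character(df$primary)
  if (!is.null(types_yaml)) {
    types <- yaml::read_yaml(types_yaml)
    for (cn in names(types)) {
      if (!cn %in% names(df)) next
      df[[cn]] <- switch(match.arg(types[[cn]], c("categorical", "numeric")),
                         categorical = as.character(df[[cn]]),
                         numeric = as.numeric(df[[cn]]))
    }
  }
  validate_phenotype(df)
  df
}

#' Write a phenotype table as tab-separated text
#' @param pheno phenotype data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotype_tsv <- function(pheno, path) {
  validate_phenotype(pheno)
  utils::write.table(pheno, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export surrogate variables with a JSON sidecar
#'
#' Writes a TSV (sample ids in rows, columns `sv1..svk`) and a `.json`
#' sidecar recording method, k, iteration count, seed and per-SV
#' group-heterogeneity p-values.
#'
#' @param sv a [surrogate_variables] object.
#' @param pheno phenotype table giving sample ids (and groups for the
#'   heterogeneity diagnostics).
#' @param path output TSV path; the sidecar is `paste0(path, ".json")`.
#' @param seed seed recorded in the sidecar (NA if unknown).
#' @return `path`, invisibly.
#' @export
write_surrogate_variables <- function(sv, pheno, path, seed = NA) {
  stopifnot(inherits(sv, "surrogate_variables"))
  g <- sv$sv
  colnames(g) <- paste0("sv", seq_len(ncol(g)))
  df <- data.frame(sample_id = pheno$sample_id, g,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(method = sv$method, k = sv$k, n_iter = sv$n_iter, seed = seed,
               heterogeneity_p = as.numeric(sv_heterogeneity(sv, pheno)))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write a ranked gene list as tab-separated text
#'
#' Columns rank, gene_id, statistic, p_value, so consumers can re-cut the
#' list at any fraction.
#'
#' @param ranked `ranked_genes` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ranked_genes <- function(ranked, path) {
  utils::write.table(ranked[, c("rank", "gene_id", "statistic", "p_value")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write pairwise concordance results as tab-separated text
#'
#' Long format: dataset_a, dataset_b, k_ov, m, n, N, log_p, empirical_p,
#' n_null (the per-pair null samples are not serialised).
#'
#' @param concordances `pairwise_concordance` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_concordance_tsv <- function(concordances, path) {
  cols <- c("dataset_a", "dataset_b", "k_ov", "m", "n", "N",
            "log_p", "empirical_p", "n_null")
  utils::write.table(as.data.frame(concordances)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write run metadata JSON
#'
#' @param path output path.
#' @param config named list of resolved parameters (echoed verbatim).
#' @param seed the run seed.
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(path, config, seed = NA) {
  meta <- list(package = "svastar",
               version = as.character(utils::packageVersion("svastar")),
               seed = seed,
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
               config = config)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
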