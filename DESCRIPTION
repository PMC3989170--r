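Package: svastar
Title: Robust Surrogate Variable Analysis for Heterogeneous Tissue Samples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Latent-variable correction for gene expression studies of
    heterogeneous tissue samples. Implements the original Leek-Storey
    iteratively reweighted surrogate variable analysis (SVA) and a modified
    variant (SVA*) that replaces local-FDR posterior weights with raw
    permutation p-values, preventing surrogate variables from absorbing the
    primary group effect when cell-type-mixture structure induces
    disease-specific gene-gene correlation. Includes a three-cell-type
    mixture simulator that reproduces that correlation structure, per-gene
    linear modelling with nested F-tests and permutation p-values, and a
    permutation-calibrated cross-study concordance framework (top-fraction
    hypergeometric overlap with dataset-pair-specific empirical null
    distributions) for measuring inter-study agreement of differential
    expression rankings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    sva
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
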