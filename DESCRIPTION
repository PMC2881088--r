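Package: netcox
Title: Network-Guided Gene Selection for Censored Survival Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies prognosis marker genes from expression data with
    right-censored survival outcomes by combining a weighted gene
    co-expression network with thresholding-regularized Cox regression.
    Builds the network (absolute-correlation similarity raised to a
    soft-thresholding power, topological overlap dissimilarity, dynamic
    tree-cut modules, intramodular connectivity), then runs an iterative
    gradient-thresholding algorithm that updates only genes with both a
    large Cox partial-likelihood gradient and high intramodular
    connectivity. Includes plain threshold gradient descent regularization
    (TGDR) as the connectivity-free special case, cross-validated tuning,
    a leave-one-out predictive logrank evaluation, per-gene occurrence
    indexes, and a synthetic-data generator with modular hub structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    survival,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
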