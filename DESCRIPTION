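Package: phylograd
Title: Community Phylogenetic Structure Along Environmental Gradients
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the phylogenetic structure of ecological
    communities sampled along environmental gradients. Computes alpha
    phylogenetic structure (mean pairwise distance, mean nearest-taxon
    distance, Faith's phylogenetic diversity) and their standardized effect
    sizes (NRI, NTI, SES.PD) under a taxon-label-shuffling null model;
    phylogenetic beta diversity (PhyloSor) with Baselga-style decomposition
    into turnover and nestedness components, species-level Sorensen
    dissimilarity, mean inter-community phylogenetic distance (COMDIST) and
    hierarchical clustering of communities; and multimodel inference over
    environmental predictors with Gaussian maximum-likelihood linear models
    ranked by small-sample corrected AIC (AICc), second-order polynomial
    fits, Pearson correlations and Mantel permutation tests. Includes a
    synthetic-data generator producing birth-death phylogenies and gradient
    community matrices with known assembly structure (random, clade-filtered,
    overdispersed, nested attrition, range turnover) for calibration and
    power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    picante,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
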