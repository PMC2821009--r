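Package: phyloscan
Title: Haplotype Network Association Scanning and Radical Substitution Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Phylogenetic genotype/phenotype association analysis for resequenced
    candidate genes. Builds statistical-parsimony haplotype networks, scans every
    network branch as a biallelic marker against quantitative phenotypes with
    permutation ANOVA and step-down max-statistic multiple-test correction, extends
    the scan to a multivariate MANOVA with partial Wilk's tests that isolate the
    phenotype driving a multivariate association, scores amino-acid substitutions
    for radical physicochemical change against the expectation under random
    replacement, and evaluates site-prediction criteria against known functional
    variants with exact 2x2 tests. Includes a cohort simulator that emulates the
    haplotype-frequency and correlated-lipid structure the analysis assumes, so the
    whole pipeline is testable end to end without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    seqinr,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    ape,
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
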