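Package: dimorph
Title: Cross-Omic Analysis of Sexual Dimorphism with Multi-Study Factor Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting sex-dimorphic molecular structure across
    proteomic and transcriptomic studies of the same tissue. Implements
    matrix preprocessing for data-independent-acquisition proteomics
    (gene-group deduplication, completeness filtering, replicate merging,
    quantile normalization), empirical-Bayes moderated two-group testing,
    weighted running-sum gene set enrichment with permutation-based
    normalized enrichment scores, hypergeometric over-representation,
    supervised principal component analysis with eigengene extraction,
    multi-study factor analysis (shared and study-specific loadings with
    diagonal specific variances) fitted by expectation/conditional
    maximization, Bartlett weighted-least-squares factor scores,
    sex-by-factor testing with post-hoc contrasts, and phospho-kinase
    array quantification. A synthetic multi-omic generator with planted
    latent factor structure provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    car,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    limma,
    fgsea,
    multcomp,
    jsonlite,
    optparse,
    knitr,
    rmarkdown,
    withr
Config/testthat/edition: 3
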