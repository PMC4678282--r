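Package: hericomp
Title: Heritable Component Analysis for Multivariate Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finds linear combinations of low-level phenotypic features whose
    narrow-sense heritability, as estimated by the variance-components
    maximum-likelihood polygenic model, is maximized. Provides pedigree
    parsing with kinship and fraternity matrix computation, a full
    maximum-likelihood heritability estimator with covariate correction,
    an L1-regularized heritability-maximization solver based on sequential
    quadratic programming, family-aware cross-validation for selecting the
    regularization weight, and a synthetic-data generator for
    family-correlated traits with implanted linear feature models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
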