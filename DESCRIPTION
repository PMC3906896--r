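Package: dupasym
Title: Substitution-Rate Asymmetry Between Duplicated Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring and testing asymmetry of amino-acid
    substitution rates between paralogous gene copies relative to their
    nearest singleton ortholog.  Implements parsimony ancestral
    reconstruction with posterior tie-resolution from depth-binned
    empirical substitution matrices, duplication-topology filters on
    reconciled gene trees, the Z-squared two-proportion asymmetry
    statistic with Yates-corrected significance and multiple-testing
    control, radicality measures (polarity change and directional
    exchangeability), a null simulator for homolog pairs under
    gamma-distributed site rates and optional epistasis, and polarized
    expression and polymorphism divergence analyses.  A synthetic-data
    generator produces reconciled families, expression, SNP and location
    tables with known ground truth for end-to-end parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
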