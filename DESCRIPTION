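Package: pagscreen
Title: Screening Genes Associated with Ordinal Disease Severity by
    Cumulative-Link Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-gene proportional-odds (cumulative probit) regression for
    linking gene expression to an ordinal clinical severity scale, with Wald
    z-tests and slope-based ranking of phenotype-associated genes.  Includes
    the surrounding analysis machinery: quantile normalization and
    probe-to-gene summarization of expression matrices, homolog mapping, an
    empirical-Bayes moderated two-group differential test, hypergeometric
    gene-set over-representation with enrichment scores, promoter-window
    integration of ChIP-seq peak intensities with expression fold-changes via
    an interaction-effect statistic, seedable synthetic-data generators for
    every stage, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    limma,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    rtracklayer,
    GenomicRanges,
    optparse,
    jsonlite
Config/testthat/edition: 3
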