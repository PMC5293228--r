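Package: crosstrait
Title: Cross-Disorder Shared-Locus Analysis of GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for testing whether index SNPs from one genome-wide
    association study (GWAS) are shared with a second, partially
    overlapping case-control GWAS, working entirely from summary
    statistics. Implements conditional Gaussian (ImpG-style) z-score
    imputation from an LD reference, sample-size-weighted z-score
    meta-analysis, a bivariate-normal correction that removes the
    z-score correlation induced by shared cases and controls, binomial
    enrichment testing of nominally shared loci with Bonferroni
    reporting, and interval-based (INRICH-style) gene-set enrichment
    with permutation and resampling correction. A synthetic-data
    generator produces paired GWAS z-score sets with known overlap
    covariance, polygenic inflation, LD-block structure and shared
    causal loci, so the whole pipeline can be exercised end-to-end
    without access to cohort-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
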