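Package: corsivlit
Title: Literature-Scale Enrichment Analysis of Systemically Variable
    Methylation Regions in EWAS Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to ask whether Illumina methylation-array probes that
    overlap CoRSIVs (correlated regions of systemic interindividual
    variation) are over-represented among probes reported in
    disease-specific epigenome-wide association study (EWAS)
    publications. Implements probe-ID text mining over a manifest-driven
    document corpus, MeSH-category incidence tables, matched
    control-region construction, a publication-weighted enrichment ratio
    with a permutation null, occurrence-decay curves and coverage-scaled
    power projections, test-retest stability summaries (intraclass
    correlation and interindividual range), hypergeometric gene-set
    over-representation, and a seeded synthetic-data generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    jsonlite,
    yaml,
    generics,
    withr,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vegan,
    fgsea,
    rtracklayer,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
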