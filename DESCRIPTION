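Package: trioscreen
Title: Rare-Variant Prioritization for Trio and Singleton Whole-Genome Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for prioritizing candidate disease
    variants in small rare-disease whole-genome cohorts that mix parent-child
    trios and singletons. Implements a stepwise SNV/indel filtration cascade
    (cohort genotyping rate, repeat/segmental-duplication exclusion,
    model-specific allele-frequency thresholds, cumulative gene-tier
    restriction, non-silent selection, and stringent singleton filters),
    inheritance-pattern discovery in trios (de novo, homozygous recessive,
    in-trans compound heterozygous, X-linked hemizygous), dual-caller copy
    number deletion consensus by reciprocal overlap with caller-specific
    rescue filters, candidate tables and diagnostic-yield summaries, and a
    seeded synthetic cohort generator with planted ground truth so every
    stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    vcfR,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
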