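Package: fampri
Title: Family-Based Germline Variant Prioritization for Cancer Pedigrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segregation-aware prioritization of germline variants from
    pedigree whole-exome sequencing, as used in familial cancer gene
    discovery. Implements the multi-stage filter cascade (affected-member
    intersection, control exclusion, region/function filters, zygosity
    filter, population allele-frequency screen), three-predictor
    pathogenicity banding (SIFT, PolyPhen2 HDIV, MutationTaster) with a
    composite hazard score, cosegregation probability from informative
    meioses, cohort presence/absence screening, alignment-column
    conservation and qPCR fold-change utilities, and a seeded generator of
    complete synthetic family-WES studies for end-to-end recovery testing.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    seqinr,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
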