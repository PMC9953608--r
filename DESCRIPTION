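Package: urvburden
Title: Ultra-Rare Variant Collapsing and Gene-Set Burden Analysis for
    Case-Control Exome Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-based collapsing analysis of ultra-rare coding variants in
    small case-control exome cohorts, as used to study non-syndromic cleft
    palate. Provides tiered variant filtering (population-frequency and CADD
    deleteriousness rules on annotated VCF input), per-sample and per-gene
    sequencing-coverage harmonization, binary carrier coding with per-gene
    two-sided Fisher's exact tests, a hypergeometric gene-set burden test of a
    curated disease-gene list against nominally enriched genes, local gene-set
    over-representation analysis with per-category Benjamini-Hochberg
    correction, and a fully synthetic cohort generator (VCF, sample sheet,
    coverage summaries, GMT gene sets, ground-truth manifest) so every stage is
    testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
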