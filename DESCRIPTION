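Package: invexpr
Title: Inversion-Aware Expression Analysis for Karyotyped RNA-Seq Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for gene expression variation associated with a
    large polymorphic chromosomal inversion. Provides a synthetic-data
    generator emulating a karyotyped adult/larval-pool RNA-seq design, a
    simplified negative-binomial differential-expression engine with
    median-of-ratios normalization, dominance-pattern classification of
    heterokaryotype expression, cis/trans localization and enrichment of
    differentially expressed transcripts relative to the inversion, an
    allele-specific-expression classifier with exact binomial false-positive
    calibration, a resampling null for overlap between differentially
    expressed transcripts and outlier SNPs, and distance-based PERMANOVA with
    sequential sums of squares.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    MASS,
    stats,
    utils,
    generics
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
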