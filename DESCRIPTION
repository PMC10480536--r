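Package: teloscreen
Title: Telomeric Repeat Enrichment Screening and Telomere Phenotype Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A read-level screen for telomere-associated proteins from
    ChIP-seq read sets: classifies each read by exact containment of a
    tandem telomeric repeat motif such as (TTAGGG)6, computes per-sample
    repeat-read ratios with quality-control gating, aggregates and ranks
    protein targets with Tukey-fence outlier calls, and provides the
    companion quantitative statistics used in telomere biology: qPCR
    relative telomere length (T/S, 2^-dCt), rank-based and parametric
    group comparisons, and per-nucleus focus colocalization counts and
    ratios (TIF and APB style) via mutual nearest-neighbor matching.
    Includes fully deterministic simulators for read sets with planted
    repeat content, cohort manifests, Ct tables and foci coordinate
    tables, so every statistic can be validated against exact ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
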