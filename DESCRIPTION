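Package: panelforge
Title: Design of High-Density SNP Genotyping Array Panels from Multi-Line
    Resequencing Catalogs
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for designing high-density SNP genotyping array panels
    from catalogs of variants segregating across many populations, as used
    for the chicken 600K array. Implements the candidate filter cascade
    (quality/minor-allele-frequency screening with prior-panel rescue and
    per-chromosome exemptions, spacing screens, array design-score
    thresholds, coverage-outlier and Hardy-Weinberg exclusions, genome
    k-mer masking), an iterative backbone-plus-gap-filling selection
    algorithm that distributes markers evenly in genetic-map distance
    across lines under a budget and group ratio, post-genotyping
    validation analytics (conversion classification, Mendelian trio
    consistency, exact Hardy-Weinberg test, allele-frequency estimation),
    population-structure PCA with Hardy-Weinberg normalisation, adjacent
    pair linkage disequilibrium, panel summary reports, and a synthetic
    data generator for multi-line catalogs, genetic maps, genotypes and
    trios.
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
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr,
    yaml
Config/testthat/edition: 3
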