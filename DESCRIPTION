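Package: barisa
Title: In Silico Evaluation of B-ARISA Primer Sets and Community Fingerprint Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating bacterial automated ribosomal intergenic
    spacer analysis (B-ARISA) primer systems. Implements mismatch-tolerant
    virtual PCR of degenerate (IUPAC) primer pairs against taxonomy-annotated
    sequence databases, rank-wise taxonomic coverage and non-target
    specificity reports, 2-bp binning of fragment-length fingerprints into
    OTU tables, and community comparison statistics (richness, Shannon
    diversity, Bray-Curtis and Jaccard dissimilarities, ANOSIM, NMDS).
    Includes a synthetic-data generator that plants primer binding sites at
    controlled mismatch counts inside rDNA-operon-like records, so every
    pipeline stage can be validated against exact ground truth without
    external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
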