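Package: secretr
Title: Ratiometric Secretome Profiling from TMT Conditioned-Media and Lysate Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies proteins from tandem-mass-tag (TMT) labelled
    peptide-spectrum-match (PSM) tables of conditioned-media and cell-lysate
    experiments, computes media/lysate (M/L) abundance ratios, tests
    brefeldin-A-induced changes with an empirical-Bayes moderated t, and
    classifies proteins as conventionally secreted, candidate unconventionally
    secreted, post-Golgi transmembrane, or intracellular. Includes PSM quality
    filters, peptide-ion deduplication, razor-peptide protein grouping,
    target-decoy FDR filtering, virtual-reference quantification, and a
    synthetic-data generator that produces ground-truth secretome experiments
    so every stage of the pipeline can be verified end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    optparse,
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
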