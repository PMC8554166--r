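Package: phycoprot
Title: Quantitative Post-Processing of Bottom-Up Proteomics from Seaweed
    Protein Extracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Post-processing of label-free bottom-up proteomics data from
    enzymatic seaweed protein extracts. Implements relative protein-group
    quantification by riBAQ and by length-normalized relative intensity,
    quality-based filtering with quantitative-loss accounting and Pearson
    correlation diagnostics, amino-acid composition estimation from peptide-
    and protein-level MS1 quantification with conversion of amino-acid
    analysis (mg/g) data to relative molar abundance, subcellular-distribution
    summaries with pooled intracellular fractions and ANOVA/Tukey comparisons,
    and post-processing of emulsifier and antioxidant peptide predictions
    (net charge, score thresholds, overlap clustering, non-redundant
    representative selection). A seeded synthetic-data generator with known
    ground truth makes every pipeline stage testable without raw LC-MS/MS data.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
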