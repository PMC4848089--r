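Package: defsup
Title: Deficiency Suppressor Screen Scoring, Interval Refinement and
    Expression-Load Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative machinery for dominant deficiency suppressor
    screens in Drosophila nonsense-mediated mRNA decay (NMD) mutants:
    Deficiency Suppression Scores (DSS) from balancer-cross progeny counts,
    binomial viability statistics, genomic candidate-region refinement by
    suppressor/non-suppressor interval elimination, per-deficiency RNA-seq
    "genomic load" with ribosomal-gene normalization and its correlation
    with suppression strength, and molecular-assay statistics (exponential
    mRNA half-life fitting, delta-delta-Ct relative expression, and
    premature-termination-codon allele stabilization ratios). Includes a
    seeded synthetic-data generator emulating the genetic and expression
    structure of such a screen, an end-to-end pipeline with a
    truth-against-recovery report, and ggplot2 visualisations.
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
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
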