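Package: divscan
Title: Divergence Scans and Essentiality-Matched Resampling Tests for
    Yeast Gene Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for genome-wide scans of sequence and
    expression divergence between two closely related species sampled at
    the population level. Computes per-gene absolute divergence (D_XY)
    and nucleotide diversity (pi) from multi-strain alignments, tests a
    focal gene set for enrichment of any per-gene statistic against
    essentiality-matched resampled cohorts, applies the same engine to
    directional cis-regulatory and total expression divergence measured
    in interspecies hybrids and purebreds, and to per-branch phylogenetic
    branch lengths. Includes alignment quality filters (gap fractions,
    population size, strain coverage), strand-aware promoter extraction,
    and a synthetic-data generator with analytic ground truth for
    validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
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
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
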