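Package: mitospectra
Title: Comparative Analysis of Mitochondrial DNA Mutation Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Annotates human mitochondrial DNA point mutations for genetic
    consequence on the rCRS coordinate system using the vertebrate
    mitochondrial genetic code, tests their genomic distribution against
    random-placement null models, compares mutation-type and consequence
    spectra across cohorts (ageing somatic, rare population, disease) with
    chi-squared contingency tests under Bonferroni-corrected thresholds, and
    compares precomputed pathogenicity-score distributions with Wilcoxon
    rank-sum tests, including enumeration of every possible amino-acid-changing
    substitution in the 13 mitochondrial protein-coding genes. A seeded
    synthetic-cohort generator reproduces the statistical structure of
    published single-cell mutation tables so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
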