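Package: neodb
Title: Proteogenomic Mutant-Peptide Databases for HLA-I Immunopeptidomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds compact proteogenomic search databases from somatic
    coding variants (COSMIC-style and MAF-style tables) for HLA class I
    immunopeptidome searching, and post-processes the resulting peptide
    identifications. Parses HGVS coding notation, applies variants to
    coding sequences, translates and classifies protein consequences
    (missense, nonsense, nonstop, start-loss, in-frame and frameshift
    indels), excises mutant entries with 50-residue flanks, merges them
    with a reference proteome, flags mass-indistinguishable mutant/wild
    peptide pairs (I/L swaps and equal-mass residue recombinations),
    applies 8-14-residue length and percent-rank binder filters, and
    compares identifications between two database searches. A seeded
    synthetic-fixture generator with a ground-truth ledger makes every
    stage testable without external downloads.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
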