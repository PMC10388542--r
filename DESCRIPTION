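Package: chlorotype
Title: Chloroplast Tandem-Repeat InDel Markers for Cytoplasm Typing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative analysis of near-identical circular chloroplast
    genomes aimed at cytoplasmic male sterility (CMS) diagnostics. Detects
    the quadripartite structure (LSC/IRb/SSC/IRa), aligns genome pairs and
    calls left-normalized SNPs and InDels, characterises large InDels as
    tandem-repeat copy-number variants, designs and applies diagnostic
    PCR markers in silico to classify cytotypes (S vs N) across cohorts,
    and places genomes on a neighbor-joining tree with bootstrap support
    from composite-likelihood Tamura-Nei distances. Includes a fully
    deterministic synthetic-genome generator so every stage is testable
    without external sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
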