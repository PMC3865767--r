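Package: paralogdiv
Title: Post-Duplication Divergence Analysis for Duplicated Protein Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analysis of evolutionary divergence between paralog clades born
    of a gene duplication, motivated by the vertebrate BACE1/BACE2 aspartyl
    protease family. Provides homolog triage classification from sequence
    architecture (signal peptide, C-terminal transmembrane stretch, PROSITE
    active-site motifs, local-alignment evidence), BioNJ distance trees with
    bootstrap support, a paired-ortholog rate-asymmetry statistic with an
    exact sign test, counting-based Ka/Ks (Nei-Gojobori pairwise and a
    SLAC-style tree-ancestor variant) over whole genes and domain/exon
    partitions, conserved-block extraction with per-column information
    content, and a seeded codon-level simulator of duplicated gene families
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    phangorn,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
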