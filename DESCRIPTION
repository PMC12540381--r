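Package: rnaneo
Title: Neoantigen Identification from Tumor RNA Sequencing Alone
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies and prioritizes candidate tumor neoantigens from RNA
    sequencing data without matched DNA sequencing. Implements somatic-variant
    filtering on depth, allele depth, base quality, strand bias, variant allele
    frequency and expression; transcript-aware protein-consequence annotation;
    enumeration of mutant 8-11-mer MHC class I epitopes with wild-type
    partners; a pluggable peptide-MHC binding-predictor interface with a
    deterministic built-in scorer and a precomputed-table adapter; weighted
    multi-dimensional priority scoring and top-N selection; mutation-centered
    27/31-mer long-peptide vaccine design; and comparison of RNA-only versus
    conventional candidate sets. A seeded synthetic-cohort generator (genome,
    transcript models, variants, expression) supports fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    generics,
    ggplot2,
    yaml,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    seqinr,
    withr
Config/testthat/edition: 3
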