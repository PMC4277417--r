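Package: asekit
Title: Allele-Specific Expression Analysis for F1 Hybrids of Inbred Parents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Computational core for allele-specific expression (ASE) studies of
    F1 hybrids whose inbred parents include the reference strain. From a genome,
    gene annotation, variant calls and per-replicate allele counts it builds
    variant-masked genomes, parental transcript and protein sequences, basic
    variant-effect annotations, exact binomial allele-imbalance tests at SNP,
    transcript and gene level with replicate-discordance and opposite-direction
    flags, a trimmed set of enriched Gene Ontology terms, and a filterable
    tabular report layer. A deterministic synthetic-study generator emulates a
    multi-tissue, multi-replicate hybrid design so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    stats,
    utils,
    vcfR
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
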