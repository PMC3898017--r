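Package: regulonmapr
Title: Mapping Bacterial Transcription-Factor Regulons from ChIP-Seq Tag Data
Version: 0.9.0
Authors@R:
    person("Regulon", "Mapper", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for mapping the binding-site catalog
    (regulon) of a bacterial transcription factor from ChIP-Seq data, built
    around the NtcA regulon of the cyanobacterium Anabaena sp. PCC 7120.
    Calls double-strand binding regions from strand-specific 5'-end tag
    coverage with a continuity-corrected z statistic, adjusts the discrete
    p-values with a Tarone-modified distribution-free Benjamini-Yekutieli
    procedure (Q and NLQ values computed in log space), assigns regions to
    genes with positional classification, scans for GTAN8TAC-like binding
    sites, summarises position-frequency matrices and per-column information
    content, and dissects bacterial Class II activator and repressor-like
    promoter architectures. Includes a seeded synthetic ChIP experiment
    generator with planted sites for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
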