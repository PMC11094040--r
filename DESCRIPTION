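Package: pongclass
Title: Ping-Pong Classification of PIWI-Bound Small RNA Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of transposon-derived PIWI-interacting RNAs (piRNAs)
    from small RNA sequencing libraries: UMI-aware adapter trimming and
    PCR-duplicate collapsing, an exact/one-mismatch ungapped mapper against a
    transposon panel, library normalization, MA-based expression-change
    grouping, 1U/10A nucleotide-bias tables, and classification of reference
    piRNAs into heterotypic (A-to-S, S-to-A) and homotypic (S-to-S) ping-pong
    categories from Siwi-IP and BmAgo3-IP libraries via the 5-prime 10-nt
    overlap partner rule. Includes a seeded synthetic-data generator (planted
    ping-pong pairs, IP enrichment, knockdown effects, UMIs, PCR duplication,
    sequencing errors) with full ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    S4Vectors,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
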