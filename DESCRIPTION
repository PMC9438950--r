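Package: gfakit
Title: Assembly Graph Statistics, Conversion and Curation for Genome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Represents genome assemblies in a unified GFA2-like graph model
    (segments, gaps, overlap edges, paths), computes assembly summary
    statistics (N50/L50, NG50/LG50, auN, base composition), converts
    losslessly among FASTA, FASTQ, GFA1 and GFA2 (plain or gzip-compressed),
    exports AGP, BED and sizes tables, filters, sorts and
    homopolymer-compresses sequences, and edits assemblies through a
    human-readable sequential instruction script executed against a
    bidirected assembly graph. Includes a seeded synthetic-assembly
    generator with ground-truth statistics for testing and demonstration.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    rlang,
    stringi,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
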