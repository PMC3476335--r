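Package: releasewise
Title: Version-Aware Access to Ensembl-Style Genome Annotation Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A single installation that transparently serves multiple schema
    releases of Ensembl-style relational genome databases. A declarative
    version-rules file resolves each (database type, schema release) to a
    named set of SQL query templates, so the same calls work unchanged
    against pre- and post-migration table layouts (the release-65 stable_id
    merge, the release-51 multi-species coordinate systems). Provides a
    registry that parses database names per Ensembl conventions, projection
    of locations across coordinate-system levels via assembly blocks, lazy
    stitching of genomic sequence from sequence-level components, transcript
    splicing and translation, cross-schema variant and homology retrieval,
    GFF3/BED/FASTA/TSV exporters, a command-line interface, and a generator
    for miniature fixture databases in every supported schema dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    DBI,
    dplyr,
    ggplot2,
    purrr,
    rlang,
    RSQLite,
    stringr,
    tibble
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
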