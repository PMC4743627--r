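Package: lociRank
Title: Overlap Enrichment Analysis for Genomic Region Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Enrichment analysis for sets of genomic regions against a
    reference database of annotated region sets. Given one or more query
    region sets and a background universe of regions, counts region-level
    overlaps with every database entry, tests each overlap with a one-sided
    Fisher's exact test, applies Benjamini-Hochberg false discovery rate
    correction, and ranks database entries by a composite max-rank score
    over p-value, log odds ratio and support. Includes a reference-database
    loader with fingerprint-based caching, background-universe construction
    and diagnostics, a seeded simulator of planted-enrichment scenarios,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'io_regions.R'
    'refdb.R'
    'universe.R'
    'enrichment.R'
    'simulate.R'
    'cli.R'
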