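Package: trfscape
Title: Identification, Classification and Developmental Profiling of
    tRNA-Derived Fragments from Small RNA-Seq Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls tRNA-derived fragments (tRFs) from stage-resolved small
    RNA-seq libraries by exact, CCA-tail-aware matching of 25-45 nt reads to
    mature mitochondrial and nuclear tRNA sequences, with
    mitochondrial-before-nuclear precedence and multi-mapping ambiguity
    filters. Classifies each fragment into anticodon-anchored structural
    regions (5' half, 3' half, 5' end, 3' end, anticodon stem-loop),
    summarizes per-anticodon totals and main regions, and profiles
    spike-in-normalized expression across six developmental stages
    (per-position coverage, relative-abundance heatmaps, hierarchical
    clustering with uncentered correlation). Includes a seeded synthetic-data
    generator that plants tRNA genes, isodecoder subtypes, decoy loci and
    stage-structured fragment libraries with a known truth table, so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    S4Vectors,
    ape,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
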