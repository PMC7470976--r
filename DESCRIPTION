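Package: retra
Title: Toolkit for Genome-Guided Transcriptome Re-Annotation
Version: 0.1.0
Authors@R:
    person("RTR", "Toolkit Authors", email = "retra@example.org", role = c("aut", "cre"))
Description: Reusable building blocks for constructing a re-annotated
    transcriptome from per-replicate genome-guided assemblies:
    replicate-support consolidation of transcript models, intron-chain
    based merging and comparison of annotations, consensus coding-potential
    classification from three evidence channels, cross-species splice
    junction conservation testing with a built-in global aligner,
    TSS/TTS/transposable-element/splice-signature feature analyses,
    seven-way alternative-splicing event classification, and
    expression-presence rules (tissue specificity, housekeeping sets,
    dominant-isoform switching).  Ships deterministic seeded generators
    for synthetic genomes, annotations, replicate assemblies, expression
    matrices and evidence tables so every pipeline stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
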