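Package: spliceproj
Title: Splice Junction Prediction in Transcripts Without a Reference Genome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts exon-exon (splice) junction positions in mRNA and
    assembled transcriptome sequences of organisms that lack a reference
    genome. Junctions annotated in one or more well-studied reference
    species are projected onto query transcripts through best-hit translated
    (six-frame) protein alignments; junctions that split codons, and are
    therefore invisible at amino-acid resolution, are resolved with a
    donor-side exon-end base motif learned from the unambiguous junctions.
    Evidence from multiple reference databases can be merged into a
    consensus set. The package includes a reference-database builder with a
    transcript-consistency (annotation quality) filter, a
    sensitivity/precision/FDR benchmarking harness with distance tolerance,
    a motif-length by minimum-exon-length parameter sweep, and a synthetic
    data generator producing toy reference species and diverged query
    transcriptomes with known junction truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
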