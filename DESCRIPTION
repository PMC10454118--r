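Package: eccpipe
Title: Extrachromosomal Circular DNA Discovery, Clustering, and Hotspot
    Analysis from Rolling-Circle Amplification Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for circulome analysis in mammalian cell
    lines: deconcatenation of Phi-29 rolling-circle-amplification long reads
    into monomer circle sequences with a periodicity-based circularity call,
    greedy incremental clustering at a sequence-identity threshold, seed-and-
    vote placement of circles on a reference genome, Z-score detection of
    eccDNA biogenesis hotspots over consecutive 500-kbp windows, structural
    composition summaries (gene, tRNA, rDNA, origin-of-replication and repeat
    content, GC), and integration with TMM-normalized expression tables via
    fold-change correlation rules. Includes a synthetic-data generator (toy
    genome, planted hotspots, concatemer reads, expression tables with planted
    dosage effects) so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
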