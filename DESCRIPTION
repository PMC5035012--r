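Package: rDNAretro
Title: Characterization of rDNA-Targeting R2 Retrotransposons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing R2-family non-LTR retrotransposons,
    which insert at a single canonical site inside 28S ribosomal RNA genes.
    The package discovers element copies in a genome by k-mer seeded
    ungapped extension, calls 5'/3' insertion junctions against a 28S
    target reference by local alignment, computes junction offsets and
    classifies target specificity (canonical, shifted, non-specific),
    detects 28S-derived segments inside element 3' UTRs, types clades
    (R2A-R2D) by their CCHH/CCHC zinc-finger complement, performs virtual
    PCR with IUPAC-degenerate primers, builds majority-rule consensus
    sequences, and reconstructs distance-based (p-distance,
    neighbor-joining, bootstrap) phylogenies. A synthetic rDNA-array
    genome simulator with a ground-truth annotation table makes the whole
    pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
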