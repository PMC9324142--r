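Package: mobilomeR
Title: LTR Retrotransposon Annotation and Mobilome Activity Detection
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Structural mining of intact LTR retrotransposons (paired LTRs,
    TG...CA termini, target-site duplications), hierarchical classification
    into superfamilies, lineages, families and subfamilies (protein-domain
    search, single-linkage LTR clustering, bootstrap/branch-length tree
    cuts), K80 LTR-divergence insertion dating, solo-LTR accounting,
    eccDNA (mobilome-seq) profiling with circle-junction detection, and
    non-reference insertion calling from paired-end reads with soft-clip
    breakpoint refinement plus a mask-and-revalidate accuracy harness.
    Includes a synthetic-data generator producing genomes, circles and
    paired-end read libraries with known ground truth so that every stage
    of the pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    data.table,
    ape,
    igraph,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Rsamtools
Config/testthat/edition: 3
SystemRequirements: mafft (for multiple alignment)
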