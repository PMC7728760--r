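Package: lcblocks
Title: Locally Collinear Block Reconstruction from de Bruijn Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes collections of closely related assembled genomes into
    locally collinear blocks by analysing a compacted de Bruijn graph. Homologous
    regions appear in the graph as chains of bubbles held together by a carrying
    path; a greedy seed-and-extend search scores candidate blocks and reports
    edge-disjoint genomic walks. Includes a centre-star aligner producing MAF
    output for each block, alignment evaluation metrics (position-pair recall and
    precision, coverage, per-column nucleotide diversity), and a synthetic-genome
    simulator with an exact homology ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
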