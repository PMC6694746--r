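Package: triokmer
Title: Alignment-Free Mining of De Novo Variant Candidates from Trio Sequencing
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Mines candidate de novo variants from mother-father-child
    sequencing trios without aligning reads first. Counted k-mers from each
    family member are stored in a coupled Bloom filter (a membership bit plane
    paired with a bitwise count plane sharing the same hash positions), child
    k-mers whose parental count ratios fall below a threshold are retained,
    sequencing-error k-mers are removed by a z-score test over Hamming-distance-1
    neighbors, surviving k-mers are extended into mappable contigs along
    unambiguous (k-1)-overlaps, and externally called variants are refined by
    k-mer support evidence. Includes a diploid trio read simulator with planted
    inherited and de novo variants for end-to-end validation, and a
    gene-proximity filter for variants overlapping lncRNA annotations.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
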