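Package: splitbridge
Title: Gene Fusion Discovery from RNA-Seq via Split-Read and Bridge-Pair Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects gene fusions and chimeric transcripts from bulk RNA-seq
    reads. Reads are aligned end-to-end to the transcriptome (and optionally
    the genome); unmapped reads are aligned locally to the genome, and pairs
    of local alignments of one read that cannot be explained by normal
    splicing are assembled into SPLIT breakpoint candidates, while
    discordant read pairs form BRIDGE candidates. Candidates are clustered
    by genomic position, directionality and breakpoint compatibility,
    refined by a rescue step, scored with a set of filter features
    (metacluster homogeneity, read-coverage statistics, junction homology,
    insert-size validity, strand concordance, biotype control) and reported
    with annotated breakpoints and junction sequences. The package also
    ships a reproducible fusion simulator that plants five classes of
    fusion events (exon-boundary, intra-exonic, intronic, intergenic and
    multi-isoform junctions) into a synthetic or user-supplied reference,
    simulates Illumina-like paired-end reads with background expression,
    and scores predictions against the planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Rcpp,
    methods,
    Biostrings,
    rtracklayer,
    IRanges,
    GenomicRanges,
    S4Vectors,
    stats,
    utils,
    withr,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
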