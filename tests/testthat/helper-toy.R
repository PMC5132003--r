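# Shared fixtures, built in code at test time.

# A tiny deterministic two-chromosome reference with two genes:
#   GA on chr1 '+': exons 101-200, 301-400, 501-600
#   GB on chr2 '-': exons 1001-1100, 1301-1400
tiny_db <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    genome <- withr::with_seed(424242, Biostrings::DNAStringSet(c(
      chr1 = paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = ""),
      chr2 = paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = ""))))
    exons <- data.frame(
      chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
      start = c(101L, 301L, 501L, 1001L, 1301L),
      end = c(200L, 400L, 600L, 1100L, 1400L),
      strand = c("+", "+", "+", "-", "-"),
      gene_id = c("GA", "GA", "GA", "GB", "GB"),
      transcript_id = c("TA", "TA", "TA", "TB", "TB"),
      gene_name = c("GENEA", "GENEA", "GENEA", "GENEB", "GENEB"),
      biotype = "protein_coding",
      stringsAsFactors = FALSE)
    cache <<- load_annotation(exons, genome)
    cache
  }
})

# A small simulated reference shared by integration-style tests.
mini_ref <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_toy_reference(n_chrom = 2L, chrom_len = 300000L,
                                       genes_per_chrom = 20L, seed = 7L)
    cache
  }
})

mini_db <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      r <- mini_ref()
      cache <<- load_annotation(r$exons, r$genome)
    }
    cache
  }
})

# random BPC-like alignment rows for clustering property tests
random_bpc_rows <- function(n, chroms = c("chr1", "chr2"), span = 1000L) {
  start <- sample.int(span, n, replace = TRUE)
  len <- sample(20:120, n, replace = TRUE)
  data.frame(
    bpc_id = paste0("x", seq_len(n)), bpc_type = "split",
    read_id = paste0("r", seq_len(n)), mate = 1L, role = 1L,
    chrom = sample(chroms, n, replace = TRUE),
    start = start, end = start + len,
    strand = sample(c("+", "-"), n, replace = TRUE),
    side = sample(c("left", "right"), n, replace = TRUE),
    bp = start, q = 1L, l = len, score = 2L * len, nm = 0L, nhits = 1L,
    multi = FALSE, stringsAsFactors = FALSE)
}

# random local-alignment rows of one read (for split-detector oracles)
random_read_alignments <- function(n, read_len = 75L) {
  q <- sample.int(read_len - 20L, n, replace = TRUE)
  l <- pmin(sample(20:60, n, replace = TRUE), read_len - q + 1L)
  start <- sample.int(50000L, n, replace = TRUE)
  data.frame(
    read_id = "r1", mate = 1L,
    chrom = sample(c("chr1", "chr2", "chr3"), n, replace = TRUE),
    start = start, end = start + l - 1L,
    strand = sample(c("+", "-"), n, replace = TRUE),
    q = q, l = l, score = 2L * l, nm = 0L, gaps = 0L, mmq = "",
    nhits = 1L, stringsAsFactors = FALSE)
}
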