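#' @useDynLib splitbridge, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors queryHits subjectHits mcols
#' @importFrom Biostrings DNAStringSet readDNAStringSet reverseComplement subseq
#' @importFrom stats rnorm runif rbinom rlnorm setNames
#' @importFrom utils head read.delim write.table
"_PACKAGE"

#' Load a transcript annotation and genome into a queryable store
#'
#' Builds a `TranscriptDB`: transcript models keyed by transcript id with an
#' interval index per chromosome, plus the genome sequence. All coordinates
#' are 1-based and closed.
#'
#' @param gtf Path to a GTF file (Ensembl dialect: `exon` features carrying
#'   `gene_id`/`transcript_id` and optionally `gene_name`/`gene_biotype`
#'   attributes), or a data.frame of exons with columns `chrom`, `start`,
#'   `end`, `strand`, `gene_id`, `transcript_id` and optionally
#'   `gene_name`, `biotype`.
#' @param genome Path to a FASTA file or a named [Biostrings::DNAStringSet].
#' @return An object of class `TranscriptDB`.
#' @export
load_annotation <- function(gtf, genome) {
  if (is.character(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  stopifnot(methods::is(genome, "DNAStringSet"))

  if (is.character(gtf)) {
    exons <- .parse_gtf_exons(gtf)
  } else {
    exons <- as.data.frame(gtf, stringsAsFactors = FALSE)
    if (is.null(exons$gene_name)) exons$gene_name <- exons$gene_id
    if (is.null(exons$biotype)) exons$biotype <- "protein_coding"
  }
  need <- c("chrom", "start", "end", "strand", "gene_id", "transcript_id")
  miss <- setdiff(need, names(exons))
  if (length(miss)) stop("exon table lacks columns: ", paste(miss, collapse = ", "))

  bad <- setdiff(unique(exons$chrom), names(genome))
  if (length(bad))
    stop("chromosome(s) in annotation absent from genome: ",
         paste(bad, collapse = ", "))

  # enforce per-transcript genomic order and transcript-frame coordinates
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  sp <- split(seq_len(nrow(exons)), exons$transcript_id)
  exons$rank_tx <- NA_integer_
  exons$t_start <- NA_integer_
  exons$t_end <- NA_integer_
  for (idx in sp) {
    strand <- exons$strand[idx[1]]
    len <- exons$end[idx] - exons$start[idx] + 1L
    ord <- if (strand == "-") rev(seq_along(idx)) else seq_along(idx)
    tlen <- len[order(ord)]           # lengths in transcript order
    te <- cumsum(tlen)
    ts <- te - tlen + 1L
    exons$rank_tx[idx[order(ord)]] <- seq_along(idx)
    exons$t_start[idx[order(ord)]] <- ts
    exons$t_end[idx[order(ord)]] <- te
  }

  tx <- do.call(rbind, lapply(sp, function(idx) {
    data.frame(transcript_id = exons$transcript_id[idx[1]],
               gene_id = exons$gene_id[idx[1]],
               gene_name = exons$gene_name[idx[1]],
               chrom = exons$chrom[idx[1]],
               strand = exons$strand[idx[1]],
               biotype = exons$biotype[idx[1]],
               start = min(exons$start[idx]),
               end = max(exons$end[idx]),
               tlen = sum(exons$end[idx] - exons$start[idx] + 1L),
               n_exons = length(idx),
               stringsAsFactors = FALSE)
  }))
  rownames(tx) <- tx$transcript_id
  stopifnot(all(tx$strand %in% c("+", "-")), all(tx$tlen >= 1))

  genes <- do.call(rbind, lapply(split(tx, tx$gene_id), function(g) {
    data.frame(gene_id = g$gene_id[1], gene_name = g$gene_name[1],
               chrom = g$chrom[1], strand = g$strand[1],
               start = min(g$start), end = max(g$end),
               biotype = g$biotype[1], stringsAsFactors = FALSE)
  }))
  rownames(genes) <- genes$gene_id

  exons_gr <- GenomicRanges::GRanges(exons$chrom,
                                     IRanges::IRanges(exons$start, exons$end),
                                     strand = exons$strand)
  S4Vectors::mcols(exons_gr)$transcript_id <- exons$transcript_id
  S4Vectors::mcols(exons_gr)$gene_id <- exons$gene_id
  tx_gr <- GenomicRanges::GRanges(tx$chrom, IRanges::IRanges(tx$start, tx$end),
                                  strand = tx$strand)
  S4Vectors::mcols(tx_gr)$transcript_id <- tx$transcript_id
  S4Vectors::mcols(tx_gr)$gene_id <- tx$gene_id

  db <- list(transcripts = tx, exons = exons, genes = genes,
             genome = genome, exons_gr = exons_gr, tx_gr = tx_gr)
  class(db) <- "TranscriptDB"
  db
}

# Minimal structural validation (field count, with line numbers) before
# handing attribute parsing to a standard reader.
.parse_gtf_exons <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  nf <- lengths(strsplit(lines[keep], "\t", fixed = TRUE))
  if (any(nf != 9)) {
    badline <- which(keep)[which(nf != 9)[1]]
    stop("malformed GTF line ", badline, " in ", path, " (expected 9 fields)")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (!length(gr)) stop("no exon features in ", path)
  m <- S4Vectors::mcols(gr)
  gname <- if (!is.null(m$gene_name)) m$gene_name else m$gene_id
  bty <- if (!is.null(m$gene_biotype)) m$gene_biotype else "protein_coding"
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             gene_id = m$gene_id, transcript_id = m$transcript_id,
             gene_name = ifelse(is.na(gname), m$gene_id, gname),
             biotype = ifelse(is.na(bty), "protein_coding", bty),
             stringsAsFactors = FALSE)
}

#' @export
print.TranscriptDB <- function(x, ...) {
  cat("TranscriptDB:", nrow(x$transcripts), "transcripts,",
      nrow(x$genes), "genes,", nrow(x$exons), "exons,",
      length(x$genome), "sequences\n")
  invisible(x)
}

#' Project a transcript interval onto the genome
#'
#' Maps a transcript-coordinate interval to its genomic exon blocks. On
#' minus-strand transcripts, transcript coordinate 1 is the 3'-most genomic
#' base of the transcript's last genomic exon (i.e. the first transcribed
#' base). Coordinates are 1-based closed.
#'
#' @param transcript_id Transcript identifier.
#' @param t_start 1-based start offset on the transcript.
#' @param t_len Interval length (>= 1).
#' @param db A `TranscriptDB`.
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`, one row
#'   per genomic block, in transcript (5'-to-3') order; block lengths sum to
#'   `t_len`.
#' @export
project_to_genome <- function(transcript_id, t_start, t_len, db) {
  tx <- db$transcripts[transcript_id, ]
  if (is.na(tx$transcript_id)) stop("unknown transcript: ", transcript_id)
  t_end <- t_start + t_len - 1L
  if (t_start < 1L || t_end > tx$tlen)
    stop("interval [", t_start, ", ", t_end, "] out of range for ",
         transcript_id, " (length ", tx$tlen, ")")
  ex <- db$exons[db$exons$transcript_id == transcript_id, , drop = FALSE]
  ex <- ex[order(ex$rank_tx), , drop = FALSE]
  hit <- ex$t_end >= t_start & ex$t_start <= t_end
  ex <- ex[hit, , drop = FALSE]
  ov_s <- pmax(ex$t_start, t_start)
  ov_e <- pmin(ex$t_end, t_end)
  if (tx$strand == "+") {
    gs <- ex$start + (ov_s - ex$t_start)
    ge <- ex$start + (ov_e - ex$t_start)
  } else {
    ge <- ex$end - (ov_s - ex$t_start)
    gs <- ex$end - (ov_e - ex$t_start)
  }
  data.frame(chrom = ex$chrom, start = gs, end = ge, strand = tx$strand,
             stringsAsFactors = FALSE)
}

# Vectorized genomic span (outer interval) of transcript intervals; used when
# converting transcriptomic alignments to genomic coordinates.
.project_spans <- function(db, transcript_id, t_start, t_end) {
  n <- length(transcript_id)
  out <- data.frame(chrom = character(n), gstart = integer(n),
                    gend = integer(n), gstrand = character(n),
                    stringsAsFactors = FALSE)
  for (id in unique(transcript_id)) {
    sel <- which(transcript_id == id)
    ex <- db$exons[db$exons$transcript_id == id, , drop = FALSE]
    ex <- ex[order(ex$rank_tx), , drop = FALSE]
    tx_strand <- ex$strand[1]
    g_of <- function(t) { # genomic position of transcript coordinate t
      i <- findInterval(t, ex$t_start)
      if (tx_strand == "+") ex$start[i] + (t - ex$t_start[i])
      else ex$end[i] - (t - ex$t_start[i])
    }
    g1 <- g_of(t_start[sel]); g2 <- g_of(t_end[sel])
    out$chrom[sel] <- ex$chrom[1]
    out$gstart[sel] <- pmin(g1, g2)
    out$gend[sel] <- pmax(g1, g2)
    out$gstrand[sel] <- tx_strand
  }
  out
}

# Transcript coordinate of a genomic position, or NA when the position does
# not fall in an exon of the transcript.
.genomic_to_transcript <- function(db, transcript_id, pos) {
  ex <- db$exons[db$exons$transcript_id == transcript_id, , drop = FALSE]
  hit <- which(ex$start <= pos & ex$end >= pos)
  if (!length(hit)) return(NA_integer_)
  e <- ex[hit[1], ]
  if (e$strand == "+") e$t_start + (pos - e$start)
  else e$t_start + (e$end - pos)
}

# Genomic position of a transcript coordinate (inverse of
# .genomic_to_transcript).
.transcript_to_genomic <- function(db, transcript_id, t) {
  ex <- db$exons[db$exons$transcript_id == transcript_id, , drop = FALSE]
  hit <- which(ex$t_start <= t & ex$t_end >= t)
  if (!length(hit)) return(NA_integer_)
  e <- ex[hit[1], ]
  if (e$strand == "+") e$start + (t - e$t_start)
  else e$end - (t - e$t_start)
}

#' Annotate a genomic position
#'
#' Classifies a position as sitting on an exon edge, inside an exon, inside
#' an intron, or in an intergenic region, and lists the genes it falls in.
#'
#' @param chrom Chromosome name.
#' @param pos 1-based genomic position.
#' @param db A `TranscriptDB`.
#' @param slack Maximum distance (bp) from an annotated exon boundary still
#'   counted as `exon_edge` (default 0: exact).
#' @return list with `category` (one of `exon_edge`, `inside_exon`,
#'   `inside_intron`, `intergenic`), `gene_ids`, `biotypes`.
#' @export
annotate_position <- function(chrom, pos, db, slack = 0) {
  p <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  ex_hit <- S4Vectors::subjectHits(
    GenomicRanges::findOverlaps(p, db$exons_gr, ignore.strand = TRUE))
  tx_hit <- S4Vectors::subjectHits(
    GenomicRanges::findOverlaps(p, db$tx_gr, ignore.strand = TRUE))
  genes_of <- function(ids) sort(unique(ids))
  if (length(ex_hit)) {
    ex <- db$exons_gr[ex_hit]
    edge <- abs(GenomicRanges::start(ex) - pos) <= slack |
      abs(GenomicRanges::end(ex) - pos) <= slack
    gids <- genes_of(S4Vectors::mcols(ex)$gene_id)
    return(list(category = if (any(edge)) "exon_edge" else "inside_exon",
                gene_ids = gids,
                biotypes = unique(db$genes[gids, "biotype"])))
  }
  # edge slack may reach beyond the exon
  if (slack > 0) {
    near <- GenomicRanges::findOverlaps(
      p + slack, db$exons_gr, ignore.strand = TRUE)
    nh <- S4Vectors::subjectHits(near)
    if (length(nh)) {
      ex <- db$exons_gr[nh]
      edge <- abs(GenomicRanges::start(ex) - pos) <= slack |
        abs(GenomicRanges::end(ex) - pos) <= slack
      if (any(edge)) {
        gids <- genes_of(S4Vectors::mcols(ex)$gene_id[edge])
        return(list(category = "exon_edge", gene_ids = gids,
                    biotypes = unique(db$genes[gids, "biotype"])))
      }
    }
  }
  if (length(tx_hit)) {
    gids <- genes_of(S4Vectors::mcols(db$tx_gr)$gene_id[tx_hit])
    return(list(category = "inside_intron", gene_ids = gids,
                biotypes = unique(db$genes[gids, "biotype"])))
  }
  list(category = "intergenic", gene_ids = character(0),
       biotypes = character(0))
}

#' Spliced transcript sequences
#'
#' @param db A `TranscriptDB`.
#' @param ids Transcript ids (default: all).
#' @return A [Biostrings::DNAStringSet], minus-strand transcripts
#'   reverse-complemented so sequences read 5' to 3'.
#' @export
transcript_seqs <- function(db, ids = NULL) {
  if (is.null(ids)) ids <- db$transcripts$transcript_id
  seqs <- lapply(ids, function(id) {
    ex <- db$exons[db$exons$transcript_id == id, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    chr <- db$genome[[ex$chrom[1]]]
    s <- unlist(Biostrings::DNAStringSet(lapply(seq_len(nrow(ex)), function(i)
      Biostrings::subseq(chr, ex$start[i], ex$end[i]))))
    if (ex$strand[1] == "-") s <- Biostrings::reverseComplement(s)
    s
  })
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}
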