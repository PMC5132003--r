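# Alignment layer: end-to-end and local read alignment against an in-memory
# k-mer index, pair classification, insert-size model and expression
# estimation. The built-in seeded mapper (end-to-end verification plus local
# Smith-Waterman) is the default engine; pre-computed alignment tables can be
# supplied instead anywhere a mapper result is consumed (bypass mode).

#' Alignment scoring scheme
#'
#' Defaults: +2 match, -2 mismatch, -6 gap open, -3 gap extension. The
#' maximum score of a read is `read length x match`.
#'
#' @param match,mismatch,gap_open,gap_extend Integer scores; `match` must be
#'   positive and the penalties non-positive.
#' @return list of class `align_scoring`.
#' @export
align_scoring <- function(match = 2L, mismatch = -2L,
                          gap_open = -6L, gap_extend = -3L) {
  stopifnot(match > 0, mismatch <= 0, gap_open <= 0, gap_extend <= 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "align_scoring")
}

#' Maximum alignment score of a read
#' @param scoring An [align_scoring()] scheme.
#' @param read_len Read length in bp.
#' @return `read_len * match`.
#' @export
score_max <- function(scoring, read_len) read_len * scoring$match

#' Build a k-mer index over reference sequences
#'
#' @param seqs Named [Biostrings::DNAStringSet] or named character vector.
#' @param k K-mer size (8-15, default 13).
#' @return list of class `sb_index` holding an external pointer; valid for
#'   the current session only.
#' @export
build_align_index <- function(seqs, k = 13L) {
  if (methods::is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  stopifnot(!is.null(names(seqs)))
  ptr <- sb_build_index(unname(seqs), names(seqs), as.integer(k))
  structure(list(ptr = ptr, names = names(seqs), k = as.integer(k)),
            class = "sb_index")
}

#' @export
print.sb_index <- function(x, ...) {
  info <- sb_index_info(x$ptr)
  cat("sb_index: k =", info$k, ",", length(info$names), "sequences,",
      format(info$n_kmers, big.mark = ","), "k-mers\n")
  invisible(x)
}

.read_chars <- function(reads) {
  out <- as.character(reads)
  names(out) <- names(reads)
  out
}

#' End-to-end alignment of reads against an index
#'
#' Mismatch-only full-length alignment seeded from the k-mer index.
#'
#' @param reads Named [Biostrings::DNAStringSet] or character vector.
#' @param index An [build_align_index()] result.
#' @param max_mm Maximum mismatches tolerated (default 6).
#' @param max_hits Maximum reported placements per read (default 4).
#' @param seed_step Offset between seeds (default: k).
#' @return data.frame with `read_id`, `ref`, `pos`, `strand`, `mm`, `nhits`.
#' @export
align_end_to_end <- function(reads, index, max_mm = 6L, max_hits = 4L,
                             seed_step = NULL) {
  rc <- .read_chars(reads)
  if (is.null(seed_step)) seed_step <- index$k
  hits <- sb_map_end_to_end(unname(rc), index$ptr, as.integer(max_mm),
                            as.integer(max_hits), as.integer(seed_step))
  data.frame(read_id = names(rc)[hits$read], ref = index$names[hits$ref],
             pos = as.integer(hits$pos), strand = hits$strand,
             mm = hits$mm, nhits = hits$nhits, stringsAsFactors = FALSE)
}

#' Local alignment of reads against an index
#'
#' Seeded local Smith-Waterman. Only alignments with score strictly greater
#' than `Score_max / 3` (configurable fraction) are retained; multiple local
#' alignments per read are kept so SPLIT candidates can be formed.
#'
#' @param reads Named [Biostrings::DNAStringSet] or character vector.
#' @param index An [build_align_index()] result.
#' @param scoring An [align_scoring()] scheme.
#' @param min_score_frac Retained score fraction of `Score_max` (default 1/3).
#' @param max_hits Maximum placements per read (default 30).
#' @param seed_step Offset between seeds (default 6).
#' @return data.frame with `read_id`, `chrom`, `start`, `end`, `strand`,
#'   `q` (1-based start in the as-sequenced read), `l` (aligned read length),
#'   `score`, `nm` (edit distance), `nhits`.
#' @export
align_local <- function(reads, index, scoring = align_scoring(),
                        min_score_frac = 1 / 3, max_hits = 30L,
                        seed_step = 6L) {
  rc <- .read_chars(reads)
  if (!length(rc))
    return(data.frame(read_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), q = integer(0), l = integer(0),
                      score = integer(0), nm = integer(0), gaps = integer(0),
                      mmq = character(0), nhits = integer(0),
                      stringsAsFactors = FALSE))
  lens <- nchar(rc)
  out <- vector("list", 0)
  for (L in sort(unique(lens))) {
    sel <- which(lens == L)
    thr <- score_max(scoring, L) * min_score_frac
    hits <- sb_map_local(unname(rc[sel]), index$ptr, scoring$match,
                         scoring$mismatch, scoring$gap_open,
                         scoring$gap_extend, as.integer(floor(thr)),
                         as.integer(max_hits), as.integer(seed_step))
    if (!nrow(hits)) next
    hits <- hits[hits$score > thr, , drop = FALSE]
    if (!nrow(hits)) next
    out[[length(out) + 1L]] <- data.frame(
      read_id = names(rc)[sel][hits$read], chrom = index$names[hits$ref],
      start = as.integer(hits$pos), end = as.integer(hits$pos + hits$rlen - 1),
      strand = hits$strand, q = hits$q, l = hits$qlen,
      score = hits$score, nm = hits$nm, gaps = hits$gaps, mmq = hits$mmq,
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(align_local(character(0), index))
  res <- do.call(rbind, out)
  # multimap count: placements of the same read covering a similar read part
  res$nhits <- 1L
  for (rid in unique(res$read_id[duplicated(res$read_id)])) {
    sel <- which(res$read_id == rid)
    qs <- res$q[sel]; qe <- res$q[sel] + res$l[sel] - 1L
    n <- vapply(seq_along(sel), function(i) {
      ov <- pmin(qe, qe[i]) - pmax(qs, qs[i]) + 1L
      sum(ov >= 0.5 * res$l[sel][i])
    }, integer(1))
    res$nhits[sel] <- n
  }
  rownames(res) <- NULL
  res
}

#' Run end-to-end alignment of a read set (step 1)
#'
#' Maps reads to the transcriptome and, optionally, reads that failed to map
#' are mapped to the genome. Transcriptomic placements are converted to
#' genomic coordinates (outer span across exon junctions). Reads whose only
#' placements are on the mitochondrial chromosome are discarded from further
#' analysis by default. Every input read ends up either in `$alignments`, in
#' `$unmapped`, or in `$discarded` (mitochondrial).
#'
#' @param reads Named reads (one mate), [Biostrings::DNAStringSet] or
#'   character.
#' @param mate Mate label: 1, 2 or "unpaired".
#' @param tx_index Transcriptome [build_align_index()]; may be `NULL`.
#' @param genome_index Optional genome index for the genome pass.
#' @param db `TranscriptDB` used to project transcript placements.
#' @param max_mm,max_hits Passed to [align_end_to_end()].
#' @param discard_mito Drop mitochondrial alignments (default TRUE).
#' @param mito Chromosome names treated as mitochondrial.
#' @return list with `alignments` (read_id, mate, chrom, start, end, strand,
#'   mm, nhits, mapped_to, transcript_id, t_start, t_end), `unmapped`
#'   (read ids) and `discarded` (read ids).
#' @export
run_end_to_end <- function(reads, mate = 1L, tx_index = NULL,
                           genome_index = NULL, db = NULL,
                           max_mm = 6L, max_hits = 4L,
                           discard_mito = TRUE, mito = c("chrM", "MT")) {
  rc <- .read_chars(reads)
  ids <- names(rc)
  aln <- NULL
  if (!is.null(tx_index)) {
    th <- align_end_to_end(rc, tx_index, max_mm = max_mm, max_hits = max_hits)
    if (nrow(th)) {
      lens <- nchar(rc)[match(th$read_id, ids)]
      sp <- .project_spans(db, th$ref, th$pos, th$pos + lens - 1L)
      gstrand <- ifelse(th$strand == "+", sp$gstrand,
                        ifelse(sp$gstrand == "+", "-", "+"))
      aln <- data.frame(read_id = th$read_id, mate = mate, chrom = sp$chrom,
                        start = sp$gstart, end = sp$gend, strand = gstrand,
                        mm = th$mm, nhits = th$nhits,
                        mapped_to = "transcriptome", transcript_id = th$ref,
                        t_start = th$pos,
                        t_end = th$pos + lens - 1L, stringsAsFactors = FALSE)
    }
  }
  mapped <- unique(if (is.null(aln)) character(0) else aln$read_id)
  rest <- setdiff(ids, mapped)
  if (!is.null(genome_index) && length(rest)) {
    gh <- align_end_to_end(rc[rest], genome_index, max_mm = max_mm,
                           max_hits = max_hits)
    if (nrow(gh)) {
      lens <- nchar(rc)[match(gh$read_id, ids)]
      ga <- data.frame(read_id = gh$read_id, mate = mate, chrom = gh$ref,
                       start = gh$pos, end = gh$pos + lens - 1L,
                       strand = gh$strand, mm = gh$mm, nhits = gh$nhits,
                       mapped_to = "genome", transcript_id = NA_character_,
                       t_start = NA_integer_, t_end = NA_integer_,
                       stringsAsFactors = FALSE)
      aln <- rbind(aln, ga)
    }
  }
  mapped <- unique(if (is.null(aln)) character(0) else aln$read_id)
  unmapped <- setdiff(ids, mapped)
  discarded <- character(0)
  if (discard_mito && !is.null(aln) && nrow(aln)) {
    is_mito <- aln$chrom %in% mito
    mito_only <- setdiff(unique(aln$read_id[is_mito]),
                         unique(aln$read_id[!is_mito]))
    aln <- aln[!is_mito, , drop = FALSE]
    discarded <- mito_only
  }
  if (is.null(aln)) aln <- data.frame(
    read_id = character(0), mate = integer(0), chrom = character(0),
    start = integer(0), end = integer(0), strand = character(0),
    mm = integer(0), nhits = integer(0), mapped_to = character(0),
    transcript_id = character(0), t_start = integer(0), t_end = integer(0),
    stringsAsFactors = FALSE)
  list(alignments = aln, unmapped = unmapped, discarded = discarded)
}

#' Run local alignment of the unmapped reads (step 2)
#'
#' @param reads Full named read set (one mate).
#' @param unmapped Ids of reads that failed end-to-end alignment.
#' @param genome_index Genome [build_align_index()].
#' @param scoring,min_score_frac,max_hits,seed_step See [align_local()].
#' @return Local alignment data.frame (see [align_local()]).
#' @export
run_local <- function(reads, unmapped, genome_index,
                      scoring = align_scoring(), min_score_frac = 1 / 3,
                      max_hits = 30L, seed_step = 6L) {
  rc <- .read_chars(reads)
  align_local(rc[intersect(names(rc), unmapped)], genome_index,
              scoring = scoring, min_score_frac = min_score_frac,
              max_hits = max_hits, seed_step = seed_step)
}

#' Classify one aligned mate pair
#'
#' A pair is `proper` when both mates align to the same chromosome with a
#' genomic gap no larger than the maximum intron size, otherwise it is a
#' `bridge_candidate`. Symmetric in its arguments.
#'
#' @param a1,a2 Lists/rows with `chrom`, `start`, `end` (genomic, projected).
#' @param I_max Maximum intron size in bp (default 20000).
#' @return "proper" or "bridge_candidate".
#' @export
classify_pair <- function(a1, a2, I_max = 20000L) {
  if (a1$chrom != a2$chrom) return("bridge_candidate")
  gap <- max(a1$start, a2$start) - min(a1$end, a2$end) - 1L
  if (gap > I_max) "bridge_candidate" else "proper"
}

# Vectorized pair classification over an alignment table. A pair is proper
# if ANY combination of the two mates' placements is proper; only pairs with
# no proper combination become bridge candidates (for those the best-scoring
# combination is recorded).
.classify_pairs <- function(aln, I_max = 20000L) {
  if (!nrow(aln)) return(list(pairs = data.frame(), proper = data.frame()))
  a1 <- aln[aln$mate == 1L, , drop = FALSE]
  a2 <- aln[aln$mate == 2L, , drop = FALSE]
  both <- intersect(unique(a1$read_id), unique(a2$read_id))
  i1 <- split(seq_len(nrow(a1)), a1$read_id)
  i2 <- split(seq_len(nrow(a2)), a2$read_id)
  # fast path: both mates have a single placement
  single <- both[lengths(i1[both]) == 1L & lengths(i2[both]) == 1L]
  out_fast <- NULL
  if (length(single)) {
    j1 <- unlist(i1[single], use.names = FALSE)
    j2 <- unlist(i2[single], use.names = FALSE)
    same <- a1$chrom[j1] == a2$chrom[j2]
    gap <- pmax(a1$start[j1], a2$start[j2]) - pmin(a1$end[j1], a2$end[j2]) - 1L
    out_fast <- data.frame(read_id = single,
                           class = ifelse(same & gap <= I_max, "proper",
                                          "bridge_candidate"),
                           i1 = j1, i2 = j2, stringsAsFactors = FALSE)
    both <- setdiff(both, single)
  }
  pairs <- vector("list", length(both))
  for (i in seq_along(both)) {
    rid <- both[i]
    x <- a1[i1[[rid]], , drop = FALSE]
    y <- a2[i2[[rid]], , drop = FALSE]
    cmb <- expand.grid(i = seq_len(nrow(x)), j = seq_len(nrow(y)))
    same <- x$chrom[cmb$i] == y$chrom[cmb$j]
    gap <- pmax(x$start[cmb$i], y$start[cmb$j]) -
      pmin(x$end[cmb$i], y$end[cmb$j]) - 1L
    proper <- same & gap <= I_max
    if (any(proper)) {
      k <- which(proper)[1]
      pairs[[i]] <- data.frame(read_id = rid, class = "proper",
                               i1 = i1[[rid]][cmb$i[k]], i2 = i2[[rid]][cmb$j[k]],
                               stringsAsFactors = FALSE)
    } else {
      sc <- -(x$mm[cmb$i] + y$mm[cmb$j])
      k <- which.max(sc)
      pairs[[i]] <- data.frame(read_id = rid, class = "bridge_candidate",
                               i1 = i1[[rid]][cmb$i[k]], i2 = i2[[rid]][cmb$j[k]],
                               stringsAsFactors = FALSE)
    }
  }
  pairs <- rbind(out_fast, do.call(rbind, pairs))
  list(pairs = pairs, a1 = a1, a2 = a2)
}

#' Estimate the insert-size model from concordant pairs
#'
#' @param insert_sizes Numeric vector of outer-distance insert sizes from
#'   concordant (properly paired) alignments.
#' @return list of class `insert_model` with `mu`, `sigma`, `n`.
#' @export
estimate_insert_model <- function(insert_sizes) {
  insert_sizes <- insert_sizes[is.finite(insert_sizes)]
  if (length(insert_sizes) < 2)
    stop("insert-size model undefined: need at least 2 concordant pairs")
  structure(list(mu = mean(insert_sizes), sigma = stats::sd(insert_sizes),
                 n = length(insert_sizes)), class = "insert_model")
}

#' @export
print.insert_model <- function(x, ...) {
  cat(sprintf("insert model: mu = %.1f bp, sigma = %.1f bp (n = %d pairs)\n",
              x$mu, x$sigma, x$n))
  invisible(x)
}

# Outer-distance insert sizes, measured in transcript coordinates for pairs
# whose mates are concordant on the same transcript (splicing-free frame).
.insert_sizes_from_pairs <- function(cls) {
  if (is.null(cls$pairs) || !nrow(cls$pairs)) return(numeric(0))
  pp <- cls$pairs[cls$pairs$class == "proper", , drop = FALSE]
  if (!nrow(pp)) return(numeric(0))
  x <- cls$a1[pp$i1, , drop = FALSE]
  y <- cls$a2[pp$i2, , drop = FALSE]
  same_tx <- !is.na(x$transcript_id) & !is.na(y$transcript_id) &
    x$transcript_id == y$transcript_id
  pmax(x$t_end[same_tx], y$t_end[same_tx]) -
    pmin(x$t_start[same_tx], y$t_start[same_tx]) + 1L
}

#' Estimate per-gene expression as mean exonic coverage
#'
#' @param proper_alignments Alignment table (projected genomic spans) of
#'   properly paired or single-end mapped reads.
#' @param db `TranscriptDB`.
#' @return list with `genes` (data.frame gene_id, mean_coverage) and `cov`
#'   (per-chromosome coverage [IRanges::RleList]); class `expr_estimate`.
#' @export
estimate_expression <- function(proper_alignments, db) {
  chroms <- names(db$genome)
  lens <- setNames(Biostrings::width(db$genome), chroms)
  if (nrow(proper_alignments)) {
    gr <- GenomicRanges::GRanges(
      proper_alignments$chrom,
      IRanges::IRanges(proper_alignments$start, proper_alignments$end),
      seqlengths = lens)
    cov <- GenomicRanges::coverage(gr)
  } else {
    cov <- methods::as(setNames(lapply(lens, function(l) S4Vectors::Rle(0L, l)),
                                chroms), "SimpleRleList")
  }
  genes <- db$genes
  mean_cov <- vapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    ex <- db$exons[db$exons$gene_id == g$gene_id, , drop = FALSE]
    exr <- IRanges::reduce(IRanges::IRanges(ex$start, ex$end))
    v <- cov[[g$chrom]]
    tot <- sum(as.numeric(sum(IRanges::Views(v, exr))))
    tot / sum(IRanges::width(exr))
  }, numeric(1))
  structure(list(genes = data.frame(gene_id = genes$gene_id,
                                    mean_coverage = mean_cov,
                                    stringsAsFactors = FALSE),
                 cov = cov), class = "expr_estimate")
}
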