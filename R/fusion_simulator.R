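# Fusion simulation: synthetic reference generation, truth annotations for
# five fusion classes, chimeric transcript construction, Illumina-like
# paired-end read simulation with background expression, and scoring of
# predictions against the planted truth.
#
# Fusion classes:
#   1 - both breakpoints at exon boundaries
#   2 - breakpoint(s) inside an exon
#   3 - breakpoint(s) inside an intron (intron retention up to the junction)
#   4 - one partner from an intergenic region
#   5 - several alternatively spliced isoforms with exon-boundary junctions

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic repeat-free reference with multi-exon genes
#'
#' Random (uniform base composition) chromosomes with non-overlapping
#' multi-exon genes laid left to right; effectively repeat-free at seed
#' length for any realistic k.
#'
#' @param n_chrom Number of chromosomes (default 4).
#' @param chrom_len Length of each chromosome in bp (default 1.25e6; the
#'   defaults give a ~5 Mb genome).
#' @param genes_per_chrom Genes per chromosome (default 60).
#' @param seed Random seed (runs are reproducible).
#' @param exon_range,intron_range,n_exon_range,gap_range Structural ranges
#'   (bp / counts) for gene construction.
#' @param pseudogene_frac Fraction of genes labeled "processed_pseudogene"
#'   (default 0).
#' @return list of class `toy_reference`: `genome` (DNAStringSet), `exons`
#'   (annotation data.frame accepted by [load_annotation()]).
#' @export
simulate_toy_reference <- function(n_chrom = 4L, chrom_len = 1250000L,
                                   genes_per_chrom = 60L, seed = 1L,
                                   exon_range = c(80L, 400L),
                                   intron_range = c(200L, 1500L),
                                   n_exon_range = c(4L, 8L),
                                   gap_range = c(2000L, 12000L),
                                   pseudogene_frac = 0) {
  withr::with_seed(seed, {
    chroms <- setNames(
      vapply(seq_len(n_chrom), function(i) .rand_dna(chrom_len), ""),
      paste0("chr", seq_len(n_chrom)))
    exon_rows <- list()
    gid <- 0L
    for (ch in names(chroms)) {
      cursor <- sample(gap_range[1]:gap_range[2], 1L)
      for (g in seq_len(genes_per_chrom)) {
        n_ex <- sample(n_exon_range[1]:n_exon_range[2], 1L)
        ex_len <- sample(exon_range[1]:exon_range[2], n_ex, replace = TRUE)
        in_len <- if (n_ex > 1)
          sample(intron_range[1]:intron_range[2], n_ex - 1L, replace = TRUE)
          else integer(0)
        span <- sum(ex_len) + sum(in_len)
        if (cursor + span > chrom_len - gap_range[1]) break
        gid <- gid + 1L
        starts <- cursor + cumsum(c(0L, ex_len[-n_ex] + in_len))
        strand <- sample(c("+", "-"), 1L)
        biotype <- if (stats::runif(1) < pseudogene_frac)
          "processed_pseudogene" else "protein_coding"
        exon_rows[[length(exon_rows) + 1L]] <- data.frame(
          chrom = ch, start = starts, end = starts + ex_len - 1L,
          strand = strand, gene_id = sprintf("G%04d", gid),
          transcript_id = sprintf("T%04d", gid),
          gene_name = sprintf("GENE%04d", gid), biotype = biotype,
          stringsAsFactors = FALSE)
        cursor <- cursor + span + sample(gap_range[1]:gap_range[2], 1L)
      }
    }
    structure(list(genome = Biostrings::DNAStringSet(chroms),
                   exons = do.call(rbind, exon_rows)),
              class = "toy_reference")
  })
}

#' Write a toy reference to FASTA + GTF files
#'
#' @param ref [simulate_toy_reference()] result.
#' @param dir Output directory (created if needed).
#' @return list with `genome` and `gtf` paths.
#' @export
write_reference <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  gtf <- file.path(dir, "annotation.gtf")
  Biostrings::writeXStringSet(ref$genome, fa)
  ex <- ref$exons
  attrs <- sprintf(
    'gene_id "%s"; transcript_id "%s"; gene_name "%s"; gene_biotype "%s";',
    ex$gene_id, ex$transcript_id, ex$gene_name, ex$biotype)
  lines <- paste(ex$chrom, "toygen", "exon", ex$start, ex$end, ".",
                 ex$strand, ".", attrs, sep = "\t")
  writeLines(lines, gtf)
  list(genome = fa, gtf = gtf)
}

# ---- fusion truth construction ---------------------------------------------

# exon table of one transcript in transcript (5'->3') order
.tx_exons <- function(db, tid) {
  ex <- db$exons[db$exons$transcript_id == tid, , drop = FALSE]
  ex[order(ex$rank_tx), , drop = FALSE]
}

# A portion is a list(blocks = data.frame(start, end) in transcript order,
# chrom, strand, bp). For the 5' role bp is the LAST transcribed base; for
# the 3' role bp is the FIRST transcribed base.
.portion_5p_exon <- function(ex, k) {
  bl <- ex[seq_len(k), c("start", "end")]
  bp <- if (ex$strand[1] == "+") ex$end[k] else ex$start[k]
  list(blocks = bl, chrom = ex$chrom[1], strand = ex$strand[1], bp = bp)
}
.portion_3p_exon <- function(ex, m) {
  n <- nrow(ex)
  bl <- ex[m:n, c("start", "end")]
  bp <- if (ex$strand[1] == "+") ex$start[m] else ex$end[m]
  list(blocks = bl, chrom = ex$chrom[1], strand = ex$strand[1], bp = bp)
}
.portion_5p_in_exon <- function(ex, k, off) {
  bl <- if (k > 1) ex[seq_len(k - 1L), c("start", "end")]
        else ex[0, c("start", "end")]
  if (ex$strand[1] == "+") {
    bl <- rbind(bl, data.frame(start = ex$start[k],
                               end = ex$start[k] + off - 1L))
    bp <- ex$start[k] + off - 1L
  } else {
    bl <- rbind(bl, data.frame(start = ex$end[k] - off + 1L, end = ex$end[k]))
    bp <- ex$end[k] - off + 1L
  }
  list(blocks = bl, chrom = ex$chrom[1], strand = ex$strand[1], bp = bp)
}
.portion_3p_in_exon <- function(ex, m, off) {
  n <- nrow(ex)
  rest <- if (m < n) ex[(m + 1L):n, c("start", "end")]
          else ex[0, c("start", "end")]
  if (ex$strand[1] == "+") {
    first <- data.frame(start = ex$start[m] + off - 1L, end = ex$end[m])
    bp <- ex$start[m] + off - 1L
  } else {
    first <- data.frame(start = ex$start[m], end = ex$end[m] - off + 1L)
    bp <- ex$end[m] - off + 1L
  }
  list(blocks = rbind(first, rest), chrom = ex$chrom[1],
       strand = ex$strand[1], bp = bp)
}
.portion_5p_in_intron <- function(ex, k, off) {
  # retains the first `off` intronic bases after exon k (transcript order)
  bl <- ex[seq_len(k), c("start", "end")]
  if (ex$strand[1] == "+") {
    bl <- rbind(bl, data.frame(start = ex$end[k] + 1L,
                               end = ex$end[k] + off))
    bp <- ex$end[k] + off
  } else {
    bl <- rbind(bl, data.frame(start = ex$start[k] - off,
                               end = ex$start[k] - 1L))
    bp <- ex$start[k] - off
  }
  list(blocks = bl, chrom = ex$chrom[1], strand = ex$strand[1], bp = bp)
}
.portion_3p_in_intron <- function(ex, m, off) {
  # retains the last `off` intronic bases before exon m (transcript order)
  n <- nrow(ex)
  rest <- ex[m:n, c("start", "end")]
  if (ex$strand[1] == "+") {
    first <- data.frame(start = ex$start[m] - off, end = ex$start[m] - 1L)
    bp <- ex$start[m] - off
  } else {
    first <- data.frame(start = ex$end[m] + 1L, end = ex$end[m] + off)
    bp <- ex$end[m] + off
  }
  list(blocks = rbind(first, rest), chrom = ex$chrom[1],
       strand = ex$strand[1], bp = bp)
}
.intron_len <- function(ex, k) {
  # intron after exon k in transcript order
  if (ex$strand[1] == "+") ex$start[k + 1L] - ex$end[k] - 1L
  else ex$start[k] - ex$end[k + 1L] - 1L
}

# intergenic portion: a segment from a gap between gene spans
.portion_intergenic <- function(db, role, len, min_gap) {
  genes <- db$genes
  cand <- list()
  for (ch in unique(names(db$genome))) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    bounds <- cbind(c(1L, g$end + 1L),
                    c(g$start - 1L, Biostrings::width(db$genome)[
                      match(ch, names(db$genome))]))
    ok <- which(bounds[, 2] - bounds[, 1] + 1L >= min_gap + len)
    for (i in ok) cand[[length(cand) + 1L]] <-
      list(chrom = ch, lo = bounds[i, 1] + min_gap %/% 2,
           hi = bounds[i, 2] - min_gap %/% 2 - len)
  }
  if (!length(cand)) stop("no intergenic gap large enough for a segment of ",
                          len, " bp")
  pick <- cand[[sample.int(length(cand), 1L)]]
  s <- sample(pick$lo:pick$hi, 1L)
  strand <- sample(c("+", "-"), 1L)
  bl <- data.frame(start = s, end = s + len - 1L)
  bp <- if (role == "5p") {
    if (strand == "+") bl$end else bl$start
  } else {
    if (strand == "+") bl$start else bl$end
  }
  list(blocks = bl, chrom = pick$chrom, strand = strand, bp = bp)
}

#' Generate truth annotations for the five fusion classes
#'
#' Samples random multi-exon gene pairs without replacement, draws
#' breakpoints according to each class definition and assigns each fusion
#' transcript a coverage drawn uniformly from `coverage_range`. Runs are
#' deterministic under `seed`.
#'
#' @param db `TranscriptDB`.
#' @param n_per_class Fusion events per class (default 20, i.e. 100 events).
#' @param seed Random seed.
#' @param coverage_range Integer coverage range (default 1-60X).
#' @param intergenic_min_gap Minimum clearance of intergenic segments from
#'   annotated genes (default 1000 bp).
#' @param min_portion Minimum length of each fusion partner's transcribed
#'   portion (default 150 bp), so simulated chimeras have mappable flanks
#'   on both sides of the junction.
#' @return list of class `fusion_specs`: `specs` (one row per fusion
#'   isoform: fusion_id, isoform, class, coverage, partner genes, junction
#'   coordinates) and `portions` (genomic block lists used to build the
#'   transcripts).
#' @export
generate_fusion_annotations <- function(db, n_per_class = 20L, seed = NULL,
                                        coverage_range = c(1L, 60L),
                                        intergenic_min_gap = 1000L,
                                        min_portion = 150L) {
  run <- function() {
    tx <- db$transcripts[db$transcripts$n_exons >= 2L, , drop = FALSE]
    tx <- tx[!duplicated(tx$gene_id), , drop = FALSE]  # one isoform per gene
    need <- n_per_class * (2L + 2L + 2L + 1L + 2L)
    if (nrow(tx) < need)
      stop("annotation too small: ", need, " multi-exon genes needed, ",
           nrow(tx), " available (deficit ", need - nrow(tx), ")")
    pool <- sample(tx$transcript_id)
    take <- function(n) { out <- pool[seq_len(n)]; pool <<- pool[-seq_len(n)]; out }
    specs <- list(); portions <- list()
    fid <- 0L
    add <- function(class, iso, cov, p5, p3, g5, g3) {
      i <- length(specs) + 1L
      specs[[i]] <<- data.frame(
        fusion_id = sprintf("FUS%03d", fid), isoform = iso, class = class,
        coverage = cov, gene_5p = g5, gene_3p = g3,
        chrom_5p = p5$chrom, bp_5p = p5$bp, strand_5p = p5$strand,
        chrom_3p = p3$chrom, bp_3p = p3$bp, strand_3p = p3$strand,
        stringsAsFactors = FALSE)
      portions[[i]] <<- list(p5 = p5, p3 = p3)
    }
    cov_draw <- function() sample(coverage_range[1]:coverage_range[2], 1L)
    gene_of_tx <- function(tid) db$transcripts[tid, "gene_id"]
    plen <- function(p) sum(p$blocks$end - p$blocks$start + 1L)

    for (cls in 1:4) for (e in seq_len(n_per_class)) {
      fid <- fid + 1L
      if (cls == 4L) {
        tid <- take(1L)
        ex <- .tx_exons(db, tid)
        n <- nrow(ex)
        inter_is_5p <- sample(c(TRUE, FALSE), 1L)
        seg_len <- sample(300:800, 1L)
        pin <- .portion_intergenic(db, if (inter_is_5p) "5p" else "3p",
                                   seg_len, intergenic_min_gap)
        for (try in 1:60) {
          if (inter_is_5p) p3 <- .portion_3p_exon(ex, sample(2:n, 1L))
          else p5 <- .portion_5p_exon(ex, sample(seq_len(n - 1L), 1L))
          gp <- if (inter_is_5p) p3 else p5
          if (plen(gp) >= min_portion) break
        }
        if (inter_is_5p)
          add(4L, 1L, cov_draw(), pin, p3, "intergenic", gene_of_tx(tid))
        else add(4L, 1L, cov_draw(), p5, pin, gene_of_tx(tid), "intergenic")
        next
      }
      tids <- take(2L)
      ex5 <- .tx_exons(db, tids[1]); ex3 <- .tx_exons(db, tids[2])
      n5 <- nrow(ex5); n3 <- nrow(ex3)
      for (try in 1:60) {
        k <- sample(seq_len(n5 - 1L), 1L)
        m <- sample(2:n3, 1L)
        if (cls == 1L) {
          p5 <- .portion_5p_exon(ex5, k)
          p3 <- .portion_3p_exon(ex3, m)
        } else if (cls == 2L) {
          which_in <- sample(1:3, 1L)  # 1: 5p inside, 2: 3p inside, 3: both
          elen5 <- ex5$end[k] - ex5$start[k] + 1L
          elen3 <- ex3$end[m] - ex3$start[m] + 1L
          p5 <- if (which_in != 2L)
            .portion_5p_in_exon(ex5, k, sample(10:(elen5 - 10L), 1L))
            else .portion_5p_exon(ex5, k)
          p3 <- if (which_in != 1L)
            .portion_3p_in_exon(ex3, m, sample(10:(elen3 - 10L), 1L))
            else .portion_3p_exon(ex3, m)
        } else {
          which_in <- sample(1:3, 1L)
          il5 <- .intron_len(ex5, k)
          il3 <- .intron_len(ex3, m - 1L)
          p5 <- if (which_in != 2L)
            .portion_5p_in_intron(ex5, k, sample(10:(il5 - 10L), 1L))
            else .portion_5p_exon(ex5, k)
          p3 <- if (which_in != 1L)
            .portion_3p_in_intron(ex3, m, sample(10:(il3 - 10L), 1L))
            else .portion_3p_exon(ex3, m)
        }
        if (plen(p5) >= min_portion && plen(p3) >= min_portion) break
      }
      add(cls, 1L, cov_draw(), p5, p3, gene_of_tx(tids[1]), gene_of_tx(tids[2]))
    }
    # class 5: several isoforms with exon-boundary junctions
    for (e in seq_len(n_per_class)) {
      fid <- fid + 1L
      tids <- take(2L)
      ex5 <- .tx_exons(db, tids[1]); ex3 <- .tx_exons(db, tids[2])
      n5 <- nrow(ex5); n3 <- nrow(ex3)
      combos <- expand.grid(k = seq_len(n5 - 1L), m = 2:n3)
      ok <- vapply(seq_len(nrow(combos)), function(w)
        plen(.portion_5p_exon(ex5, combos$k[w])) >= min_portion &&
        plen(.portion_3p_exon(ex3, combos$m[w])) >= min_portion, TRUE)
      if (any(ok)) combos <- combos[ok, , drop = FALSE]
      n_iso <- min(sample(2:3, 1L), nrow(combos))
      pick <- combos[sample.int(nrow(combos), n_iso), , drop = FALSE]
      for (j in seq_len(n_iso))
        add(5L, j, cov_draw(), .portion_5p_exon(ex5, pick$k[j]),
            .portion_3p_exon(ex3, pick$m[j]),
            gene_of_tx(tids[1]), gene_of_tx(tids[2]))
    }
    specs <- do.call(rbind, specs)
    rownames(specs) <- NULL
    structure(list(specs = specs, portions = portions),
              class = "fusion_specs")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Build chimeric transcript sequences from fusion specs
#'
#' Splices the 5' portion and the 3' portion (reverse-complementing
#' minus-strand portions) and joins them at the junction. Sequence names
#' encode the truth: `fusion_id|isoform|class|coverage|junction_offset`.
#'
#' @param fspecs [generate_fusion_annotations()] result.
#' @param db `TranscriptDB`.
#' @return Named [Biostrings::DNAStringSet] of fusion transcripts.
#' @export
build_fusion_transcripts <- function(fspecs, db) {
  blocks_seq <- function(p) {
    parts <- lapply(seq_len(nrow(p$blocks)), function(i) {
      s <- Biostrings::subseq(db$genome[[p$chrom]], p$blocks$start[i],
                              p$blocks$end[i])
      if (p$strand == "-") s <- Biostrings::reverseComplement(s)
      as.character(s)
    })
    paste(unlist(parts), collapse = "")
  }
  sp <- fspecs$specs
  seqs <- character(nrow(sp))
  nm <- character(nrow(sp))
  for (i in seq_len(nrow(sp))) {
    s5 <- blocks_seq(fspecs$portions[[i]]$p5)
    s3 <- blocks_seq(fspecs$portions[[i]]$p3)
    seqs[i] <- paste0(s5, s3)
    nm[i] <- paste(sp$fusion_id[i], sp$isoform[i], sp$class[i],
                   sp$coverage[i], nchar(s5), sep = "|")
  }
  setNames(Biostrings::DNAStringSet(seqs), nm)
}

#' Read-simulation parameters
#'
#' @param read_len Read length (default 75 bp).
#' @param frag_mean,frag_sd Fragment length Normal(300, 80) by default.
#' @param sub_rate_5p,sub_rate_3p Per-base substitution rate, ramping
#'   linearly along the read (defaults 0.1% to 1%, Illumina-like).
#' @param ins_rate,del_rate Per-base indel rates (0.01% / 0.02%).
#' @param strandedness "none", "forward" (mate 1 is sense) or "reverse".
#' @return list of class `sim_read_params`.
#' @export
sim_read_params <- function(read_len = 75L, frag_mean = 300, frag_sd = 80,
                            sub_rate_5p = 0.001, sub_rate_3p = 0.01,
                            ins_rate = 1e-4, del_rate = 2e-4,
                            strandedness = c("none", "forward", "reverse")) {
  strandedness <- match.arg(strandedness)
  stopifnot(read_len >= 1, frag_mean >= read_len)
  structure(list(read_len = as.integer(read_len), frag_mean = frag_mean,
                 frag_sd = frag_sd, sub_rate_5p = sub_rate_5p,
                 sub_rate_3p = sub_rate_3p, ins_rate = ins_rate,
                 del_rate = del_rate, strandedness = strandedness),
            class = "sim_read_params")
}

.revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# simulate n read pairs from one transcript sequence (no error injection)
.sim_pairs_from_tx <- function(txchar, n, params, prefix) {
  rl <- params$read_len
  tlen <- nchar(txchar)
  if (n < 1L || tlen < rl) return(list(r1 = character(0), r2 = character(0)))
  flen <- pmin(pmax(round(stats::rnorm(n, params$frag_mean, params$frag_sd)),
                    rl), tlen)
  start <- floor(stats::runif(n, 1, tlen - flen + 1 + 1 - 1e-9))
  sense_read <- substring(txchar, start, start + rl - 1L)
  anti_read <- .revcomp_chr(substring(txchar, start + flen - rl,
                                      start + flen - 1L))
  first_sense <- switch(params$strandedness,
                        none = stats::runif(n) < 0.5,
                        forward = rep(TRUE, n),
                        reverse = rep(FALSE, n))
  r1 <- ifelse(first_sense, sense_read, anti_read)
  r2 <- ifelse(first_sense, anti_read, sense_read)
  ids <- paste0(prefix, ":", seq_len(n))
  list(r1 = setNames(r1, ids), r2 = setNames(r2, ids))
}

# inject substitution and indel errors (vectorized by read position)
.add_seq_errors <- function(reads, params) {
  n <- length(reads)
  if (!n) return(reads)
  rl <- nchar(reads[1])
  bases <- c("A", "C", "G", "T")
  rates <- params$sub_rate_5p +
    (params$sub_rate_3p - params$sub_rate_5p) *
    (seq_len(rl) - 1) / max(1L, rl - 1L)
  for (j in seq_len(rl)) {
    hit <- which(stats::runif(n) < rates[j])
    if (!length(hit)) next
    orig <- substr(reads[hit], j, j)
    repl <- sample(bases, length(hit), replace = TRUE)
    clash <- repl == orig
    while (any(clash)) {
      repl[clash] <- sample(bases, sum(clash), replace = TRUE)
      clash <- repl == orig
    }
    substr(reads[hit], j, j) <- repl
  }
  p_indel <- rl * (params$ins_rate + params$del_rate)
  sel <- which(stats::runif(n) < p_indel)
  for (i in sel) {
    pos <- sample(2:(rl - 1L), 1L)
    fill <- sample(bases, 1L)
    if (stats::runif(1) < params$ins_rate /
        (params$ins_rate + params$del_rate)) {
      reads[i] <- substr(paste0(substr(reads[i], 1, pos - 1L), fill,
                                substr(reads[i], pos, rl)), 1, rl)
    } else {
      reads[i] <- paste0(substr(reads[i], 1, pos - 1L),
                         substr(reads[i], pos + 1L, rl), fill)
    }
  }
  reads
}

#' Simulate paired-end reads from fusion transcripts
#'
#' The number of pairs per transcript is `round(coverage x length /
#' (2 x read_len))`; fragment lengths are Normal(`frag_mean`, `frag_sd`)
#' truncated to `[read_len, transcript length]`; substitution and indel
#' errors follow the Illumina-like model in `params`; mate orientation
#' follows the strandedness mode. Deterministic under `seed`.
#'
#' @param transcripts Named [Biostrings::DNAStringSet]
#'   ([build_fusion_transcripts()] output, or any named sequences).
#' @param params [sim_read_params()].
#' @param coverage Optional named coverage vector; by default parsed from
#'   the 4th `|`-field of the sequence names.
#' @param seed Random seed.
#' @return list with `read1`, `read2` (named character vectors; names are
#'   unique pair ids).
#' @export
simulate_reads <- function(transcripts, params = sim_read_params(),
                           coverage = NULL, seed = NULL) {
  run <- function() {
    txc <- as.character(transcripts)
    if (is.null(coverage)) {
      fields <- strsplit(names(txc), "|", fixed = TRUE)
      coverage <- vapply(fields, function(x)
        suppressWarnings(as.numeric(x[4])), numeric(1))
      coverage[is.na(coverage)] <- 10
    } else coverage <- coverage[names(txc)]
    r1 <- list(); r2 <- list()
    for (i in seq_along(txc)) {
      tlen <- nchar(txc[i])
      if (tlen < params$read_len) {
        warning("transcript ", names(txc)[i], " shorter than read length; ",
                "skipped")
        next
      }
      n <- round(coverage[i] * tlen / (2 * params$read_len))
      p <- .sim_pairs_from_tx(txc[i], n, params, names(txc)[i])
      r1[[i]] <- p$r1; r2[[i]] <- p$r2
    }
    r1 <- unlist(r1); r2 <- unlist(r2)
    if (is.null(r1)) r1 <- character(0)
    if (is.null(r2)) r2 <- character(0)
    list(read1 = .add_seq_errors(r1, params),
         read2 = .add_seq_errors(r2, params))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate background reads from the annotated transcriptome
#'
#' Reads are drawn from annotated (non-fusion) transcripts with abundance
#' proportional to an expression profile; the default synthetic profile is
#' log-normal(1, 1) per gene so no external data is required.
#'
#' @param db `TranscriptDB`.
#' @param n_pairs Total pair budget (default 25000).
#' @param params [sim_read_params()].
#' @param profile Optional named (gene_id) non-negative weight vector.
#' @param seed Random seed.
#' @return list with `read1`, `read2`.
#' @export
add_background_reads <- function(db, n_pairs = 25000L,
                                 params = sim_read_params(),
                                 profile = NULL, seed = NULL) {
  run <- function() {
    txs <- transcript_seqs(db)
    genes <- db$transcripts[names(txs), "gene_id"]
    if (is.null(profile)) {
      w <- stats::rlnorm(length(unique(genes)), 1, 1)
      names(w) <- unique(genes)
    } else w <- profile
    wt <- w[genes]
    wt[is.na(wt)] <- 0
    prob <- wt * Biostrings::width(txs)
    if (sum(prob) <= 0 || n_pairs < 1L)
      return(list(read1 = character(0), read2 = character(0)))
    counts <- as.vector(stats::rmultinom(1, n_pairs, prob))
    r1 <- list(); r2 <- list()
    txc <- as.character(txs)
    for (i in which(counts > 0)) {
      p <- .sim_pairs_from_tx(txc[i], counts[i], params,
                              paste0("bg|", names(txc)[i]))
      r1[[length(r1) + 1L]] <- p$r1; r2[[length(r2) + 1L]] <- p$r2
    }
    r1 <- unlist(r1); r2 <- unlist(r2)
    if (is.null(r1)) r1 <- character(0)
    if (is.null(r2)) r2 <- character(0)
    list(read1 = .add_seq_errors(r1, params),
         read2 = .add_seq_errors(r2, params))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Write reads as FASTQ
#'
#' @param reads Named character vector or DNAStringSet.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads)
  quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(x)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Read a FASTQ file as a named DNAStringSet
#' @param path FASTQ path.
#' @return Named [Biostrings::DNAStringSet].
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Simulate a complete fusion dataset
#'
#' Convenience wrapper reproducing the full study design for one dataset:
#' truth annotations (`n_per_class` per class), fusion transcripts, fusion
#' reads at the assigned coverages, plus background reads.
#'
#' @param db `TranscriptDB`.
#' @param n_per_class Fusions per class (default 20).
#' @param background_pairs Background pair budget (default 25000).
#' @param params [sim_read_params()].
#' @param seed Random seed (drives truth, fusion reads and background).
#' @return list with `read1`, `read2` (named character vectors), `truth`
#'   (spec data.frame), `specs` (full `fusion_specs`), `transcripts`.
#' @export
simulate_fusion_dataset <- function(db, n_per_class = 20L,
                                    background_pairs = 25000L,
                                    params = sim_read_params(),
                                    seed = 1L) {
  fs <- generate_fusion_annotations(db, n_per_class = n_per_class,
                                    seed = seed)
  ftx <- build_fusion_transcripts(fs, db)
  fr <- simulate_reads(ftx, params = params, seed = seed + 1000L)
  bg <- add_background_reads(db, n_pairs = background_pairs, params = params,
                             seed = seed + 2000L)
  list(read1 = c(fr$read1, bg$read1), read2 = c(fr$read2, bg$read2),
       truth = fs$specs, specs = fs, transcripts = ftx)
}

#' Score fusion predictions against the simulated truth
#'
#' A prediction is a true positive when, for each fusion partner, the
#' reported breakpoint lies within `tol` bp of the exact junction point
#' (partner order may be swapped). Each truth entry (class-5 isoforms count
#' separately) is matched at most once.
#'
#' @param truth Truth data.frame (`$truth` of [simulate_fusion_dataset()] or
#'   `$specs$specs`), or a path to a truth TSV.
#' @param predictions Report data.frame ([build_fusion_records()]) or path.
#' @param tol Breakpoint tolerance in bp (default 20).
#' @return list with `TP`, `FP`, `FN`, `recall`, `precision` (NA when there
#'   are no predictions), and `per_class` (class, n, detected, recall).
#' @export
evaluate_predictions <- function(truth, predictions, tol = 20L) {
  if (is.character(truth)) truth <- utils::read.delim(truth)
  if (is.character(predictions)) predictions <- read_fusion_report(predictions)
  n_t <- nrow(truth); n_p <- nrow(predictions)
  matched_t <- rep(FALSE, n_t)
  matched_p <- rep(FALSE, n_p)
  hit <- function(pc5, pb5, pc3, pb3, tc5, tb5, tc3, tb3)
    (pc5 == tc5 & abs(pb5 - tb5) <= tol & pc3 == tc3 & abs(pb3 - tb3) <= tol) |
    (pc5 == tc3 & abs(pb5 - tb3) <= tol & pc3 == tc5 & abs(pb3 - tb5) <= tol)
  if (n_p && n_t) for (p in seq_len(n_p)) {
    ok <- which(!matched_t &
                  hit(predictions$chrom_5p[p], predictions$bp_5p[p],
                      predictions$chrom_3p[p], predictions$bp_3p[p],
                      truth$chrom_5p, truth$bp_5p,
                      truth$chrom_3p, truth$bp_3p))
    if (length(ok)) {
      matched_t[ok[1]] <- TRUE
      matched_p[p] <- TRUE
    }
  }
  TP <- sum(matched_p); FP <- n_p - TP; FN <- n_t - sum(matched_t)
  per_class <- if (n_t && !is.null(truth$class)) {
    do.call(rbind, lapply(sort(unique(truth$class)), function(cl) {
      sel <- truth$class == cl
      data.frame(class = cl, n = sum(sel), detected = sum(matched_t[sel]),
                 recall = sum(matched_t[sel]) / sum(sel))
    }))
  } else NULL
  list(TP = TP, FP = FP, FN = FN,
       recall = if (n_t) sum(matched_t) / n_t else NA_real_,
       precision = if (n_p) TP / n_p else NA_real_,
       per_class = per_class)
}
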