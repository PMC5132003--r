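# SPLIT detection: pairs of local alignments of one read that flank a fusion
# junction. Two conditions qualify an ordered pair (first = lower read
# coordinate q):
#   1. the pair cannot be explained by a normal spliced alignment: different
#      chromosomes, or genomic separation beyond the maximum intron size, or
#      strand/order incompatible with splicing (inversions);
#   2. the pair is near-contiguous in read coordinates:
#      -T_inner <= g <= T_outer with g = q_second - (q_first + l_first),
#      i.e. up to T_inner bp of overlap (microhomology) and up to T_outer bp
#      of unaligned gap.

#' SPLIT detection parameters
#'
#' @param I_max Maximum intron size in bp (default 20000, human-genome
#'   scale).
#' @param T_inner Maximum read-coordinate intersection between the two local
#'   alignments (microhomology), default 10 bp.
#' @param T_outer Maximum read-coordinate distance between the two local
#'   alignments, default 2 bp.
#' @param max_configs Maximum SPLIT configurations formed from one read
#'   (default 20), highest combined alignment score first.
#' @return list of class `split_params`.
#' @export
split_params <- function(I_max = 20000L, T_inner = 10L, T_outer = 2L,
                         max_configs = 20L) {
  stopifnot(I_max >= 0, T_inner >= 0, T_outer >= 0, max_configs >= 0)
  structure(list(I_max = as.integer(I_max), T_inner = as.integer(T_inner),
                 T_outer = as.integer(T_outer),
                 max_configs = as.integer(max_configs)),
            class = "split_params")
}

# Genomic slack tolerated when deciding whether a same-chromosome pair is a
# plausible spliced alignment; fixed (independent of T_inner) so enlarging
# the read-coordinate thresholds can only add candidates.
.SPLICE_SLACK <- 5L

.splice_compatible <- function(x_chrom, x_start, x_end, x_strand,
                               y_chrom, y_start, y_end, y_strand, I_max) {
  same <- x_chrom == y_chrom & x_strand == y_strand
  gap_fwd <- y_start - x_end - 1L   # '+': read order follows genomic order
  gap_rev <- x_start - y_end - 1L   # '-': genomic order reversed
  gap <- ifelse(x_strand == "+", gap_fwd, gap_rev)
  same & gap >= -.SPLICE_SLACK & gap <= I_max
}

#' Form SPLIT candidates from the local alignments of one read
#'
#' Tests every ordered pair of local alignments (by read coordinate) against
#' the two SPLIT conditions and returns at most `max_configs` candidates,
#' ranked by combined alignment score, then fewest mismatches, then
#' lexicographic locus order.
#'
#' @param alns Local alignments of a single read ([align_local()] rows);
#'   all rows must share `read_id`.
#' @param params [split_params()].
#' @param scoring [align_scoring()]; used when an oversized read-coordinate
#'   overlap has to be trimmed (see Details).
#' @return data.frame of SPLIT candidates: `first_*`/`second_*` alignment
#'   fields, `g` (read-coordinate gap), combined `score`, `multi`, and the
#'   implied breakpoints `bp1_chrom`, `bp1_pos`, `bp1_side`, `bp2_chrom`,
#'   `bp2_pos`, `bp2_side` (sides name the genomic side of the alignments on
#'   which the breakpoint lies).
#' @details A local alignment can over-extend past a true junction when a
#' mismatch is recouped by downstream chance matches, inflating the
#' read-coordinate overlap beyond `T_inner`. A pair that satisfies
#' condition 1 but overlaps by more than `T_inner` is therefore re-tested
#' after trimming the overlap from the side whose trimmed alignment retains
#' the higher score; the trim is accepted only when the trimmed alignment
#' still scores above the local-alignment threshold. Trimmed candidates
#' have `g = 0` and breakpoints at the trimmed (clean) boundary.
#' @export
form_split_candidates <- function(alns, params = split_params(),
                                  scoring = align_scoring()) {
  if (nrow(alns) && length(unique(alns$read_id)) != 1L)
    stop("form_split_candidates expects the alignments of one read")
  .form_splits_one(alns, params, scoring)
}

.empty_splits <- function() {
  cols <- c("read_id", "mate", "g", "score",
            paste0("first_", c("chrom", "start", "end", "strand", "q", "l",
                               "score", "nm", "nhits")),
            paste0("second_", c("chrom", "start", "end", "strand", "q", "l",
                                "score", "nm", "nhits")),
            "bp1_chrom", "bp1_pos", "bp1_side",
            "bp2_chrom", "bp2_pos", "bp2_side", "multi")
  df <- as.data.frame(setNames(rep(list(vector("integer", 0)), length(cols)),
                               cols))
  for (ch in c("read_id", "first_chrom", "first_strand", "second_chrom",
               "second_strand", "bp1_chrom", "bp1_side", "bp2_chrom",
               "bp2_side")) df[[ch]] <- character(0)
  df$multi <- logical(0)
  df
}

.form_splits_one <- function(a, params, scoring = align_scoring(),
                             allow_trim = TRUE) {
  n <- nrow(a)
  if (n < 2L) return(.empty_splits())
  ij <- expand.grid(i = seq_len(n), j = seq_len(n))
  ij <- ij[a$q[ij$i] < a$q[ij$j], , drop = FALSE]
  if (!nrow(ij)) return(.empty_splits())
  i <- ij$i; j <- ij$j
  g <- a$q[j] - (a$q[i] + a$l[i])
  cond2 <- g >= -params$T_inner & g <= params$T_outer
  cond1 <- !.splice_compatible(a$chrom[i], a$start[i], a$end[i], a$strand[i],
                               a$chrom[j], a$start[j], a$end[j], a$strand[j],
                               params$I_max)
  extra <- NULL
  trimmed_ok <- logical(length(i))
  if (allow_trim) {
    # any read-coordinate overlap is trimmed back to the boundary that
    # maximizes reference identity (ties toward the donor side); pairs whose
    # overlap exceeds T_inner are only kept in trimmed form
    trim_idx <- which(cond1 & g < 0L)
    if (length(trim_idx)) {
      L_est <- max(a$q + a$l) - 1L
      thr <- scoring$match * L_est / 3
      parts <- lapply(trim_idx, function(w) {
        tmp <- .trim_pair_rows(a, i[w], j[w], g[w], thr, scoring)
        if (is.null(tmp)) return(NULL)
        .form_splits_one(tmp, params, scoring, allow_trim = FALSE)
      })
      ok <- !vapply(parts, is.null, TRUE)
      trimmed_ok[trim_idx[ok]] <- TRUE
      parts <- parts[ok]
      if (length(parts)) extra <- do.call(rbind, parts)
    }
  }
  keep <- which(cond1 & cond2 & !trimmed_ok)
  if (!length(keep) && is.null(extra)) return(.empty_splits())
  out <- NULL
  if (length(keep)) {
    i <- i[keep]; j <- j[keep]; g <- g[keep]
    d <- pmax(0L, -g)  # overlap assigned to the donor side
    bp1_side <- ifelse(a$strand[i] == "+", "right", "left")
    bp1_pos <- ifelse(a$strand[i] == "+", a$end[i], a$start[i])
    bp2_side <- ifelse(a$strand[j] == "+", "left", "right")
    bp2_pos <- ifelse(a$strand[j] == "+", a$start[j] + d, a$end[j] - d)
    out <- data.frame(
      read_id = a$read_id[i],
      mate = if (is.null(a$mate)) NA_integer_ else a$mate[i],
      g = g, score = a$score[i] + a$score[j],
      first_chrom = a$chrom[i], first_start = a$start[i], first_end = a$end[i],
      first_strand = a$strand[i], first_q = a$q[i], first_l = a$l[i],
      first_score = a$score[i], first_nm = a$nm[i], first_nhits = a$nhits[i],
      second_chrom = a$chrom[j], second_start = a$start[j],
      second_end = a$end[j], second_strand = a$strand[j], second_q = a$q[j],
      second_l = a$l[j], second_score = a$score[j], second_nm = a$nm[j],
      second_nhits = a$nhits[j],
      bp1_chrom = a$chrom[i], bp1_pos = as.integer(bp1_pos), bp1_side = bp1_side,
      bp2_chrom = a$chrom[j], bp2_pos = as.integer(bp2_pos), bp2_side = bp2_side,
      multi = a$nhits[i] > 1L | a$nhits[j] > 1L,
      stringsAsFactors = FALSE)
  }
  out <- rbind(out, extra)
  if (is.null(out) || !nrow(out)) return(.empty_splits())
  ord <- order(-out$score, out$first_nm + out$second_nm, out$first_chrom,
               out$first_start, out$second_chrom, out$second_start)
  out <- out[ord, , drop = FALSE]
  out <- utils::head(out, params$max_configs)
  rownames(out) <- NULL
  out
}

# Trim an oversized read-coordinate overlap between alignments i (first) and
# j (second) of one read. Returns a 2-row alignment frame with the overlap
# removed from the side whose trimmed alignment keeps the higher score, or
# NULL when neither trimmed alignment clears the score threshold. Exact
# score recomputation uses the reported mismatch positions and is only
# attempted for gap-free alignments.
.trim_pair_rows <- function(a, i, j, g, thr, scoring) {
  t <- -g
  mm_of <- function(k) {
    if (is.null(a$mmq) || is.na(a$mmq[k]) || !nzchar(a$mmq[k])) integer(0)
    else as.integer(strsplit(a$mmq[k], ",", fixed = TRUE)[[1]])
  }
  gap_of <- function(k) if (is.null(a$gaps)) 0L else a$gaps[k]
  ma <- scoring$match; mi <- scoring$mismatch
  optA <- optB <- NULL
  if (gap_of(i) == 0L && a$l[i] - t >= 1L) {
    cols <- (a$q[i] + a$l[i] - t):(a$q[i] + a$l[i] - 1L)
    x <- sum(mm_of(i) %in% cols)
    nsc <- a$score[i] - (ma * (t - x) + mi * x)
    if (nsc > thr) optA <- list(score = nsc, x = x)
  }
  if (gap_of(j) == 0L && a$l[j] - t >= 1L) {
    cols <- a$q[j]:(a$q[j] + t - 1L)
    x <- sum(mm_of(j) %in% cols)
    nsc <- a$score[j] - (ma * (t - x) + mi * x)
    if (nsc > thr) optB <- list(score = nsc, x = x)
  }
  if (is.null(optA) && is.null(optB)) return(NULL)
  # prefer trimming the second (acceptor-side) alignment on ties so that
  # genuine microhomology stays assigned to the donor side
  use_first <- !is.null(optA) &&
    (is.null(optB) || optA$score > optB$score)
  tmp <- a[c(i, j), , drop = FALSE]
  if (use_first) {
    tmp$l[1] <- tmp$l[1] - t
    if (tmp$strand[1] == "+") tmp$end[1] <- tmp$end[1] - t
    else tmp$start[1] <- tmp$start[1] + t
    tmp$score[1] <- optA$score
    tmp$nm[1] <- tmp$nm[1] - optA$x
  } else {
    tmp$q[2] <- tmp$q[2] + t
    tmp$l[2] <- tmp$l[2] - t
    if (tmp$strand[2] == "+") tmp$start[2] <- tmp$start[2] + t
    else tmp$end[2] <- tmp$end[2] - t
    tmp$score[2] <- optB$score
    tmp$nm[2] <- tmp$nm[2] - optB$x
  }
  tmp
}

# All reads at once (grouped by read_id).
.form_splits_all <- function(locals, params = split_params(),
                             scoring = align_scoring()) {
  if (!nrow(locals)) return(.empty_splits())
  multi <- names(which(table(locals$read_id) >= 2L))
  if (!length(multi)) return(.empty_splits())
  locals <- locals[locals$read_id %in% multi, , drop = FALSE]
  parts <- lapply(split(seq_len(nrow(locals)), locals$read_id), function(idx)
    .form_splits_one(locals[idx, , drop = FALSE], params, scoring))
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Breakpoints implied by a SPLIT candidate
#'
#' The donor breakpoint is the genomic coordinate of the last read base of
#' the first (lower-q) alignment; the acceptor breakpoint is the coordinate
#' of the first read base following it in the second alignment. When the two
#' alignments overlap in read coordinates (microhomology), the overlap is
#' assigned to the donor side, deterministically. `side` names the genomic
#' end of the supporting alignments at which the breakpoint sits: a cluster
#' with side `right` extends 5'-to-3' toward the breakpoint on the forward
#' genomic axis.
#'
#' @param sc One row of [form_split_candidates()] output.
#' @return data.frame with two rows (`chrom`, `pos`, `side`): donor then
#'   acceptor.
#' @export
implied_breakpoint <- function(sc) {
  stopifnot(nrow(sc) == 1L)
  data.frame(chrom = c(sc$bp1_chrom, sc$bp2_chrom),
             pos = c(sc$bp1_pos, sc$bp2_pos),
             side = c(sc$bp1_side, sc$bp2_side),
             stringsAsFactors = FALSE)
}
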