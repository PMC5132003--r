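# Refinement and filtering of putative fusions: mate-pair consistency for
# SPLIT support, absorption of bridge-only events, multimap resolution, the
# filter feature set (metacluster homogeneity, coverage statistics, junction
# homology, insert validity, strand concordance, biotype control) and the
# final thresholded verdict.

.mate_id <- function(read_id) {
  ifelse(grepl("/1$", read_id), sub("/1$", "/2", read_id),
         ifelse(grepl("/2$", read_id), sub("/2$", "/1", read_id),
                NA_character_))
}

# recompute support counts; drop fusions left without support
.recount <- function(fus) {
  if (!nrow(fus$fusions)) return(fus)
  ns <- table(fus$support$fusion_id[fus$support$type == "split"])
  nb <- table(fus$support$fusion_id[fus$support$type == "bridge"])
  fus$fusions$n_split <- as.integer(ns[fus$fusions$fusion_id])
  fus$fusions$n_bridge <- as.integer(nb[fus$fusions$fusion_id])
  fus$fusions$n_split[is.na(fus$fusions$n_split)] <- 0L
  fus$fusions$n_bridge[is.na(fus$fusions$n_bridge)] <- 0L
  keep <- fus$fusions$n_split + fus$fusions$n_bridge > 0L
  fus$fusions <- fus$fusions[keep, , drop = FALSE]
  fus$support <- fus$support[fus$support$fusion_id %in%
                               fus$fusions$fusion_id, , drop = FALSE]
  fus
}

#' Filter thresholds
#'
#' Default thresholds aim at a compromise between recall and precision; all
#' are configurable and re-filtering on saved features does not require
#' re-running the pipeline.
#'
#' @param min_support Minimum supporting reads (SPLIT + BRIDGE), default 2.
#' @param min_homogeneity Minimum metacluster homogeneity weight (0.25).
#' @param min_unique_split_fraction Minimum fraction of distinct SPLIT
#'   genomic footprints (0.05).
#' @param max_breakpoint_offset_dev Maximum deviation of the mean in-read
#'   breakpoint position from the read middle, as a fraction of read length
#'   (0.25).
#' @param max_homology_score Maximum normalized contiguous-reference
#'   alignment score of the junction sequence (0.8); higher means the
#'   "fusion" sequence exists contiguously in the reference.
#' @param min_valid_insert_ratio Minimum fraction of BRIDGE inserts inside
#'   the 3-sigma interval (0.5); only applied when BRIDGE support exists.
#' @param min_strand_concordance Minimum strand consistency for stranded
#'   protocols (0.8): the dominant orientation fraction, so consistently
#'   antisense fusions are flagged, not filtered.
#' @param drop_biotypes Biotype substrings whose exclusive presence on a
#'   partner discards the fusion (pseudogene, processed_transcript).
#' @param allow_biotype_override Keep fusions failing the biotype rule
#'   (default FALSE).
#' @param allow_intergenic Report fusions with an unannotated partner
#'   (default TRUE).
#' @param weights Fusion-score weights: unique SPLIT with consistent mate,
#'   unique SPLIT without mate information, multimapped SPLIT, BRIDGE.
#' @return list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_support = 2L,
                              min_homogeneity = 0.25,
                              min_unique_split_fraction = 0.05,
                              max_breakpoint_offset_dev = 0.25,
                              max_homology_score = 0.8,
                              min_valid_insert_ratio = 0.5,
                              min_strand_concordance = 0.8,
                              drop_biotypes = c("pseudogene",
                                                "processed_transcript"),
                              allow_biotype_override = FALSE,
                              allow_intergenic = TRUE,
                              weights = c(split_mated = 3, split = 2,
                                          split_multi = 1, bridge = 1)) {
  structure(as.list(environment()), class = "filter_thresholds")
}

#' Discard SPLIT support without a consistent mate pair
#'
#' For paired-end data, a SPLIT read whose mate maps farther than the
#' maximum intron size from both fusion partner breakpoints is removed from
#' the fusion's support. Mates without any alignment carry no information
#' and are kept (`mate_ok = NA`). A no-op for single-end data.
#'
#' @param fus `sb_fusions`.
#' @param alignments End-to-end alignment table ([run_end_to_end()]
#'   `$alignments`, both mates combined).
#' @param I_max Maximum intron size (bp).
#' @param paired Set `FALSE` for single-end libraries (identity).
#' @return Updated `sb_fusions`; support gains a `mate_ok` column.
#' @export
enforce_split_mate_consistency <- function(fus, alignments, I_max = 20000L,
                                           paired = TRUE) {
  if (!nrow(fus$fusions)) return(fus)
  fus$support$mate_ok <- NA
  if (!paired) return(fus)
  sup <- fus$support
  is_split <- sup$type == "split"
  mid <- .mate_id(sup$read_id)
  fx <- fus$fusions[match(sup$fusion_id, fus$fusions$fusion_id), ]
  aln_by_read <- split(seq_len(nrow(alignments)), alignments$read_id)
  drop <- logical(nrow(sup))
  for (i in which(is_split & !is.na(mid))) {
    rows <- aln_by_read[[mid[i]]]
    if (is.null(rows)) next  # unmapped mate: no information
    a <- alignments[rows, , drop = FALSE]
    ok <- (a$chrom == fx$chrom_5p[i] &
             pmax(a$start - fx$bp_5p[i], fx$bp_5p[i] - a$end, 0L) <= I_max) |
          (a$chrom == fx$chrom_3p[i] &
             pmax(a$start - fx$bp_3p[i], fx$bp_3p[i] - a$end, 0L) <= I_max)
    if (any(ok)) fus$support$mate_ok[i] <- TRUE else drop[i] <- TRUE
  }
  fus$support <- fus$support[!drop, , drop = FALSE]
  .recount(fus)
}

#' Merge bridge-only fusions into nearby SPLIT-supported events
#'
#' A fusion supported only by BRIDGE pairs whose two partners both lie
#' within the maximum intron size of a SPLIT-supported fusion's partners
#' (with matching directionality) is absorbed into it, so one event is not
#' reported twice. Support counts add.
#'
#' @param fus `sb_fusions`.
#' @param I_max Maximum intron size (bp).
#' @return Updated `sb_fusions`.
#' @export
merge_bridge_only_fusions <- function(fus, I_max = 20000L) {
  f <- fus$fusions
  if (!nrow(f)) return(fus)
  bo <- which(f$n_split == 0L)
  tg <- which(f$n_split > 0L)
  if (!length(bo) || !length(tg)) return(fus)
  near <- function(c1, p1, s1, c2, p2, s2)
    c1 == c2 & s1 == s2 & abs(p1 - p2) <= I_max
  for (i in bo) {
    straight <- near(f$chrom_5p[i], f$bp_5p[i], f$side_5p[i],
                     f$chrom_5p[tg], f$bp_5p[tg], f$side_5p[tg]) &
                near(f$chrom_3p[i], f$bp_3p[i], f$side_3p[i],
                     f$chrom_3p[tg], f$bp_3p[tg], f$side_3p[tg])
    crossed <- near(f$chrom_5p[i], f$bp_5p[i], f$side_5p[i],
                    f$chrom_3p[tg], f$bp_3p[tg], f$side_3p[tg]) &
               near(f$chrom_3p[i], f$bp_3p[i], f$side_3p[i],
                    f$chrom_5p[tg], f$bp_5p[tg], f$side_5p[tg])
    hit <- tg[straight | crossed]
    if (!length(hit)) next
    dist <- abs(f$bp_5p[i] - f$bp_5p[hit]) + abs(f$bp_3p[i] - f$bp_3p[hit])
    target <- hit[which.min(dist)]
    fus$support$fusion_id[fus$support$fusion_id == f$fusion_id[i]] <-
      f$fusion_id[target]
    fus$fusions <- fus$fusions[fus$fusions$fusion_id != f$fusion_id[i], ,
                               drop = FALSE]
  }
  .recount(fus)
}

#' Fusion score
#'
#' Weighted sum over supporting reads: unique SPLIT with a consistent mate
#' pair scores 3, unique SPLIT without mate information 2, multimapped
#' SPLIT 1, BRIDGE 1 (weights configurable).
#'
#' @param support Support rows of one fusion (`sb_fusions$support` subset).
#' @param weights Named weights (see [filter_thresholds()]).
#' @return Numeric score.
#' @export
fusion_score <- function(support, weights = c(split_mated = 3, split = 2,
                                              split_multi = 1, bridge = 1)) {
  if (!nrow(support)) return(0)
  mate_ok <- if (is.null(support$mate_ok)) rep(NA, nrow(support))
             else support$mate_ok
  w <- ifelse(support$type == "bridge", weights[["bridge"]],
              ifelse(support$multi, weights[["split_multi"]],
                     ifelse(!is.na(mate_ok) & mate_ok,
                            weights[["split_mated"]], weights[["split"]])))
  sum(w)
}

.fusion_scores <- function(fus, weights) {
  vapply(fus$fusions$fusion_id, function(fid)
    fusion_score(fus$support[fus$support$fusion_id == fid, , drop = FALSE],
                 weights), numeric(1))
}

#' Resolve multimapped reads across fusions
#'
#' Iteratively assigns each read supporting several putative fusions to the
#' fusion with the largest score, recomputing scores until assignments
#' stabilize (ties go to the lexicographically smallest fusion id). After
#' resolution every read supports exactly one fusion.
#'
#' @param fus `sb_fusions`.
#' @param weights Fusion-score weights.
#' @param max_iter Iteration cap (default 50); exceeded assignments are
#'   frozen with a warning.
#' @return Updated `sb_fusions`.
#' @export
resolve_multimapped <- function(fus, weights = c(split_mated = 3, split = 2,
                                                 split_multi = 1, bridge = 1),
                                max_iter = 50L) {
  if (!nrow(fus$fusions)) return(fus)
  # one support per read within a fusion (best-scoring configuration)
  sup <- fus$support
  ord <- order(sup$fusion_id, sup$read_id, -sup$score_bpc)
  sup <- sup[ord, , drop = FALSE]
  sup <- sup[!duplicated(sup[c("fusion_id", "read_id")]), , drop = FALSE]
  fus$support <- sup
  fus <- .recount(fus)
  for (it in seq_len(max_iter)) {
    sup <- fus$support
    dup_reads <- unique(sup$read_id[duplicated(sup$read_id)])
    if (!length(dup_reads)) return(fus)
    scores <- .fusion_scores(fus, weights)
    names(scores) <- fus$fusions$fusion_id
    drop <- logical(nrow(sup))
    for (rid in dup_reads) {
      rows <- which(sup$read_id == rid)
      sc <- scores[sup$fusion_id[rows]]
      best <- rows[order(-sc, sup$fusion_id[rows])][1]
      drop[setdiff(rows, best)] <- TRUE
    }
    if (!any(drop)) return(fus)
    fus$support <- sup[!drop, , drop = FALSE]
    fus <- .recount(fus)
  }
  warning("multimap resolution did not stabilize within ", max_iter,
          " iterations; assignments frozen")
  fus
}

#' Metacluster homogeneity
#'
#' Fusions whose cluster blocks intersect or lie within `gap` bp of each
#' other form a metacluster. Each fusion side's weight is its share of the
#' supporting alignments in the metacluster; the fusion's homogeneity
#' weight is the minimum over its two sides. False positives arising from
#' local sequence homology typically carry low weight.
#'
#' @param fus `sb_fusions`.
#' @param gap Metacluster grouping distance (default 1000 bp).
#' @return `sb_fusions` with a `homogeneity_weight` column on `$fusions`.
#' @export
compute_homogeneity <- function(fus, gap = 1000L) {
  f <- fus$fusions
  if (!nrow(f)) return(fus)
  n_sup <- f$n_split + f$n_bridge
  cl <- fus$clusters
  side_df <- rbind(
    data.frame(fusion = f$fusion_id, cluster = f$cluster_5p, n = n_sup),
    data.frame(fusion = f$fusion_id, cluster = f$cluster_3p, n = n_sup))
  ci <- match(side_df$cluster, cl$cluster)
  gr <- GenomicRanges::GRanges(cl$chrom[ci],
                               IRanges::IRanges(cl$start[ci], cl$end[ci]))
  red <- GenomicRanges::reduce(gr, min.gapwidth = gap + 1L)
  mc <- S4Vectors::subjectHits(GenomicRanges::findOverlaps(gr, red,
                                                           maxgap = gap))
  # each side competes with the alignments of OTHER fusions sharing its
  # metacluster; a fusion's own opposite side is not competition
  w <- vapply(seq_len(nrow(side_df)), function(i) {
    same_mc <- mc == mc[i]
    other <- sum(side_df$n[same_mc & side_df$fusion != side_df$fusion[i]])
    side_df$n[i] / (side_df$n[i] + other)
  }, numeric(1))
  hw <- tapply(w, side_df$fusion, min)
  fus$fusions$homogeneity_weight <- as.numeric(hw[f$fusion_id])
  fus
}

#' Coverage features of the supporting reads
#'
#' Computes, per fusion: the fraction of distinct SPLIT genomic footprints
#' (`unique_split_fraction`), the deviation of the mean in-read breakpoint
#' position from the read middle as a fraction of read length
#' (`breakpoint_offset_dev`), whether at least one SPLIT support has no
#' multimappings (`has_unique_split`), and the mean properly-aligned read
#' depth in windows flanking each breakpoint (`flank_cov_5p`/`flank_cov_3p`,
#' advisory) when an expression estimate is supplied.
#'
#' @param fus `sb_fusions`.
#' @param read_len Read length in bp.
#' @param expr Optional [estimate_expression()] result.
#' @param flank_w Flank window width (default 100 bp).
#' @return `sb_fusions` with feature columns added to `$fusions`.
#' @export
compute_coverage_features <- function(fus, read_len, expr = NULL,
                                      flank_w = 100L) {
  f <- fus$fusions
  if (!nrow(f)) return(fus)
  usf <- bod <- rep(NA_real_, nrow(f))
  hus <- rep(NA, nrow(f))
  fc5 <- fc3 <- rep(NA_real_, nrow(f))
  for (i in seq_len(nrow(f))) {
    s <- fus$support[fus$support$fusion_id == f$fusion_id[i] &
                       fus$support$type == "split", , drop = FALSE]
    if (nrow(s)) {
      fp <- paste(s$start_r1, s$end_r1, s$start_r2, s$end_r2)
      usf[i] <- length(unique(fp)) / nrow(s)
      qj <- s$q_r1 + s$l_r1 - 1L
      qj <- qj[!is.na(qj)]
      if (length(qj)) bod[i] <- abs(mean(qj) - read_len / 2) / read_len
      hus[i] <- any(!s$multi)
    }
    if (!is.null(expr)) {
      win_mean <- function(chrom, bp, side) {
        v <- expr$cov[[chrom]]
        if (is.null(v)) return(NA_real_)
        if (side == "right") { a <- max(1L, bp - flank_w + 1L); b <- bp }
        else { a <- bp; b <- min(length(v), bp + flank_w - 1L) }
        if (b < a) return(NA_real_)
        mean(as.numeric(S4Vectors::window(v, a, b)))
      }
      fc5[i] <- win_mean(f$chrom_5p[i], f$bp_5p[i], f$side_5p[i])
      fc3[i] <- win_mean(f$chrom_3p[i], f$bp_3p[i], f$side_3p[i])
    }
  }
  fus$fusions$unique_split_fraction <- usf
  fus$fusions$breakpoint_offset_dev <- bod
  fus$fusions$has_unique_split <- hus
  fus$fusions$flank_cov_5p <- fc5
  fus$fusions$flank_cov_3p <- fc3
  fus
}

#' Junction homology score
#'
#' Reconstructs the fusion sequence bounded by the read evidence and
#' locally aligns it back to the reference (genome and transcriptome). The
#' score of the best single contiguous alignment, normalized by the
#' sequence's maximum score, is close to 1 when the putative junction
#' sequence exists contiguously in the reference (a homology artifact) and
#' close to 0.5 for a genuine junction of unrelated sequences.
#'
#' @param fus `sb_fusions`.
#' @param db `TranscriptDB`.
#' @param indexes list of [build_align_index()] objects to search (genome
#'   and, optionally, transcriptome).
#' @param scoring [align_scoring()].
#' @param max_flank Cap on the evidence flank per side (default 150 bp).
#' @return `sb_fusions` with a `homology_score` column.
#' @export
compute_homology_score <- function(fus, db, indexes,
                                   scoring = align_scoring(),
                                   max_flank = 150L) {
  f <- fus$fusions
  if (!nrow(f)) return(fus)
  if (!is.list(indexes) || inherits(indexes, "sb_index"))
    indexes <- list(indexes)
  hs <- rep(NA_real_, nrow(f))
  cl <- fus$clusters
  for (i in seq_len(nrow(f))) {
    ev5 <- with(cl[cl$cluster == f$cluster_5p[i], ], end - start + 1L)
    ev3 <- with(cl[cl$cluster == f$cluster_3p[i], ], end - start + 1L)
    flank <- max(30L, min(max_flank, ev5, ev3))
    seq <- tryCatch(reconstruct_junction_sequence(f[i, ], db, flank = flank),
                    error = function(e) NULL)
    if (is.null(seq)) next
    len <- nchar(seq$sequence)
    best <- 0
    for (ix in indexes) {
      h <- align_local(setNames(seq$sequence, "junction"), ix,
                       scoring = scoring, min_score_frac = 0.2,
                       max_hits = 5L)
      if (nrow(h)) best <- max(best, max(h$score))
    }
    hs[i] <- best / score_max(scoring, len)
  }
  fus$fusions$homology_score <- hs
  fus
}

#' BRIDGE insert-size validity
#'
#' Measures each supporting BRIDGE pair's insert across the reconstructed
#' fusion (mate-to-breakpoint distances on each side, projected through the
#' annotated transcript where one contains both mate and breakpoint, so
#' spliced-out introns do not inflate the insert). An insert is valid when
#' it lies within 3 sigma of the insert-size model; the fraction of valid
#' inserts is the feature. Fusions without BRIDGE support get ratio 1.
#'
#' @param fus `sb_fusions`.
#' @param insert_model [estimate_insert_model()] result.
#' @param db `TranscriptDB`.
#' @return `sb_fusions` with a `valid_insert_ratio` column.
#' @export
compute_insert_validity <- function(fus, insert_model, db) {
  f <- fus$fusions
  if (!nrow(f)) return(fus)
  lo <- insert_model$mu - 3 * insert_model$sigma
  hi <- insert_model$mu + 3 * insert_model$sigma
  vir <- rep(1, nrow(f))
  tx_by_gene <- split(db$transcripts$transcript_id, db$transcripts$gene_id)
  side_dist <- function(chrom, bp, side, start, end, genes) {
    outer <- if (side == "right") start else end
    gd <- if (side == "right") bp - start + 1L else end - bp + 1L
    for (g in genes) for (tid in tx_by_gene[[g]]) {
      t1 <- .genomic_to_transcript(db, tid, bp)
      t2 <- .genomic_to_transcript(db, tid, outer)
      if (!is.na(t1) && !is.na(t2)) return(abs(t1 - t2) + 1L)
    }
    gd
  }
  for (i in seq_len(nrow(f))) {
    s <- fus$support[fus$support$fusion_id == f$fusion_id[i] &
                       fus$support$type == "bridge", , drop = FALSE]
    if (!nrow(s)) next
    g5 <- strsplit(f$gene_5p[i], ",")[[1]]
    g3 <- strsplit(f$gene_3p[i], ",")[[1]]
    ins <- vapply(seq_len(nrow(s)), function(j) {
      on5 <- s$cluster_r1[j] == f$cluster_5p[i]
      d5 <- side_dist(f$chrom_5p[i], f$bp_5p[i], f$side_5p[i],
                      if (on5) s$start_r1[j] else s$start_r2[j],
                      if (on5) s$end_r1[j] else s$end_r2[j], g5)
      d3 <- side_dist(f$chrom_3p[i], f$bp_3p[i], f$side_3p[i],
                      if (on5) s$start_r2[j] else s$start_r1[j],
                      if (on5) s$end_r2[j] else s$end_r1[j], g3)
      d5 + d3
    }, numeric(1))
    vir[i] <- mean(ins >= lo & ins <= hi)
  }
  fus$fusions$valid_insert_ratio <- vir
  fus
}

#' Strand concordance and antisense flags
#'
#' For strand-specific protocols, the fraction of supporting read parts
#' aligned according to the protocol and the annotated gene strand is
#' computed per partner. A partner whose supports are predominantly in the
#' opposite orientation is flagged antisense. Inert (ratio 1, no flags) for
#' unstranded data or unannotated partners.
#'
#' @param fus `sb_fusions`.
#' @param protocol "none", "forward" or "reverse".
#' @return `sb_fusions` with `strand_concordance_5p/_3p`, `antisense_5p/_3p`
#'   and `strand_consistency` (dominant orientation fraction, minimum over
#'   partners) columns.
#' @export
compute_strand_concordance <- function(fus, protocol = c("none", "forward",
                                                         "reverse")) {
  protocol <- match.arg(protocol)
  f <- fus$fusions
  if (!nrow(f)) return(fus)
  n <- nrow(f)
  c5 <- c3 <- rep(NA_real_, n)
  a5 <- a3 <- rep(FALSE, n)
  cons <- rep(1, n)
  if (protocol != "none") {
    flip <- function(s) ifelse(s == "+", "-", "+")
    for (i in seq_len(n)) {
      s <- fus$support[fus$support$fusion_id == f$fusion_id[i], , drop = FALSE]
      side_conc <- function(side_cluster, gene_strand) {
        if (is.na(gene_strand)) return(NA_real_)
        on1 <- s$cluster_r1 == side_cluster
        obs <- ifelse(on1, s$strand_r1, s$strand_r2)
        mate <- ifelse(s$type == "bridge", ifelse(on1, 1L, 2L),
                       ifelse(is.na(s$mate), 1L, s$mate))
        expected <- ifelse((mate == 1L) == (protocol == "forward"),
                           gene_strand, flip(gene_strand))
        mean(obs == expected)
      }
      c5[i] <- side_conc(f$cluster_5p[i], f$gene_strand_5p[i])
      c3[i] <- side_conc(f$cluster_3p[i], f$gene_strand_3p[i])
      a5[i] <- !is.na(c5[i]) && c5[i] < 0.5
      a3[i] <- !is.na(c3[i]) && c3[i] < 0.5
      dom <- function(x) if (is.na(x)) NA_real_ else max(x, 1 - x)
      cons[i] <- min(dom(c5[i]), dom(c3[i]), 1, na.rm = TRUE)
    }
  }
  fus$fusions$strand_concordance_5p <- c5
  fus$fusions$strand_concordance_3p <- c3
  fus$fusions$antisense_5p <- a5
  fus$fusions$antisense_3p <- a3
  fus$fusions$strand_consistency <- cons
  fus
}

#' Apply the final filter thresholds
#'
#' Every violated threshold is recorded; a fusion passes when no reason
#' remains. The verdict can be recomputed on a saved feature table with
#' adjusted thresholds without re-running the pipeline.
#'
#' @param fus `sb_fusions` with features computed.
#' @param thresholds [filter_thresholds()].
#' @param db `TranscriptDB` (biotype lookup).
#' @param stranded Whether a strand-specific protocol was used.
#' @return `sb_fusions` with `pass` and `fail_reasons` columns.
#' @export
apply_filters <- function(fus, thresholds = filter_thresholds(), db = NULL,
                          stranded = FALSE) {
  f <- fus$fusions
  if (!nrow(f)) return(fus)
  th <- thresholds
  reasons <- vector("list", nrow(f))
  add <- function(i, r) reasons[[i]] <<- c(reasons[[i]], r)
  col <- function(name) if (name %in% names(f)) f[[name]] else rep(NA, nrow(f))
  hw <- col("homogeneity_weight"); usf <- col("unique_split_fraction")
  bod <- col("breakpoint_offset_dev"); hus <- col("has_unique_split")
  hom <- col("homology_score"); vir <- col("valid_insert_ratio")
  sc <- col("strand_consistency")
  biotypes_of <- function(genes) {
    g <- strsplit(genes, ",")[[1]]
    g <- g[nzchar(g)]
    if (!length(g) || is.null(db)) return(character(0))
    db$genes[g, "biotype"]
  }
  for (i in seq_len(nrow(f))) {
    if (f$n_split[i] + f$n_bridge[i] < th$min_support) add(i, "min_support")
    if (!is.na(hw[i]) && hw[i] < th$min_homogeneity) add(i, "min_homogeneity")
    if (f$n_split[i] > 0) {
      if (!is.na(usf[i]) && usf[i] < th$min_unique_split_fraction)
        add(i, "min_unique_split_fraction")
      if (!is.na(bod[i]) && bod[i] > th$max_breakpoint_offset_dev)
        add(i, "max_breakpoint_offset_dev")
      if (f$n_bridge[i] == 0 && !is.na(hus[i]) && !hus[i])
        add(i, "has_unique_split")
    }
    if (!is.na(hom[i]) && hom[i] > th$max_homology_score)
      add(i, "max_homology_score")
    if (f$n_bridge[i] > 0 && !is.na(vir[i]) &&
        vir[i] < th$min_valid_insert_ratio)
      add(i, "min_valid_insert_ratio")
    if (stranded && !is.na(sc[i]) && sc[i] < th$min_strand_concordance)
      add(i, "min_strand_concordance")
    if (!th$allow_biotype_override) {
      drop_bt <- function(b) length(b) > 0 &&
        all(vapply(b, function(x) any(vapply(th$drop_biotypes, grepl, TRUE,
                                             x = x)), TRUE))
      if (drop_bt(biotypes_of(f$gene_5p[i])) ||
          drop_bt(biotypes_of(f$gene_3p[i]))) add(i, "biotype")
    }
    if (!th$allow_intergenic &&
        (!nzchar(f$gene_5p[i]) || !nzchar(f$gene_3p[i])))
      add(i, "intergenic")
  }
  fus$fusions$pass <- lengths(reasons) == 0L
  fus$fusions$fail_reasons <- vapply(reasons, paste, "", collapse = ",")
  fus
}

#' Merge duplicate fusions with sub-resolvable breakpoints
#'
#' Junction-flanking sequence homology can yield two self-consistent
#' breakpoint conventions for one event (reads in the two orientations
#' assign the homologous block to opposite sides), separated by more than
#' the clustering tolerance. Fusions whose two breakpoints both lie within
#' `radius` bp of another fusion's (same directionality, either partner
#' order) are treated as one event: support is pooled into the fusion with
#' the most SPLIT evidence (ties: most total support, then smallest id),
#' whose breakpoint pair is kept.
#'
#' @param fus `sb_fusions`.
#' @param radius Duplicate radius in bp (default 20, twice the clustering
#'   tolerance).
#' @return Updated `sb_fusions`.
#' @export
merge_duplicate_fusions <- function(fus, radius = 20L) {
  f <- fus$fusions
  if (nrow(f) < 2L) return(fus)
  ord <- order(-f$n_split, -(f$n_split + f$n_bridge), f$fusion_id)
  f <- f[ord, , drop = FALSE]
  absorbed <- character(0)
  for (i in seq_len(nrow(f) - 1L)) {
    if (f$fusion_id[i] %in% absorbed) next
    for (j in (i + 1L):nrow(f)) {
      if (f$fusion_id[j] %in% absorbed) next
      straight <- f$chrom_5p[i] == f$chrom_5p[j] &&
        f$side_5p[i] == f$side_5p[j] &&
        abs(f$bp_5p[i] - f$bp_5p[j]) <= radius &&
        f$chrom_3p[i] == f$chrom_3p[j] &&
        f$side_3p[i] == f$side_3p[j] &&
        abs(f$bp_3p[i] - f$bp_3p[j]) <= radius
      crossed <- f$chrom_5p[i] == f$chrom_3p[j] &&
        f$side_5p[i] == f$side_3p[j] &&
        abs(f$bp_5p[i] - f$bp_3p[j]) <= radius &&
        f$chrom_3p[i] == f$chrom_5p[j] &&
        f$side_3p[i] == f$side_5p[j] &&
        abs(f$bp_3p[i] - f$bp_5p[j]) <= radius
      if (straight || crossed) {
        fus$support$fusion_id[fus$support$fusion_id == f$fusion_id[j]] <-
          f$fusion_id[i]
        absorbed <- c(absorbed, f$fusion_id[j])
      }
    }
  }
  if (length(absorbed))
    fus$fusions <- fus$fusions[!(fus$fusions$fusion_id %in% absorbed), ,
                               drop = FALSE]
  .recount(fus)
}
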