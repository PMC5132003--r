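# Clustering of breakpoint-candidate (BPC) alignments. A BPC is a SPLIT read
# (two local alignments of one read) or a BRIDGE pair (two discordant
# end-to-end mate alignments). Each BPC contributes two genomic alignments;
# clustering groups alignments by interval intersection, then separates
# clusters by directionality (which genomic side of the alignments the
# breakpoint lies on) and by breakpoint-position compatibility, and finally
# BPCs are aggregated into putative fusions keyed by their cluster pair.
#
# Direction table (alignment strand x BPC role -> breakpoint side):
#   SPLIT first segment  '+' -> right   SPLIT first segment  '-' -> left
#   SPLIT second segment '+' -> left    SPLIT second segment '-' -> right
#   BRIDGE mate          '+' -> right   BRIDGE mate          '-' -> left
# ("right" = the breakpoint sits at the high-coordinate end of the
# supporting alignments; reads approach it 5'-to-3' on the forward axis.)

# Build the BPC alignment table from SPLIT candidates and bridge pairs.
# splits: .form_splits_all() output; bridges: data.frame with mate1/mate2
# alignment fields (chrom1, start1, end1, strand1, nhits1, ... and 2).
.bpc_table <- function(splits = NULL, bridges = NULL) {
  rows <- list()
  if (!is.null(splits) && nrow(splits)) {
    n <- nrow(splits)
    id <- paste0("s", seq_len(n))
    rows$s1 <- data.frame(
      bpc_id = id, bpc_type = "split", read_id = splits$read_id,
      mate = splits$mate, role = 1L,
      chrom = splits$first_chrom, start = splits$first_start,
      end = splits$first_end, strand = splits$first_strand,
      side = splits$bp1_side, bp = splits$bp1_pos,
      q = splits$first_q, l = splits$first_l,
      score = splits$first_score, nm = splits$first_nm,
      nhits = splits$first_nhits, multi = splits$multi,
      stringsAsFactors = FALSE)
    rows$s2 <- data.frame(
      bpc_id = id, bpc_type = "split", read_id = splits$read_id,
      mate = splits$mate, role = 2L,
      chrom = splits$second_chrom, start = splits$second_start,
      end = splits$second_end, strand = splits$second_strand,
      side = splits$bp2_side, bp = splits$bp2_pos,
      q = splits$second_q, l = splits$second_l,
      score = splits$second_score, nm = splits$second_nm,
      nhits = splits$second_nhits, multi = splits$multi,
      stringsAsFactors = FALSE)
  }
  if (!is.null(bridges) && nrow(bridges)) {
    n <- nrow(bridges)
    id <- paste0("b", seq_len(n))
    multi <- bridges$nhits1 > 1L | bridges$nhits2 > 1L
    mk <- function(role) data.frame(
      bpc_id = id, bpc_type = "bridge", read_id = bridges$read_id,
      mate = role, role = role,
      chrom = bridges[[paste0("chrom", role)]],
      start = bridges[[paste0("start", role)]],
      end = bridges[[paste0("end", role)]],
      strand = bridges[[paste0("strand", role)]],
      side = ifelse(bridges[[paste0("strand", role)]] == "+", "right", "left"),
      bp = NA_integer_, q = NA_integer_, l = NA_integer_,
      score = 0L, nm = bridges[[paste0("mm", role)]],
      nhits = bridges[[paste0("nhits", role)]], multi = multi,
      stringsAsFactors = FALSE)
    rows$b1 <- mk(1L)
    rows$b2 <- mk(2L)
  }
  if (!length(rows))
    return(data.frame(bpc_id = character(0), bpc_type = character(0),
                      read_id = character(0), mate = integer(0),
                      role = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), side = character(0),
                      bp = integer(0), q = integer(0), l = integer(0),
                      score = integer(0), nm = integer(0),
                      nhits = integer(0), multi = logical(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cluster BPC alignments by genomic intersection
#'
#' Iterative insertion: an alignment with no intersection starts a new
#' cluster; intersecting one cluster joins it; intersecting several merges
#' them first. The final clustering is independent of insertion order (it
#' equals the connected components of the interval-overlap graph) and no two
#' cluster spans intersect.
#'
#' @param bpcs BPC alignment data.frame (columns `chrom`, `start`, `end`
#'   at minimum).
#' @return The input with a `cluster` column added.
#' @export
build_clusters <- function(bpcs) {
  n <- nrow(bpcs)
  if (!n) {
    bpcs$cluster <- integer(0)
    return(bpcs)
  }
  bpcs$cluster <- NA_integer_
  nextid <- 1L
  for (ch in unique(bpcs$chrom)) {
    idx <- which(bpcs$chrom == ch)
    cid <- integer(0); cs <- integer(0); ce <- integer(0)
    assign <- integer(length(idx))
    for (t in seq_along(idx)) {
      s <- bpcs$start[idx[t]]; e <- bpcs$end[idx[t]]
      ov <- which(cs <= e & ce >= s)
      if (length(ov) == 0L) {
        cid <- c(cid, nextid); cs <- c(cs, s); ce <- c(ce, e)
        assign[t] <- nextid
        nextid <- nextid + 1L
      } else if (length(ov) == 1L) {
        cs[ov] <- min(cs[ov], s); ce[ov] <- max(ce[ov], e)
        assign[t] <- cid[ov]
      } else {
        keep <- ov[1L]
        news <- min(cs[ov], s); newe <- max(ce[ov], e)
        assign[assign %in% cid[ov[-1L]]] <- cid[keep]
        cs[keep] <- news; ce[keep] <- newe
        assign[t] <- cid[keep]
        cid <- cid[-ov[-1L]]; cs <- cs[-ov[-1L]]; ce <- ce[-ov[-1L]]
      }
    }
    bpcs$cluster[idx] <- assign
  }
  bpcs$cluster <- as.integer(factor(bpcs$cluster))
  bpcs
}

#' Separate clusters by directionality
#'
#' Partitions each cluster's members by the direction to the breakpoint
#' (`side`), inferred from alignment strand and the alignment's role inside
#' its BPC (read-coordinate order for SPLITs, mate identifier for BRIDGEs);
#' see the direction table in the package source.
#'
#' @param bpcs Clustered BPC table ([build_clusters()] output; needs a
#'   `side` column).
#' @return The table with `cluster` renumbered so that every cluster is
#'   direction-homogeneous.
#' @export
split_by_directionality <- function(bpcs) {
  if (!nrow(bpcs)) return(bpcs)
  bpcs$cluster <- as.integer(factor(paste(bpcs$cluster, bpcs$side)))
  bpcs
}

#' Separate clusters by breakpoint position
#'
#' Within each direction-homogeneous cluster, SPLIT-implied breakpoint
#' positions are grouped by single-linkage with chain-breaking: positions
#' are sorted and a new group starts whenever the gap to the previous
#' position exceeds `tol`. BRIDGE-only members attach to the compatible
#' group nearest their junction-side edge; members compatible with no group
#' stay together as a bridge-only cluster.
#'
#' @param bpcs Direction-homogeneous BPC table.
#' @param tol Breakpoint compatibility tolerance in bp (default 10).
#' @param bridge_tol Maximum distance from a bridge alignment's junction-side
#'   edge to a breakpoint it can support; use `mu + 3 sigma` of the insert
#'   model when available (default 1000).
#' @return The table with `cluster` renumbered so that SPLIT breakpoints
#'   within a cluster differ by at most `tol`.
#' @export
split_by_breakpoint <- function(bpcs, tol = 10L, bridge_tol = 1000L) {
  if (!nrow(bpcs)) return(bpcs)
  sub <- rep(1L, nrow(bpcs))
  for (cl in unique(bpcs$cluster)) {
    idx <- which(bpcs$cluster == cl)
    has_bp <- !is.na(bpcs$bp[idx])
    if (!any(has_bp)) next
    pos <- sort(unique(bpcs$bp[idx][has_bp]))
    grp_of_pos <- cumsum(c(1L, diff(pos) > tol))
    names(grp_of_pos) <- as.character(pos)
    g <- integer(length(idx))
    g[has_bp] <- grp_of_pos[as.character(bpcs$bp[idx][has_bp])]
    if (any(!has_bp)) {
      # consensus breakpoint per group: most supported position, tie -> lowest
      cons <- vapply(split(bpcs$bp[idx][has_bp], g[has_bp]), function(v) {
        tab <- table(v)
        as.integer(names(tab)[which.max(tab)])
      }, integer(1))
      side <- bpcs$side[idx][1]
      nb <- which(!has_bp)
      edge <- if (side == "right") bpcs$end[idx][nb] else bpcs$start[idx][nb]
      orphan <- max(g) + 1L
      for (w in seq_along(nb)) {
        d <- if (side == "right") cons - edge[w] else edge[w] - cons
        okg <- which(d >= -5L & d <= bridge_tol)
        g[nb[w]] <- if (length(okg)) {
          as.integer(names(cons)[okg][which.min(abs(d[okg]))])
        } else orphan
      }
    }
    sub[idx] <- g
  }
  bpcs$cluster <- as.integer(factor(paste(bpcs$cluster, sub)))
  bpcs
}

# Per-cluster summary: span, side, consensus breakpoint (majority SPLIT
# position; bridge-only clusters get their junction-side span edge and are
# flagged approximate).
.summarize_clusters <- function(bpcs) {
  if (!nrow(bpcs))
    return(data.frame(cluster = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      side = character(0), n = integer(0), bp = integer(0),
                      approx = logical(0), stringsAsFactors = FALSE))
  parts <- lapply(split(seq_len(nrow(bpcs)), bpcs$cluster), function(idx) {
    b <- bpcs[idx, , drop = FALSE]
    has_bp <- !is.na(b$bp)
    if (any(has_bp)) {
      tab <- table(b$bp[has_bp])
      bp <- as.integer(names(tab)[which.max(tab)])
      approx <- FALSE
    } else {
      bp <- if (b$side[1] == "right") max(b$end) else min(b$start)
      approx <- TRUE
    }
    data.frame(cluster = b$cluster[1], chrom = b$chrom[1],
               start = min(b$start), end = max(b$end), side = b$side[1],
               n = nrow(b), bp = bp, approx = approx, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

# Full clustering stack: intersection clustering, directionality separation,
# breakpoint separation.
.cluster_bpcs <- function(bpcs, tol = 10L, bridge_tol = 1000L) {
  bpcs <- build_clusters(bpcs)
  bpcs <- split_by_directionality(bpcs)
  bpcs <- split_by_breakpoint(bpcs, tol = tol, bridge_tol = bridge_tol)
  list(members = bpcs, clusters = .summarize_clusters(bpcs))
}

#' Assemble putative fusions from clustered BPCs
#'
#' Each BPC maps to the pair of clusters holding its two alignments; BPCs
#' whose alignments fall into a single cluster are degenerate and dropped
#' (recorded in the `dropped` element). The 5'/3' order of the partners is
#' fixed by library strand-specificity when available, else by the annotated
#' gene strand at the breakpoints, with genomic order as the deterministic
#' fallback.
#'
#' @param members Clustered BPC table (`$members` of the clustering stack).
#' @param clusters Cluster summary (`$clusters`).
#' @param db `TranscriptDB` (used for the annotation-based ordering rule).
#' @param strandedness One of "none", "forward", "reverse".
#' @return list of class `sb_fusions`: `fusions` data.frame (one row per
#'   putative fusion: clusters, breakpoints, support counts, ordering
#'   provenance), `support` data.frame (one row per supporting BPC),
#'   `members`, `clusters`, `strandedness`, `dropped`.
#' @export
form_putative_fusions <- function(members, clusters, db,
                                  strandedness = c("none", "forward",
                                                   "reverse")) {
  strandedness <- match.arg(strandedness)
  empty <- function(dropped = character(0)) structure(list(
    fusions = data.frame(), support = data.frame(), members = members,
    clusters = clusters, strandedness = strandedness,
    dropped = dropped), class = "sb_fusions")
  if (!nrow(members)) return(empty())
  r1 <- members[members$role == 1L, , drop = FALSE]
  r2 <- members[members$role == 2L, , drop = FALSE]
  m <- match(r1$bpc_id, r2$bpc_id)
  r2 <- r2[m, , drop = FALSE]
  ok <- !is.na(m) & r1$cluster != r2$cluster
  dropped <- r1$bpc_id[!ok]
  if (!any(ok)) return(empty(dropped))
  r1 <- r1[ok, , drop = FALSE]; r2 <- r2[ok, , drop = FALSE]
  ca <- pmin(r1$cluster, r2$cluster)
  cb <- pmax(r1$cluster, r2$cluster)
  support <- data.frame(
    fusion_id = paste0("F", ca, "_", cb), bpc_id = r1$bpc_id,
    type = r1$bpc_type, read_id = r1$read_id, mate = r1$mate,
    multi = r1$multi,
    cluster_r1 = r1$cluster, cluster_r2 = r2$cluster,
    strand_r1 = r1$strand, strand_r2 = r2$strand,
    bp_r1 = r1$bp, bp_r2 = r2$bp,
    start_r1 = r1$start, end_r1 = r1$end,
    start_r2 = r2$start, end_r2 = r2$end,
    q_r1 = r1$q, l_r1 = r1$l, q_r2 = r2$q, l_r2 = r2$l,
    score_bpc = r1$score + r2$score,
    rescued = FALSE, stringsAsFactors = FALSE)
  rownames(support) <- NULL

  ann_cache <- new.env()
  gene_at <- function(chrom, pos) {
    key <- paste0(chrom, ":", pos)
    if (!is.null(ann_cache[[key]])) return(ann_cache[[key]])
    a <- annotate_position(chrom, pos, db)
    gs <- if (length(a$gene_ids)) db$genes[a$gene_ids[1], "strand"]
          else NA_character_
    v <- list(gene_ids = a$gene_ids, strand = gs)
    ann_cache[[key]] <- v
    v
  }

  fus_rows <- list()
  for (fid in unique(support$fusion_id)) {
    s <- support[support$fusion_id == fid, , drop = FALSE]
    ca <- min(s$cluster_r1[1], s$cluster_r2[1])
    cb <- max(s$cluster_r1[1], s$cluster_r2[1])
    cA <- clusters[clusters$cluster == ca, ]
    cB <- clusters[clusters$cluster == cb, ]
    # 5'/3' assignment
    five <- NA_integer_; how <- "positional"
    if (strandedness != "none") {
      # vote: the cluster holding the protocol-sense part is the 5' side
      votes <- integer(0)
      for (r in seq_len(nrow(s))) {
        if (s$type[r] == "split") {
          mate <- if (is.na(s$mate[r])) 1L else s$mate[r]
          sense <- (mate == 1L) == (strandedness == "forward")
          votes <- c(votes, if (sense) s$cluster_r1[r] else s$cluster_r2[r])
        } else {
          sense_mate <- if (strandedness == "forward") 1L else 2L
          votes <- c(votes, if (s$mate[r] == sense_mate) s$cluster_r1[r]
                            else s$cluster_r2[r])
        }
      }
      tab <- table(votes)
      if (length(tab) && max(tab) > sum(tab) / 2) {
        five <- as.integer(names(tab)[which.max(tab)])
        how <- "protocol"
      }
    }
    gA <- gene_at(cA$chrom, cA$bp)
    gB <- gene_at(cB$chrom, cB$bp)
    if (is.na(five)) {
      donorA <- !is.na(gA$strand) &&
        ((cA$side == "right" & gA$strand == "+") |
         (cA$side == "left" & gA$strand == "-"))
      donorB <- !is.na(gB$strand) &&
        ((cB$side == "right" & gB$strand == "+") |
         (cB$side == "left" & gB$strand == "-"))
      if (isTRUE(donorA) && !isTRUE(donorB)) {
        five <- ca; how <- "annotation"
      } else if (isTRUE(donorB) && !isTRUE(donorA)) {
        five <- cb; how <- "annotation"
      } else {
        ord <- order(c(cA$chrom, cB$chrom), c(cA$bp, cB$bp))
        five <- c(ca, cb)[ord[1]]
        how <- "positional"
      }
    }
    three <- if (five == ca) cb else ca
    c5 <- clusters[clusters$cluster == five, ]
    c3 <- clusters[clusters$cluster == three, ]
    g5 <- if (five == ca) gA else gB
    g3 <- if (five == ca) gB else gA
    fus_rows[[fid]] <- data.frame(
      fusion_id = fid, cluster_5p = five, cluster_3p = three,
      chrom_5p = c5$chrom, bp_5p = c5$bp, side_5p = c5$side,
      approx_5p = c5$approx,
      chrom_3p = c3$chrom, bp_3p = c3$bp, side_3p = c3$side,
      approx_3p = c3$approx,
      gene_5p = paste(g5$gene_ids, collapse = ","),
      gene_3p = paste(g3$gene_ids, collapse = ","),
      gene_strand_5p = if (is.na(g5$strand)) NA_character_ else g5$strand,
      gene_strand_3p = if (is.na(g3$strand)) NA_character_ else g3$strand,
      n_split = sum(s$type == "split"), n_bridge = sum(s$type == "bridge"),
      order_by = how, stringsAsFactors = FALSE)
  }
  fusions <- do.call(rbind, fus_rows)
  rownames(fusions) <- NULL
  structure(list(fusions = fusions, support = support, members = members,
                 clusters = clusters, strandedness = strandedness,
                 dropped = dropped), class = "sb_fusions")
}

#' @export
print.sb_fusions <- function(x, ...) {
  cat("sb_fusions:", nrow(x$fusions), "putative fusions,",
      nrow(x$support), "supporting BPCs,", nrow(x$clusters), "clusters\n")
  invisible(x)
}

#' Rescue unused local alignments into existing fusions
#'
#' Local alignments that did not form a SPLIT (typically because the second
#' read part was too short to pass the local-score threshold) are revisited:
#' an alignment with score above half the read's maximum score and edit
#' distance below 2 that intersects a cluster concordantly with its
#' direction and breakpoint has the remaining (unaligned) part of its read
#' realigned against each partner cluster's breakpoint region. Successful
#' realignments are added as rescued SPLIT support. For bridge-only
#' clusters, extra positional tolerance derived from the insert-size model
#' is allowed and the breakpoint is then set to the position with the most
#' rescued-read evidence. Breakpoints of clusters that already have SPLIT
#' evidence are never changed.
#'
#' @param fus `sb_fusions` from [form_putative_fusions()].
#' @param locals Local alignment table ([align_local()] output).
#' @param reads Named character vector (or `DNAStringSet`) with the read
#'   sequences referenced by `locals`.
#' @param db `TranscriptDB` (genome sequence source).
#' @param scoring [align_scoring()].
#' @param insert_model Optional [estimate_insert_model()] result; sets the
#'   bridge-only search tolerance to `mu + 3 sigma` (default 500 without a
#'   model).
#' @param min_score_frac Host-alignment score threshold as a fraction of the
#'   read's maximum score (default 0.5); also applied to the rescued part.
#' @param max_ed Maximum edit distance (exclusive bound is `max_ed + 1`;
#'   default 1, i.e. edit distance < 2).
#' @param min_part Minimum length of the remaining read part worth
#'   realigning (default 16 bp).
#' @return The updated `sb_fusions` (support rows added, counts updated,
#'   bridge-only breakpoints refined); rescued rows have `rescued = TRUE`.
#' @export
rescue_alignments <- function(fus, locals, reads, db,
                              scoring = align_scoring(), insert_model = NULL,
                              min_score_frac = 0.5, max_ed = 1L,
                              min_part = 16L) {
  if (!nrow(fus$fusions) || !nrow(locals)) return(fus)
  rc <- .read_chars(reads)
  extra <- if (!is.null(insert_model))
    as.integer(round(insert_model$mu + 3 * insert_model$sigma)) else 500L
  used_reads <- unique(fus$support$read_id[fus$support$type == "split"])
  cand <- locals[!(locals$read_id %in% used_reads), , drop = FALSE]
  if (!nrow(cand)) return(fus)
  L <- nchar(rc[cand$read_id])
  keep <- cand$score > min_score_frac * score_max(scoring, L) &
    cand$nm <= max_ed & !is.na(L)
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand)) return(fus)

  cl <- fus$clusters
  # partner clusters per cluster id, via the putative fusions
  partner_map <- split(c(fus$fusions$cluster_3p, fus$fusions$cluster_5p),
                       c(fus$fusions$cluster_5p, fus$fusions$cluster_3p))
  fusion_of <- function(c1, c2) {
    paste0("F", min(c1, c2), "_", max(c1, c2))
  }
  needed_strand <- function(side, role) {
    if (side == "right") { if (role == 1L) "+" else "-" }
    else { if (role == 1L) "-" else "+" }
  }
  new_support <- list()
  bp_votes <- list()  # cluster id -> vector of implied breakpoints

  for (i in seq_len(nrow(cand))) {
    a <- cand[i, ]
    hosts <- which(cl$chrom == a$chrom & cl$start <= a$end & cl$end >= a$start)
    if (!length(hosts)) next
    read <- rc[[a$read_id]]
    Lr <- nchar(read)
    for (h in hosts) {
      host <- cl[h, ]
      role <- if ((host$side == "right" && a$strand == "+") ||
                  (host$side == "left" && a$strand == "-")) 1L else 2L
      # direction concordance: the alignment's own junction side must match
      if (needed_strand(host$side, role) != a$strand) next
      edge <- if (host$side == "right") a$end else a$start
      if (!host$approx) {
        if (abs(edge - host$bp) > 3L) next
      } else {
        d <- if (host$side == "right") host$bp - a$end else a$start - host$bp
        if (d < -3L || d > extra) next
      }
      part <- if (role == 1L) substr(read, a$q + a$l, Lr)
              else substr(read, 1L, a$q - 1L)
      if (nchar(part) < min_part) next
      partners <- unique(partner_map[[as.character(host$cluster)]])
      for (pc in partners) {
        pcl <- cl[cl$cluster == pc, ]
        role_p <- 3L - role
        str_p <- needed_strand(pcl$side, role_p)
        pad <- nchar(part) + 10L
        ext <- if (pcl$approx) extra else 0L
        # candidate windows: the genomic breakpoint region, plus (for exact
        # breakpoints inside an annotated exon) the spliced transcript frame,
        # which captures partner halves that span a splice junction
        wins <- list()
        if (pcl$side == "left") {
          ws <- pcl$bp; we <- pcl$bp + pad + ext
        } else {
          ws <- pcl$bp - pad - ext; we <- pcl$bp
        }
        chrlen <- Biostrings::width(db$genome)[match(pcl$chrom,
                                                     names(db$genome))]
        ws <- max(1L, ws); we <- min(chrlen, we)
        if (we - ws + 1L >= min_part)
          wins[[1]] <- list(seq = as.character(
            Biostrings::subseq(db$genome[[pcl$chrom]], ws, we)),
            ws = ws, genomic = TRUE,
            junction_end = if (pcl$side == "left") "start" else "end",
            rc_query = str_p == "-")
        if (!pcl$approx) {
          exh <- db$exons[db$exons$chrom == pcl$chrom &
                            db$exons$start <= pcl$bp &
                            db$exons$end >= pcl$bp, , drop = FALSE]
          for (tid in unique(exh$transcript_id)) {
            gs <- db$transcripts[tid, "strand"]
            t_bp <- .genomic_to_transcript(db, tid, pcl$bp)
            if (is.na(t_bp)) next
            tlen <- db$transcripts[tid, "tlen"]
            donor_like <- (pcl$side == "right" && gs == "+") ||
              (pcl$side == "left" && gs == "-")
            if (donor_like) {
              ta <- max(1L, t_bp - pad); tb <- t_bp
              jend <- "end"
            } else {
              ta <- t_bp; tb <- min(tlen, t_bp + pad)
              jend <- "start"
            }
            if (tb - ta + 1L < min_part) next
            tseq <- substr(as.character(transcript_seqs(db, tid)), ta, tb)
            wins[[length(wins) + 1L]] <- list(seq = tseq, ws = NA_integer_,
              genomic = FALSE, junction_end = jend,
              rc_query = xor(str_p == "-", gs == "-"),
              tid = tid, t_off = ta - 1L, donor_like = donor_like)
          }
        } else {
          # approximate (bridge-only) partner: also try the spliced frame of
          # transcripts overlapping the search region; the junction position
          # is inferred from the realignment itself
          txh <- db$transcripts[db$transcripts$chrom == pcl$chrom &
                                  db$transcripts$start <= we &
                                  db$transcripts$end >= ws, , drop = FALSE]
          for (tid in txh$transcript_id) {
            gs <- txh[tid, "strand"]
            donor_like <- (pcl$side == "right" && gs == "+") ||
              (pcl$side == "left" && gs == "-")
            tseq <- as.character(transcript_seqs(db, tid))
            if (nchar(tseq) < min_part) next
            wins[[length(wins) + 1L]] <- list(seq = tseq, ws = NA_integer_,
              genomic = FALSE, junction_end = "none",
              rc_query = xor(str_p == "-", gs == "-"),
              tid = tid, t_off = 0L, donor_like = donor_like)
          }
        }
        sw <- NULL; win_used <- NULL
        for (wn in wins) {
          qq <- if (wn$rc_query)
            as.character(Biostrings::reverseComplement(Biostrings::DNAString(part)))
            else part
          cand_sw <- sb_sw_align(qq, wn$seq, scoring$match, scoring$mismatch,
                                 scoring$gap_open, scoring$gap_extend)
          if (cand_sw$score <= min_score_frac * scoring$match * nchar(part))
            next
          if (cand_sw$nm > max_ed) next
          wlen <- nchar(wn$seq)
          junction_ok <- if (wn$junction_end == "start") cand_sw$rstart <= 4L
                         else (cand_sw$rstart + cand_sw$rlen - 1L) >= wlen - 3L
          if (!pcl$approx && !junction_ok) next
          sw <- cand_sw; win_used <- wn
          break
        }
        if (is.null(sw)) next
        host_bp <- if (host$approx) edge else host$bp
        part_bp <- if (!pcl$approx) pcl$bp
          else if (win_used$genomic) {
            if (pcl$side == "left") win_used$ws + sw$rstart - 1L
            else win_used$ws + sw$rstart + sw$rlen - 2L
          } else {
            t_j <- win_used$t_off +
              if (win_used$donor_like) sw$rstart + sw$rlen - 1L else sw$rstart
            .transcript_to_genomic(db, win_used$tid, t_j)
          }
        if (is.na(part_bp)) next
        ws <- if (win_used$genomic) win_used$ws else pcl$bp
        if (host$approx)
          bp_votes[[as.character(host$cluster)]] <-
            c(bp_votes[[as.character(host$cluster)]], host_bp)
        if (pcl$approx)
          bp_votes[[as.character(pc)]] <-
            c(bp_votes[[as.character(pc)]], part_bp)
        c1 <- if (role == 1L) host$cluster else pc
        c2 <- if (role == 1L) pc else host$cluster
        pstart <- ws + sw$rstart - 1L
        pend <- pstart + sw$rlen - 1L
        q_in_part <- if (str_p == "+") sw$qstart
                     else nchar(part) - (sw$qstart + sw$qlen - 1L) + 1L
        part_off <- if (role == 1L) a$q + a$l else 1L
        q_p <- part_off + q_in_part - 1L
        new_support[[length(new_support) + 1L]] <- data.frame(
          fusion_id = fusion_of(host$cluster, pc),
          bpc_id = paste0("r", length(new_support) + 1L),
          type = "split", read_id = a$read_id,
          mate = NA_integer_, multi = a$nhits > 1L,
          cluster_r1 = c1, cluster_r2 = c2,
          strand_r1 = if (role == 1L) a$strand else str_p,
          strand_r2 = if (role == 1L) str_p else a$strand,
          bp_r1 = if (role == 1L) host_bp else part_bp,
          bp_r2 = if (role == 1L) part_bp else host_bp,
          start_r1 = if (role == 1L) a$start else pstart,
          end_r1 = if (role == 1L) a$end else pend,
          start_r2 = if (role == 1L) pstart else a$start,
          end_r2 = if (role == 1L) pend else a$end,
          q_r1 = if (role == 1L) a$q else q_p,
          l_r1 = if (role == 1L) a$l else sw$qlen,
          q_r2 = if (role == 1L) q_p else a$q,
          l_r2 = if (role == 1L) sw$qlen else a$l,
          score_bpc = a$score + sw$score,
          rescued = TRUE, stringsAsFactors = FALSE)
        break  # one rescue per host alignment
      }
    }
  }
  if (!length(new_support)) return(fus)
  add <- do.call(rbind, new_support)
  # a read rescues at most one fusion
  add <- add[!duplicated(add$read_id), , drop = FALSE]
  fus$support <- rbind(fus$support, add)
  # refine bridge-only breakpoints by majority evidence
  for (cid in names(bp_votes)) {
    ci <- which(fus$clusters$cluster == as.integer(cid))
    if (!fus$clusters$approx[ci]) next
    tab <- table(bp_votes[[cid]])
    newbp <- as.integer(names(tab)[which.max(tab)])
    fus$clusters$bp[ci] <- newbp
    fus$clusters$approx[ci] <- FALSE
    sel5 <- fus$fusions$cluster_5p == as.integer(cid)
    fus$fusions$bp_5p[sel5] <- newbp
    fus$fusions$approx_5p[sel5] <- FALSE
    sel3 <- fus$fusions$cluster_3p == as.integer(cid)
    fus$fusions$bp_3p[sel3] <- newbp
    fus$fusions$approx_3p[sel3] <- FALSE
  }
  # recount support
  ns <- table(fus$support$fusion_id[fus$support$type == "split"])
  fus$fusions$n_split <- as.integer(ns[fus$fusions$fusion_id])
  fus$fusions$n_split[is.na(fus$fusions$n_split)] <- 0L
  fus
}
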