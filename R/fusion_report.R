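# Reporting: breakpoint annotation, fusion-type classification, junction
# sequence reconstruction and (de)serialization of the report table.
# Reported coordinates are 1-based inclusive.

#' Classify the type of a fusion event
#'
#' @param fusion One row of `sb_fusions$fusions` (or a report record with
#'   the same fields).
#' @param db `TranscriptDB`.
#' @param readthrough_dist Maximum genomic separation for a read-through
#'   call (default 200 kb).
#' @param edge_slack Slack for exon-edge matching of the breakpoints.
#' @return list with `type` (one of "inter-chromosomal", "read-through",
#'   "intra-chromosomal-other") and `flags` (may include
#'   "involving-intergenic" and "involving-intron"), plus the per-partner
#'   breakpoint categories `category_5p`, `category_3p`.
#' @export
classify_fusion_type <- function(fusion, db, readthrough_dist = 200000L,
                                 edge_slack = 0L) {
  a5 <- annotate_position(fusion$chrom_5p, fusion$bp_5p, db, slack = edge_slack)
  a3 <- annotate_position(fusion$chrom_3p, fusion$bp_3p, db, slack = edge_slack)
  flags <- character(0)
  if (a5$category == "intergenic" || a3$category == "intergenic")
    flags <- c(flags, "involving-intergenic")
  if (a5$category == "inside_intron" || a3$category == "inside_intron")
    flags <- c(flags, "involving-intron")
  if (fusion$chrom_5p != fusion$chrom_3p) {
    type <- "inter-chromosomal"
  } else {
    type <- "intra-chromosomal-other"
    s5 <- fusion$gene_strand_5p; s3 <- fusion$gene_strand_3p
    if (!is.na(s5) && !is.na(s3) && s5 == s3 &&
        abs(fusion$bp_3p - fusion$bp_5p) <= readthrough_dist) {
      downstream <- if (s5 == "+") fusion$bp_5p < fusion$bp_3p
                    else fusion$bp_5p > fusion$bp_3p
      if (downstream) type <- "read-through"
    }
  }
  list(type = type, flags = flags,
       category_5p = a5$category, category_3p = a3$category)
}

#' Reconstruct the fusion junction sequence
#'
#' Strand-aware concatenation of `flank` bases ending at the 5' breakpoint
#' with `flank` bases starting at the 3' breakpoint; useful for PCR primer
#' design. The junction sits after position `junction_at` (= length of the
#' 5' part) of the returned sequence.
#'
#' @param fusion One row of `sb_fusions$fusions`.
#' @param db `TranscriptDB`.
#' @param flank Flank length per side in bp (default 500).
#' @return list with `sequence` (character), `junction_at`, `truncated`
#'   (TRUE when a breakpoint was closer than `flank` to a contig end).
#' @export
reconstruct_junction_sequence <- function(fusion, db, flank = 500L) {
  part <- function(chrom, bp, side, role5) {
    chr <- db$genome[[chrom]]
    if (is.null(chr)) stop("unknown chromosome: ", chrom)
    n <- length(chr)
    if (side == "right") { a <- bp - flank + 1L; b <- bp } else {
      a <- bp; b <- bp + flank - 1L
    }
    trunc <- a < 1L || b > n
    a <- max(1L, a); b <- min(n, b)
    s <- Biostrings::subseq(chr, a, b)
    # the 5' part must END at the junction, the 3' part must START at it;
    # a left-side 5' partner (or right-side 3' partner) reads on the
    # reverse strand
    rc <- (role5 && side == "left") || (!role5 && side == "right")
    if (rc) s <- Biostrings::reverseComplement(s)
    list(seq = as.character(s), trunc = trunc)
  }
  p5 <- part(fusion$chrom_5p, fusion$bp_5p, fusion$side_5p, TRUE)
  p3 <- part(fusion$chrom_3p, fusion$bp_3p, fusion$side_3p, FALSE)
  list(sequence = paste0(p5$seq, p3$seq), junction_at = nchar(p5$seq),
       truncated = p5$trunc || p3$trunc)
}

#' Build report records from filtered fusions
#'
#' @param fus `sb_fusions` after feature computation and filtering.
#' @param db `TranscriptDB`.
#' @param only_pass Keep only passing fusions (default TRUE).
#' @param junction_seq Include the reconstructed junction sequence.
#' @param junction_flank Flank per side for the junction sequence.
#' @param edge_slack Exon-edge slack for breakpoint categories.
#' @return data.frame of fusion records (one row per fusion), 1-based
#'   coordinates, deterministically sorted by breakpoint.
#' @export
build_fusion_records <- function(fus, db, only_pass = TRUE,
                                 junction_seq = FALSE, junction_flank = 500L,
                                 edge_slack = 0L) {
  f <- fus$fusions
  if (!is.null(f$pass) && only_pass) f <- f[f$pass, , drop = FALSE]
  if (!nrow(f)) return(.empty_report())
  gene_names <- function(ids) {
    g <- strsplit(ids, ",")[[1]]
    g <- g[nzchar(g)]
    if (!length(g)) return("intergenic")
    paste(db$genes[g, "gene_name"], collapse = ",")
  }
  rows <- lapply(seq_len(nrow(f)), function(i) {
    ty <- classify_fusion_type(f[i, ], db, edge_slack = edge_slack)
    js <- if (junction_seq)
      reconstruct_junction_sequence(f[i, ], db, flank = junction_flank)
    else list(sequence = NA_character_, junction_at = NA_integer_)
    get <- function(col, default = NA_real_)
      if (col %in% names(f)) f[[col]][i] else default
    data.frame(
      fusion_id = f$fusion_id[i],
      gene_5p = gene_names(f$gene_5p[i]), gene_3p = gene_names(f$gene_3p[i]),
      gene_id_5p = ifelse(nzchar(f$gene_5p[i]), f$gene_5p[i], "intergenic"),
      gene_id_3p = ifelse(nzchar(f$gene_3p[i]), f$gene_3p[i], "intergenic"),
      chrom_5p = f$chrom_5p[i], bp_5p = f$bp_5p[i],
      side_5p = f$side_5p[i], category_5p = ty$category_5p,
      chrom_3p = f$chrom_3p[i], bp_3p = f$bp_3p[i],
      side_3p = f$side_3p[i], category_3p = ty$category_3p,
      fusion_type = ty$type, flags = paste(ty$flags, collapse = ","),
      n_split = f$n_split[i], n_bridge = f$n_bridge[i],
      approx_breakpoint = f$approx_5p[i] | f$approx_3p[i],
      homogeneity_weight = get("homogeneity_weight"),
      unique_split_fraction = get("unique_split_fraction"),
      breakpoint_offset_dev = get("breakpoint_offset_dev"),
      has_unique_split = get("has_unique_split", NA),
      homology_score = get("homology_score"),
      valid_insert_ratio = get("valid_insert_ratio"),
      strand_consistency = get("strand_consistency"),
      antisense_5p = get("antisense_5p", NA),
      antisense_3p = get("antisense_3p", NA),
      pass = get("pass", NA), fail_reasons = get("fail_reasons", ""),
      junction_seq = js$sequence, junction_at = js$junction_at,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom_5p, out$bp_5p, out$chrom_3p, out$bp_3p), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_report <- function() {
  data.frame(fusion_id = character(0), gene_5p = character(0),
             gene_3p = character(0), gene_id_5p = character(0),
             gene_id_3p = character(0), chrom_5p = character(0),
             bp_5p = integer(0), side_5p = character(0),
             category_5p = character(0), chrom_3p = character(0),
             bp_3p = integer(0), side_3p = character(0),
             category_3p = character(0), fusion_type = character(0),
             flags = character(0), n_split = integer(0),
             n_bridge = integer(0), approx_breakpoint = logical(0),
             homogeneity_weight = numeric(0),
             unique_split_fraction = numeric(0),
             breakpoint_offset_dev = numeric(0),
             has_unique_split = logical(0), homology_score = numeric(0),
             valid_insert_ratio = numeric(0),
             strand_consistency = numeric(0), antisense_5p = logical(0),
             antisense_3p = logical(0), pass = logical(0),
             fail_reasons = character(0), junction_seq = character(0),
             junction_at = integer(0), stringsAsFactors = FALSE)
}

#' Write a fusion report as TSV
#'
#' One row per fusion, stable column order, 1-based coordinates; an empty
#' record set yields a header-only file. Optionally writes the supporting
#' alignments as a SAM text file with a `fs:Z:` tag naming the fusion.
#'
#' @param records [build_fusion_records()] output.
#' @param path Output TSV path.
#' @param fus Optional `sb_fusions` (needed for `support_sam`).
#' @param db Optional `TranscriptDB` (needed for `support_sam` headers).
#' @param support_sam Optional path for the supporting-read SAM.
#' @return `path`, invisibly.
#' @export
write_fusion_report <- function(records, path, fus = NULL, db = NULL,
                                support_sam = NULL) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(support_sam) && !is.null(fus) && !is.null(db)) {
    con <- file(support_sam, "w")
    on.exit(close(con))
    writeLines("@HD\tVN:1.6\tSO:unknown", con)
    for (ch in names(db$genome))
      writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ch,
                         Biostrings::width(db$genome)[match(ch, names(db$genome))]),
                 con)
    sup <- fus$support[fus$support$fusion_id %in% records$fusion_id, ,
                       drop = FALSE]
    cl <- fus$clusters
    for (i in seq_len(nrow(sup))) for (r in 1:2) {
      st <- sup[[paste0("start_r", r)]][i]
      en <- sup[[paste0("end_r", r)]][i]
      cid <- sup[[paste0("cluster_r", r)]][i]
      chrom <- cl$chrom[match(cid, cl$cluster)]
      if (is.na(st)) next
      flag <- if (sup[[paste0("strand_r", r)]][i] == "-") 16L else 0L
      writeLines(paste(sup$read_id[i], flag, chrom, st, 255L,
                       paste0(en - st + 1L, "M"), "*", 0L, 0L, "*", "*",
                       paste0("fs:Z:", sup$fusion_id[i]), sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Read a fusion report written by [write_fusion_report()]
#'
#' @param path Report TSV path.
#' @return data.frame of records.
#' @export
read_fusion_report <- function(path) {
  chr_cols <- c(fusion_id = "character", gene_5p = "character",
                gene_3p = "character", gene_id_5p = "character",
                gene_id_3p = "character", chrom_5p = "character",
                chrom_3p = "character", side_5p = "character",
                side_3p = "character", category_5p = "character",
                category_3p = "character", fusion_type = "character",
                flags = "character", fail_reasons = "character",
                junction_seq = "character")
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  cls <- chr_cols[intersect(names(chr_cols), header)]
  out <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = cls)
  if (!nrow(out)) return(.empty_report())
  out
}
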