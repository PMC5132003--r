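# End-to-end orchestration of the calling pipeline:
#   1  end-to-end alignment to transcriptome (and optionally genome)
#   2  local alignment of unmapped reads to the genome
#   3  SPLIT candidate formation
#   4  pair classification, insert-size model, expression (paired-end only)
#   5  clustering, rescue, putative fusion assembly
#   6  refinement, feature computation, filtering
#   7  reporting
# Stage outputs are checkpointed in the work directory so filtering can be
# repeated with adjusted thresholds without re-alignment.

#' Pipeline configuration
#'
#' @param reads1,reads2 FASTQ paths or named sequence vectors; `reads2`
#'   `NULL` for single-end data.
#' @param genome FASTA path or `DNAStringSet`.
#' @param gtf GTF path or exon data.frame (see [load_annotation()]).
#' @param workdir Optional checkpoint/report directory.
#' @param strandedness "none", "forward" or "reverse".
#' @param I_max Maximum intron size (default 20000 bp).
#' @param split [split_params()].
#' @param thresholds [filter_thresholds()].
#' @param scoring [align_scoring()].
#' @param k K-mer size for the alignment indexes (default 13).
#' @param max_mm Maximum end-to-end mismatches (default 6).
#' @param map_to_genome Also map transcriptome-unmapped reads end-to-end to
#'   the genome (default TRUE).
#' @param discard_mito,mito Mitochondrial read handling (see
#'   [run_end_to_end()]).
#' @param bp_tol Cluster breakpoint tolerance (default 10 bp).
#' @param rescue Run the rescue step (default TRUE).
#' @param junction_seq Include junction sequences in the report.
#' @param edge_slack Exon-edge slack for breakpoint categories (default 0).
#' @param seed Recorded for provenance (the caller is deterministic).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(reads1, reads2 = NULL, genome, gtf,
                            workdir = NULL,
                            strandedness = c("none", "forward", "reverse"),
                            I_max = 20000L, split = NULL,
                            thresholds = filter_thresholds(),
                            scoring = align_scoring(), k = 13L,
                            max_mm = 6L, map_to_genome = TRUE,
                            discard_mito = TRUE, mito = c("chrM", "MT"),
                            bp_tol = 10L, rescue = TRUE,
                            junction_seq = FALSE, edge_slack = 0L,
                            seed = NULL) {
  strandedness <- match.arg(strandedness)
  if (is.null(split)) split <- split_params(I_max = I_max)
  structure(as.list(environment()), class = "pipeline_config")
}

.load_reads <- function(x, suffix) {
  if (is.character(x) && length(x) == 1L && file.exists(x))
    x <- read_fastq(x)
  rc <- .read_chars(x)
  if (is.null(names(rc)) || !all(nzchar(names(rc))))
    names(rc) <- paste0("read", seq_along(rc))
  if (!all(grepl("/[12]$", names(rc))))
    names(rc) <- paste0(sub("/[12]$", "", names(rc)), suffix)
  rc
}

#' Run the full fusion-calling pipeline
#'
#' @param config [pipeline_config()].
#' @return list of class `sb_run`: `records` (the report), `fusions`
#'   (`sb_fusions` with features), `insert_model`, `expr`, `db`, `eval`
#'   input tables, and the paths written to `workdir` (if any).
#' @export
run_pipeline <- function(config) {
  cfg <- config
  db <- if (inherits(cfg$gtf, "TranscriptDB")) cfg$gtf
        else load_annotation(cfg$gtf, cfg$genome)
  paired <- !is.null(cfg$reads2)
  r1 <- .load_reads(cfg$reads1, "/1")
  r2 <- if (paired) .load_reads(cfg$reads2, "/2") else NULL

  txs <- transcript_seqs(db)
  tx_index <- build_align_index(txs, k = cfg$k)
  genome_index <- build_align_index(db$genome, k = cfg$k)

  # Step 1: end-to-end alignment (+ projection to genomic coordinates)
  e1 <- run_end_to_end(r1, mate = 1L, tx_index = tx_index,
                       genome_index = if (cfg$map_to_genome) genome_index,
                       db = db, max_mm = cfg$max_mm,
                       discard_mito = cfg$discard_mito, mito = cfg$mito)
  aln <- e1$alignments
  unmapped <- list(e1$unmapped)
  if (paired) {
    e2 <- run_end_to_end(r2, mate = 2L, tx_index = tx_index,
                         genome_index = if (cfg$map_to_genome) genome_index,
                         db = db, max_mm = cfg$max_mm,
                         discard_mito = cfg$discard_mito, mito = cfg$mito)
    aln <- rbind(aln, e2$alignments)
    unmapped[[2]] <- e2$unmapped
  }

  # Step 4a: pair classification, insert model, expression
  insert_model <- NULL
  bridges <- NULL
  expr <- NULL
  if (paired) {
    aln$base_id <- sub("/[12]$", "", aln$read_id)
    cls <- .classify_pairs(
      within(aln, read_id <- base_id), I_max = cfg$I_max)
    ins <- .insert_sizes_from_pairs(cls)
    if (length(ins) >= 2L) insert_model <- estimate_insert_model(ins)
    if (!is.null(cls$pairs) && nrow(cls$pairs)) {
      pp <- cls$pairs[cls$pairs$class == "proper", , drop = FALSE]
      proper_aln <- rbind(cls$a1[pp$i1, , drop = FALSE],
                          cls$a2[pp$i2, , drop = FALSE])
      expr <- estimate_expression(proper_aln, db)
      bc <- cls$pairs[cls$pairs$class == "bridge_candidate", , drop = FALSE]
      if (nrow(bc)) {
        x <- cls$a1[bc$i1, , drop = FALSE]
        y <- cls$a2[bc$i2, , drop = FALSE]
        bridges <- data.frame(
          read_id = sub("/[12]$", "", x$read_id),
          chrom1 = x$chrom, start1 = x$start, end1 = x$end,
          strand1 = x$strand, mm1 = x$mm, nhits1 = x$nhits,
          chrom2 = y$chrom, start2 = y$start, end2 = y$end,
          strand2 = y$strand, mm2 = y$mm, nhits2 = y$nhits,
          stringsAsFactors = FALSE)
      }
    }
  } else {
    expr <- estimate_expression(aln, db)
  }

  # Step 2-3: local alignment of unmapped reads, SPLIT candidates
  loc1 <- run_local(r1, unmapped[[1]], genome_index, scoring = cfg$scoring)
  if (nrow(loc1)) loc1$mate <- 1L
  locals <- loc1
  if (paired) {
    loc2 <- run_local(r2, unmapped[[2]], genome_index, scoring = cfg$scoring)
    if (nrow(loc2)) loc2$mate <- 2L
    locals <- rbind(loc1, loc2)
  }
  if (!"mate" %in% names(locals)) locals$mate <- integer(0)
  splits <- .form_splits_all(locals, cfg$split, cfg$scoring)

  # Step 5: clustering and putative fusions
  bridge_tol <- if (!is.null(insert_model))
    as.integer(ceiling(insert_model$mu + 3 * insert_model$sigma)) else 1000L
  bpcs <- .bpc_table(splits, bridges)
  clustered <- .cluster_bpcs(bpcs, tol = cfg$bp_tol, bridge_tol = bridge_tol)
  fus <- form_putative_fusions(clustered$members, clustered$clusters, db,
                               strandedness = cfg$strandedness)
  all_reads <- if (paired) c(r1, r2) else r1
  if (cfg$rescue)
    fus <- rescue_alignments(fus, locals, all_reads, db,
                             scoring = cfg$scoring,
                             insert_model = insert_model)

  # Step 6: refinement, features, filtering
  fus <- enforce_split_mate_consistency(fus, aln, I_max = cfg$I_max,
                                        paired = paired)
  fus <- merge_bridge_only_fusions(fus, I_max = cfg$I_max)
  fus <- merge_duplicate_fusions(fus)
  fus <- resolve_multimapped(fus, weights = cfg$thresholds$weights)
  fus <- compute_homogeneity(fus)
  read_len <- if (length(r1)) max(nchar(r1)) else 0L
  fus <- compute_coverage_features(fus, read_len = read_len, expr = expr)
  fus <- compute_homology_score(fus, db, list(genome_index, tx_index),
                                scoring = cfg$scoring)
  if (!is.null(insert_model))
    fus <- compute_insert_validity(fus, insert_model, db)
  fus <- compute_strand_concordance(fus, protocol = cfg$strandedness)
  fus <- apply_filters(fus, thresholds = cfg$thresholds, db = db,
                       stranded = cfg$strandedness != "none")

  # Step 7: report
  records <- build_fusion_records(fus, db, only_pass = TRUE,
                                  junction_seq = cfg$junction_seq,
                                  edge_slack = cfg$edge_slack)
  paths <- NULL
  if (!is.null(cfg$workdir)) {
    dir.create(cfg$workdir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      report = file.path(cfg$workdir, "report.tsv"),
      features = file.path(cfg$workdir, "features.tsv"),
      support = file.path(cfg$workdir, "support.tsv"),
      config = file.path(cfg$workdir, "run_config.json"))
    write_fusion_report(records, paths$report)
    utils::write.table(fus$fusions, paths$features, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(fus$support, paths$support, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cfg_flat <- cfg[vapply(cfg, function(x)
      is.atomic(x) && length(x) < 10, TRUE)]
    jsonlite::write_json(cfg_flat, paths$config, auto_unbox = TRUE,
                         null = "null")
  }
  structure(list(records = records, fusions = fus,
                 insert_model = insert_model, expr = expr, db = db,
                 paths = paths), class = "sb_run")
}

#' @export
print.sb_run <- function(x, ...) {
  cat("sb_run:", nrow(x$records), "reported fusions (",
      nrow(x$fusions$fusions), "putative )\n")
  invisible(x)
}

#' Re-filter saved fusion features with new thresholds
#'
#' Re-applies [apply_filters()] to a feature checkpoint (no re-alignment).
#'
#' @param x An `sb_run`, an `sb_fusions`, or a `workdir` path containing
#'   `features.tsv`.
#' @param thresholds [filter_thresholds()].
#' @param db `TranscriptDB` (for biotype lookups and report annotation).
#' @param stranded Whether the protocol was strand-specific.
#' @return data.frame of passing records under the new thresholds.
#' @export
refilter_fusions <- function(x, thresholds, db, stranded = FALSE) {
  fus <- if (inherits(x, "sb_run")) x$fusions
         else if (inherits(x, "sb_fusions")) x
         else {
           feats <- utils::read.delim(file.path(x, "features.tsv"),
                                      stringsAsFactors = FALSE)
           structure(list(fusions = feats, support = data.frame(),
                          clusters = data.frame(), dropped = character(0)),
                     class = "sb_fusions")
         }
  fus <- apply_filters(fus, thresholds = thresholds, db = db,
                       stranded = stranded)
  build_fusion_records(fus, db, only_pass = TRUE)
}
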