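# Fusion simulator: truth generation, transcript construction, read
# simulation, background reads, prediction scoring.

test_that("truth generation yields the requested class design", {
  db <- mini_db()
  fs <- generate_fusion_annotations(db, n_per_class = 4L, seed = 21L)
  sp <- fs$specs
  events <- sp[!duplicated(sp$fusion_id), ]
  expect_equal(nrow(events), 20L)               # 4 per class, 5 classes
  expect_equal(as.vector(table(events$class)), rep(4L, 5L))
  expect_true(all(sp$coverage >= 1 & sp$coverage <= 60))
  # class 5 carries at least 2 isoforms per event
  iso <- table(sp$fusion_id[sp$class == 5L])
  expect_true(all(iso >= 2L))
  # determinism: same seed, identical truth
  fs2 <- generate_fusion_annotations(db, n_per_class = 4L, seed = 21L)
  expect_identical(fs$specs, fs2$specs)
  # too-small annotation: error lists the deficit
  small <- local({
    r <- mini_ref()
    keep <- r$exons$gene_id %in% unique(r$exons$gene_id)[1:5]
    load_annotation(r$exons[keep, ], r$genome)
  })
  expect_error(generate_fusion_annotations(small, n_per_class = 4L),
               "deficit")
})

test_that("class-4 intergenic partners avoid all annotated genes", {
  db <- mini_db()
  fs <- generate_fusion_annotations(db, n_per_class = 4L, seed = 33L)
  sp <- fs$specs
  for (i in which(sp$class == 4L)) {
    p <- fs$portions[[i]]
    pin <- if (sp$gene_5p[i] == "intergenic") p$p5 else p$p3
    seg <- GenomicRanges::GRanges(pin$chrom,
                                  IRanges::IRanges(min(pin$blocks$start),
                                                   max(pin$blocks$end)))
    hits <- GenomicRanges::findOverlaps(seg, db$tx_gr, ignore.strand = TRUE)
    expect_equal(length(hits), 0L)
  }
})

test_that("fusion transcripts splice portions and encode the junction", {
  db <- mini_db()
  fs <- generate_fusion_annotations(db, n_per_class = 3L, seed = 44L)
  ftx <- build_fusion_transcripts(fs, db)
  sp <- fs$specs
  plen <- function(p) sum(p$blocks$end - p$blocks$start + 1L)
  for (i in seq_len(nrow(sp))) {
    fields <- strsplit(names(ftx)[i], "|", fixed = TRUE)[[1]]
    j <- as.integer(fields[5])
    # junction offset in the header equals the 5' portion length
    expect_equal(j, plen(fs$portions[[i]]$p5))
    expect_equal(Biostrings::width(ftx)[i],
                 plen(fs$portions[[i]]$p5) + plen(fs$portions[[i]]$p3))
  }
  # class-3 transcripts contain intronic bases adjacent to the junction:
  # extract the retained intron block manually and match it in the sequence
  i3 <- which(sp$class == 3L)
  found_intronic <- FALSE
  for (i in i3) {
    p5 <- fs$portions[[i]]$p5
    last <- p5$blocks[nrow(p5$blocks), ]
    ann <- annotate_position(p5$chrom, sp$bp_5p[i], db)
    if (ann$category != "inside_intron") next
    found_intronic <- TRUE
    block_seq <- as.character(Biostrings::subseq(db$genome[[p5$chrom]],
                                                 last$start, last$end))
    if (p5$strand == "-")
      block_seq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(block_seq)))
    j <- sum(p5$blocks$end - p5$blocks$start + 1L)
    expect_equal(substr(as.character(ftx[[i]]),
                        j - nchar(block_seq) + 1L, j), block_seq)
  }
  expect_true(found_intronic)
})

test_that("read counts follow coverage and errors respect the null model", {
  tx <- Biostrings::DNAStringSet(c(
    t1500 = withr::with_seed(1, paste(sample(c("A", "C", "G", "T"), 1500,
                                             TRUE), collapse = ""))))
  pr0 <- sim_read_params(sub_rate_5p = 0, sub_rate_3p = 0, ins_rate = 0,
                         del_rate = 0)
  rd <- simulate_reads(tx, params = pr0, coverage = c(t1500 = 60), seed = 2L)
  # coverage 60X, 1500 bp transcript, 75 bp reads: 600 pairs
  expect_equal(length(rd$read1), 600L)
  expect_equal(length(rd$read2), 600L)
  # zero error rates: every read substring-matches the transcript (mate 2
  # up to reverse complement)
  txc <- as.character(tx[[1]])
  rc <- function(x) as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(x)))
  ok1 <- vapply(rd$read1, function(r)
    grepl(r, txc, fixed = TRUE) || grepl(rc(r), txc, fixed = TRUE), TRUE)
  ok2 <- vapply(rd$read2, function(r)
    grepl(r, txc, fixed = TRUE) || grepl(rc(r), txc, fixed = TRUE), TRUE)
  expect_true(all(ok1) && all(ok2))
  # forward-stranded mode: mate 1 always matches the transcript sense
  rdf <- simulate_reads(tx, params = sim_read_params(sub_rate_5p = 0,
                          sub_rate_3p = 0, ins_rate = 0, del_rate = 0,
                          strandedness = "forward"),
                        coverage = c(t1500 = 20), seed = 3L)
  expect_true(all(vapply(rdf$read1, grepl, TRUE, x = txc, fixed = TRUE)))
  # determinism: identical seeds give identical reads and FASTQ bytes
  rda <- simulate_reads(tx, coverage = c(t1500 = 10), seed = 5L)
  rdb <- simulate_reads(tx, coverage = c(t1500 = 10), seed = 5L)
  expect_identical(rda, rdb)
  dir <- withr::local_tempdir()
  write_fastq(rda$read1, file.path(dir, "a.fq"))
  write_fastq(rdb$read1, file.path(dir, "b.fq"))
  expect_identical(readLines(file.path(dir, "a.fq")),
                   readLines(file.path(dir, "b.fq")))
  # nonzero error model perturbs some reads
  rde <- simulate_reads(tx, params = sim_read_params(),
                        coverage = c(t1500 = 30), seed = 6L)
  frac_exact <- mean(vapply(rde$read1, function(r)
    grepl(r, txc, fixed = TRUE) || grepl(rc(r), txc, fixed = TRUE), TRUE))
  expect_lt(frac_exact, 1)
  expect_gt(frac_exact, 0.4)
})

test_that("background reads respect the pair budget and the profile", {
  db <- mini_db()
  bg <- add_background_reads(db, n_pairs = 10000L, seed = 4L)
  expect_equal(length(bg$read1), 10000L)
  expect_equal(length(bg$read2), 10000L)
  # all-zero profile: empty output
  zero <- setNames(rep(0, nrow(db$genes)), db$genes$gene_id)
  bg0 <- add_background_reads(db, n_pairs = 1000L, profile = zero, seed = 4L)
  expect_length(bg0$read1, 0L)
  # a one-gene profile draws only from that gene's transcript
  one <- zero; one[["G0001"]] <- 1
  bg1 <- add_background_reads(db, n_pairs = 200L, profile = one, seed = 4L)
  expect_true(all(grepl("T0001", names(bg1$read1))))
})

test_that("prediction scoring applies the 20 bp per-breakpoint rule", {
  truth <- data.frame(fusion_id = c("A", "B"), isoform = 1L,
                      class = c(1L, 2L), coverage = 10,
                      chrom_5p = "chr1", bp_5p = c(1000L, 9000L),
                      chrom_3p = "chr2", bp_3p = c(5000L, 12000L),
                      stringsAsFactors = FALSE)
  pred <- data.frame(chrom_5p = c("chr1", "chr1"),
                     bp_5p = c(1015L, 9025L),
                     chrom_3p = c("chr2", "chr2"),
                     bp_3p = c(5000L, 12000L), stringsAsFactors = FALSE)
  # 15 bp off on one side: TP; 25 bp off: FP and the truth stays FN
  ev <- evaluate_predictions(truth, pred, tol = 20L)
  expect_equal(ev$TP, 1L)
  expect_equal(ev$FP, 1L)
  expect_equal(ev$FN, 1L)
  expect_equal(ev$recall, 0.5)
  expect_equal(ev$precision, 0.5)
  # swapped partner order still matches
  swp <- data.frame(chrom_5p = "chr2", bp_5p = 5000L, chrom_3p = "chr1",
                    bp_3p = 1000L, stringsAsFactors = FALSE)
  expect_equal(evaluate_predictions(truth, swp, tol = 20L)$TP, 1L)
  # no predictions: recall 0, precision undefined (NA)
  ev0 <- evaluate_predictions(truth, pred[0, ], tol = 20L)
  expect_equal(ev0$recall, 0)
  expect_true(is.na(ev0$precision))
  # per-class breakdown covers each class once
  expect_equal(ev$per_class$recall, c(1, 0))
})

test_that("toy references are reproducible and structurally sound", {
  r1 <- simulate_toy_reference(n_chrom = 1L, chrom_len = 100000L,
                               genes_per_chrom = 6L, seed = 12L)
  r2 <- simulate_toy_reference(n_chrom = 1L, chrom_len = 100000L,
                               genes_per_chrom = 6L, seed = 12L)
  expect_identical(as.character(r1$genome), as.character(r2$genome))
  expect_identical(r1$exons, r2$exons)
  db <- load_annotation(r1$exons, r1$genome)
  expect_true(all(db$transcripts$n_exons >= 2L))
  # genes do not overlap
  gr <- GenomicRanges::GRanges(db$genes$chrom,
                               IRanges::IRanges(db$genes$start, db$genes$end))
  expect_equal(length(GenomicRanges::findOverlaps(gr, drop.self = TRUE)), 0L)
})
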