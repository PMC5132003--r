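# Clustering of breakpoint candidates: interval clustering, directionality
# and breakpoint separation, putative fusion assembly, rescue.

bpc_row <- function(chrom, start, end, side = "right", bp = NA_integer_,
                    id = "b1", type = "split", role = 1L, strand = "+",
                    read = id) {
  data.frame(bpc_id = id, bpc_type = type, read_id = read, mate = 1L,
             role = role, chrom = chrom, start = start, end = end,
             strand = strand, side = side, bp = bp, q = 1L,
             l = end - start + 1L, score = 50L, nm = 0L, nhits = 1L,
             multi = FALSE, stringsAsFactors = FALSE)
}

test_that("iterative insertion produces non-intersecting clusters", {
  disjoint <- rbind(bpc_row("chr1", 100L, 200L), bpc_row("chr1", 500L, 600L),
                    bpc_row("chr2", 100L, 200L))
  expect_equal(length(unique(build_clusters(disjoint)$cluster)), 3L)
  # [100,200], [150,250], [240,300] inserted in order chain into one
  # cluster spanning 100-300 (rule ii twice)
  chain <- rbind(bpc_row("chr1", 100L, 200L), bpc_row("chr1", 150L, 250L),
                 bpc_row("chr1", 240L, 300L))
  cc <- build_clusters(chain)
  expect_equal(length(unique(cc$cluster)), 1L)
  # merge case (rule iii): two separate clusters joined by a spanning one
  bridge3 <- rbind(bpc_row("chr1", 100L, 150L), bpc_row("chr1", 300L, 350L),
                   bpc_row("chr1", 140L, 310L))
  expect_equal(length(unique(build_clusters(bridge3)$cluster)), 1L)
})

test_that("final clustering is independent of insertion order", {
  library(utils)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  partition_sig <- function(df) {
    grp <- split(df$bpc_id, df$cluster)
    sort(unname(vapply(grp, function(g) paste(sort(g), collapse = ","), "")))
  }
  set.seed(42)
  for (rep in 1:6) {
    n <- sample(4:6, 1)
    rows <- random_bpc_rows(n, chroms = "chr1", span = 300L)
    ref_sig <- NULL
    for (ord in perms(seq_len(n))) {
      sig <- partition_sig(build_clusters(rows[ord, , drop = FALSE]))
      if (is.null(ref_sig)) ref_sig <- sig else expect_equal(sig, ref_sig)
    }
  }
})

test_that("directionality separates clusters; compatible members co-cluster", {
  mixed <- rbind(bpc_row("chr1", 100L, 200L, side = "right", id = "s1"),
                 bpc_row("chr1", 120L, 220L, side = "left", id = "s2"))
  out <- split_by_directionality(build_clusters(mixed))
  expect_equal(length(unique(out$cluster)), 2L)
  # homogeneous cluster unchanged
  hom <- rbind(bpc_row("chr1", 100L, 200L, side = "right", id = "s1"),
               bpc_row("chr1", 120L, 220L, side = "right", id = "s2"))
  expect_equal(length(unique(split_by_directionality(
    build_clusters(hom))$cluster)), 1L)
  # a SPLIT first segment on '+' and a BRIDGE mate-1 on '+' at one locus
  # share direction (both point right) and co-cluster
  pair <- rbind(bpc_row("chr1", 100L, 175L, side = "right", id = "s1",
                        type = "split", role = 1L, bp = 175L),
                bpc_row("chr1", 130L, 205L, side = "right", id = "b1",
                        type = "bridge", role = 1L))
  out2 <- split_by_directionality(build_clusters(pair))
  expect_equal(length(unique(out2$cluster)), 1L)
})

test_that("breakpoint separation groups positions by chained tolerance", {
  mk <- function(bps) do.call(rbind, lapply(seq_along(bps), function(i)
    bpc_row("chr1", 950L, 1100L, side = "right", bp = bps[i],
            id = paste0("s", i))))
  d1 <- split_by_breakpoint(split_by_directionality(build_clusters(
    mk(c(1000L, 1004L, 1050L)))), tol = 10L)
  grp <- split(d1$bp, d1$cluster)
  expect_equal(length(grp), 2L)
  expect_true(any(vapply(grp, function(g) setequal(g, c(1000L, 1004L)), TRUE)))
  # identical breakpoints stay together
  d2 <- split_by_breakpoint(split_by_directionality(build_clusters(
    mk(rep(1000L, 4)))), tol = 10L)
  expect_equal(length(unique(d2$cluster)), 1L)
  # chain 1000, 1008, 1016: consecutive gaps within tolerance keep the
  # chain in a single cluster under the documented single-linkage rule
  d3 <- split_by_breakpoint(split_by_directionality(build_clusters(
    mk(c(1000L, 1008L, 1016L)))), tol = 10L)
  expect_equal(length(unique(d3$cluster)), 1L)
})

test_that("putative fusions aggregate BPCs keyed by cluster pairs", {
  db <- tiny_db()
  rows <- list()
  for (i in 1:5) {  # 5 SPLITs linking locus A (chr1, in GA) and B (chr2, GB)
    rows[[length(rows) + 1]] <-
      bpc_row("chr1", 530L, 600L, side = "right", bp = 600L,
              id = paste0("s", i), role = 1L, read = paste0("r", i))
    rows[[length(rows) + 1]] <-
      bpc_row("chr2", 1301L, 1370L, side = "left", bp = 1301L,
              id = paste0("s", i), role = 2L, read = paste0("r", i))
  }
  for (i in 1:2) {  # 2 BRIDGEs for the same event
    rows[[length(rows) + 1]] <-
      bpc_row("chr1", 520L, 595L, side = "right", id = paste0("b", i),
              type = "bridge", role = 1L, read = paste0("p", i))
    rows[[length(rows) + 1]] <-
      bpc_row("chr2", 1310L, 1385L, side = "left", id = paste0("b", i),
              type = "bridge", role = 2L, strand = "-", read = paste0("p", i))
  }
  members <- do.call(rbind, rows)
  cl <- splitbridge:::.cluster_bpcs(members)
  fus <- form_putative_fusions(cl$members, cl$clusters, db)
  expect_equal(nrow(fus$fusions), 1L)
  expect_equal(fus$fusions$n_split, 5L)
  expect_equal(fus$fusions$n_bridge, 2L)
  # conservation: every BPC appears in support or was dropped
  expect_equal(sort(unique(c(fus$support$bpc_id, fus$dropped))),
               sort(unique(members$bpc_id)))
  # unstranded ordering: chr1 partner is in GA ('+' gene, breakpoint on its
  # right = transcription flows into the junction) so it is the 5' side
  expect_equal(fus$fusions$chrom_5p, "chr1")
  expect_equal(fus$fusions$gene_5p, "GA")
})

test_that("degenerate BPCs with both alignments in one cluster are dropped", {
  db <- tiny_db()
  members <- rbind(
    bpc_row("chr1", 100L, 200L, side = "right", bp = 200L, id = "s1",
            role = 1L),
    bpc_row("chr1", 150L, 250L, side = "right", bp = 200L, id = "s1",
            role = 2L))
  cl <- splitbridge:::.cluster_bpcs(members)
  fus <- form_putative_fusions(cl$members, cl$clusters, db)
  expect_equal(nrow(fus$fusions), 0L)
  expect_equal(fus$dropped, "s1")
})

test_that("clustering stack is idempotent and conserves members", {
  set.seed(17)
  rows <- random_bpc_rows(30L)
  cl1 <- splitbridge:::.cluster_bpcs(rows)
  cl2 <- splitbridge:::.cluster_bpcs(cl1$members)
  sig <- function(m) split(m$bpc_id, m$cluster)
  expect_equal(unname(lapply(sig(cl2$members), sort)),
               unname(lapply(sig(cl1$members), sort)))
  expect_equal(nrow(cl1$members), nrow(rows))
})

test_that("rescue adds compatible unused alignments and respects limits", {
  # planted fusion on the tiny reference: GA exon3 end (chr1:600, right) to
  # GB transcript start (chr2:1400, left; '-' strand gene)
  db <- tiny_db()
  g1 <- db$genome$chr1; g2 <- db$genome$chr2
  donor <- as.character(Biostrings::subseq(g1, 541L, 600L))       # 60 bp
  acc20 <- as.character(Biostrings::reverseComplement(
    Biostrings::subseq(g2, 1381L, 1400L)))                        # 20 bp
  # junction read: 60 bp donor + 20 bp acceptor; the acceptor part is too
  # short for an independent local alignment (score 40 < 160/3)
  jread <- paste0(donor, acc20)
  gidx <- build_align_index(db$genome, k = 13L)
  locals <- align_local(setNames(jread, "resc/1"), gidx)
  expect_true(any(locals$chrom == "chr1" & locals$score > 0.5 * 160))
  # an existing fusion at the same breakpoints (from other reads)
  members <- rbind(
    bpc_row("chr1", 520L, 600L, side = "right", bp = 600L, id = "s1",
            role = 1L),
    bpc_row("chr2", 1330L, 1400L, side = "right", bp = 1400L, id = "s1",
            role = 2L, strand = "-"))
  cl <- splitbridge:::.cluster_bpcs(members)
  fus <- form_putative_fusions(cl$members, cl$clusters, db)
  expect_equal(nrow(fus$fusions), 1L)
  out <- rescue_alignments(fus, locals, c("resc/1" = jread), db)
  expect_equal(out$fusions$n_split, 2L)
  expect_true(any(out$support$rescued))
  # breakpoints of SPLIT-derived clusters never move
  expect_equal(out$fusions$bp_5p, fus$fusions$bp_5p)
  expect_equal(out$fusions$bp_3p, fus$fusions$bp_3p)
  # an alignment with edit distance 2 is never rescued
  locals_ed2 <- locals
  locals_ed2$nm <- 2L
  out2 <- rescue_alignments(fus, locals_ed2, c("resc/1" = jread), db)
  expect_false(any(out2$support$rescued))
})
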