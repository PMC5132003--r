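# Refinement and filter features: mate consistency, bridge-only merging,
# scoring, multimap resolution, the feature computations and the final
# thresholded verdict.

# construct an sb_fusions object directly
make_fus <- function(fusions, support, clusters = NULL) {
  if (is.null(clusters)) {
    clusters <- data.frame(
      cluster = unique(c(fusions$cluster_5p, fusions$cluster_3p)))
    clusters$chrom <- "chr1"
    clusters$start <- 100L * clusters$cluster
    clusters$end <- clusters$start + 80L
    clusters$side <- "right"
    clusters$n <- 1L
    clusters$bp <- clusters$end
    clusters$approx <- FALSE
  }
  structure(list(fusions = fusions, support = support, clusters = clusters,
                 members = data.frame(), strandedness = "none",
                 dropped = character(0)), class = "sb_fusions")
}

fusion_row <- function(id, c5 = 1L, c3 = 2L, chrom5 = "chr1", bp5 = 1000L,
                       side5 = "right", chrom3 = "chr2", bp3 = 5000L,
                       side3 = "left", gene5 = "GA", gene3 = "GB",
                       gs5 = "+", gs3 = "+", n_split = 2L, n_bridge = 1L) {
  data.frame(fusion_id = id, cluster_5p = c5, cluster_3p = c3,
             chrom_5p = chrom5, bp_5p = bp5, side_5p = side5,
             approx_5p = FALSE, chrom_3p = chrom3, bp_3p = bp3,
             side_3p = side3, approx_3p = FALSE, gene_5p = gene5,
             gene_3p = gene3, gene_strand_5p = gs5, gene_strand_3p = gs3,
             n_split = n_split, n_bridge = n_bridge, order_by = "annotation",
             stringsAsFactors = FALSE)
}

support_row <- function(fid, bpc, type = "split", read = bpc, multi = FALSE,
                        c1 = 1L, c2 = 2L, s1 = "+", s2 = "+",
                        bp1 = 1000L, bp2 = 5000L, st1 = 950L, en1 = 1000L,
                        st2 = 5000L, en2 = 5050L, q1 = 1L, l1 = 40L,
                        q2 = 41L, l2 = 35L, score = 150L, mate = 1L,
                        rescued = FALSE) {
  data.frame(fusion_id = fid, bpc_id = bpc, type = type, read_id = read,
             mate = mate, multi = multi, cluster_r1 = c1, cluster_r2 = c2,
             strand_r1 = s1, strand_r2 = s2, bp_r1 = bp1, bp_r2 = bp2,
             start_r1 = st1, end_r1 = en1, start_r2 = st2, end_r2 = en2,
             q_r1 = q1, l_r1 = l1, q_r2 = q2, l_r2 = l2, score_bpc = score,
             rescued = rescued, stringsAsFactors = FALSE)
}

test_that("SPLIT support without a consistent mate pair is discarded", {
  fus <- make_fus(fusion_row("F1", n_split = 2L, n_bridge = 0L),
                  rbind(support_row("F1", "s1", read = "r1/1"),
                        support_row("F1", "s2", read = "r2/1")))
  # r1's mate lands 500 bp from the 3' partner; r2's mate on an unrelated
  # chromosome far from both partners
  aln <- data.frame(read_id = c("r1/2", "r2/2"),
                    chrom = c("chr2", "chr9"),
                    start = c(5500L, 100000L), end = c(5575L, 100075L),
                    stringsAsFactors = FALSE)
  out <- enforce_split_mate_consistency(fus, aln, I_max = 20000L)
  expect_equal(out$fusions$n_split, 1L)
  expect_equal(out$support$bpc_id, "s1")
  expect_true(out$support$mate_ok[1])
  # single-end data: identity
  out_se <- enforce_split_mate_consistency(fus, aln, paired = FALSE)
  expect_equal(out_se$fusions$n_split, 2L)
})

test_that("bridge-only fusions merge into nearby split-supported events", {
  f <- rbind(fusion_row("F1", c5 = 1L, c3 = 2L, n_split = 3L, n_bridge = 0L),
             fusion_row("F2", c5 = 3L, c3 = 4L, bp5 = 4000L, bp3 = 8000L,
                        n_split = 0L, n_bridge = 2L))
  s <- rbind(support_row("F1", "s1", read = "a"),
             support_row("F1", "s2", read = "b"),
             support_row("F1", "s3", read = "c"),
             support_row("F2", "b1", type = "bridge", read = "d"),
             support_row("F2", "b2", type = "bridge", read = "e"))
  # 3 kb away, same directionality: absorbed, support summed
  out <- merge_bridge_only_fusions(make_fus(f, s), I_max = 20000L)
  expect_equal(nrow(out$fusions), 1L)
  expect_equal(out$fusions$n_split, 3L)
  expect_equal(out$fusions$n_bridge, 2L)
  # 1 Mb away: unchanged
  f2 <- f; f2$bp_5p[2] <- 1000000L; f2$bp_3p[2] <- 2005000L
  expect_equal(nrow(merge_bridge_only_fusions(make_fus(f2, s))$fusions), 2L)
  # opposite directionality: not merged
  f3 <- f; f3$side_5p[2] <- "left"
  expect_equal(nrow(merge_bridge_only_fusions(make_fus(f3, s))$fusions), 2L)
})

test_that("fusion score applies the declared support weights", {
  sup <- rbind(support_row("F1", "s1"), support_row("F1", "s2"),
               support_row("F1", "b1", type = "bridge"))
  sup$mate_ok <- c(TRUE, TRUE, NA)
  # two unique mated SPLITs (3 each) + one BRIDGE (1) = 7
  expect_equal(fusion_score(sup), 7)
  expect_equal(fusion_score(sup[0, ]), 0)
  # monotone: adding any support never decreases the score
  for (extra in list(support_row("F1", "x", multi = TRUE),
                     support_row("F1", "y", type = "bridge"))) {
    extra$mate_ok <- NA
    expect_gte(fusion_score(rbind(sup, extra)), fusion_score(sup))
  }
  # without mate information a unique SPLIT scores 2
  sup$mate_ok <- NA
  expect_equal(fusion_score(sup[1, , drop = FALSE]), 2)
})

test_that("multimap resolution assigns each read to its best fusion", {
  f <- rbind(fusion_row("F1", c5 = 1L, c3 = 2L),
             fusion_row("F2", c5 = 3L, c3 = 4L))
  strong <- do.call(rbind, lapply(1:10, function(i)
    support_row("F1", paste0("u", i), read = paste0("u", i))))
  weak <- rbind(support_row("F2", "w1", read = "w1"),
                support_row("F2", "w2", read = "w2"))
  shared <- rbind(support_row("F1", "m1", read = "mm", multi = TRUE),
                  support_row("F2", "m2", read = "mm", multi = TRUE))
  fus <- make_fus(f, rbind(strong, weak, shared))
  out <- resolve_multimapped(fus)
  # the shared read goes to the higher-scoring fusion
  expect_equal(out$support$fusion_id[out$support$read_id == "mm"], "F1")
  # postcondition: every read supports exactly one fusion
  expect_false(any(duplicated(out$support$read_id)))
  # symmetric tie: lexicographically smallest fusion id wins
  ftie <- rbind(fusion_row("FA", c5 = 1L, c3 = 2L),
                fusion_row("FB", c5 = 3L, c3 = 4L))
  stie <- rbind(support_row("FA", "t1", read = "tt", multi = TRUE),
                support_row("FB", "t2", read = "tt", multi = TRUE))
  out2 <- resolve_multimapped(make_fus(ftie, stie))
  expect_equal(out2$support$fusion_id, "FA")
})

test_that("metacluster homogeneity is the fusion's share of alignments", {
  # sole fusion in its metacluster: weight 1
  f1 <- fusion_row("F1")
  s1 <- rbind(support_row("F1", "s1", read = "a"),
              support_row("F1", "s2", read = "b"),
              support_row("F1", "b1", type = "bridge", read = "c"))
  f1$n_split <- 2L; f1$n_bridge <- 1L
  out1 <- compute_homogeneity(make_fus(f1, s1))
  expect_equal(out1$fusions$homogeneity_weight, 1)
  # 8 alignments of 40 in the metacluster: weight 0.2
  f2 <- rbind(fusion_row("F1", c5 = 1L, c3 = 10L, n_split = 8L,
                         n_bridge = 0L),
              fusion_row("F2", c5 = 2L, c3 = 20L, n_split = 32L,
                         n_bridge = 0L))
  sup2 <- rbind(
    do.call(rbind, lapply(1:8, function(i)
      support_row("F1", paste0("a", i), read = paste0("a", i),
                  c1 = 1L, c2 = 10L))),
    do.call(rbind, lapply(1:32, function(i)
      support_row("F2", paste0("b", i), read = paste0("b", i),
                  c1 = 2L, c2 = 20L))))
  clusters <- data.frame(cluster = c(1L, 2L, 10L, 20L),
                         chrom = c("chr1", "chr1", "chr2", "chr2"),
                         start = c(1000L, 1100L, 5000L, 5100L),
                         end = c(1080L, 1180L, 5080L, 5180L),
                         side = "right", n = 1L,
                         bp = c(1080L, 1180L, 5080L, 5180L), approx = FALSE,
                         stringsAsFactors = FALSE)
  out2 <- compute_homogeneity(make_fus(f2, sup2, clusters))
  expect_equal(out2$fusions$homogeneity_weight[1], 0.2)
  # weights of fusions sharing a metacluster sum to at most 1
  expect_lte(sum(out2$fusions$homogeneity_weight), 1)
})

test_that("coverage features capture footprint diversity and offsets", {
  f <- fusion_row("F1", n_split = 10L, n_bridge = 0L)
  # 10 SPLITs with identical genomic footprints: unique fraction 1/10
  s_same <- do.call(rbind, lapply(1:10, function(i)
    support_row("F1", paste0("s", i), read = paste0("s", i))))
  out <- compute_coverage_features(make_fus(f, s_same), read_len = 75L)
  expect_equal(out$fusions$unique_split_fraction, 0.1)
  expect_true(out$fusions$has_unique_split)
  # in-read junction offsets symmetric around the read middle: deviation ~ 0
  offs <- c(30L, 35L, 40L, 45L)   # q_r1 + l_r1 - 1 averages 37.5 = 75/2
  s_sym <- do.call(rbind, lapply(seq_along(offs), function(i)
    support_row("F1", paste0("y", i), read = paste0("y", i), q1 = 1L,
                l1 = offs[i], st1 = 900L + i, en1 = 900L + i + offs[i])))
  out2 <- compute_coverage_features(make_fus(f, s_sym), read_len = 75L)
  expect_lt(out2$fusions$breakpoint_offset_dev, 0.01)
  # all-multimapped SPLIT-only support trips the unique-split requirement
  s_mm <- do.call(rbind, lapply(1:3, function(i)
    support_row("F1", paste0("m", i), read = paste0("m", i), multi = TRUE)))
  f_mm <- fusion_row("F1", n_split = 3L, n_bridge = 0L)
  out3 <- apply_filters(compute_coverage_features(make_fus(f_mm, s_mm),
                                                  read_len = 75L))
  expect_false(out3$fusions$pass)
  expect_match(out3$fusions$fail_reasons, "has_unique_split")
})

test_that("junction homology separates genuine junctions from artifacts", {
  db <- tiny_db()
  gidx <- build_align_index(db$genome, k = 13L)
  # genuine junction of two unrelated loci: each half aligns alone (~0.5)
  f_true <- fusion_row("F1", chrom5 = "chr1", bp5 = 700L, side5 = "right",
                       chrom3 = "chr2", bp3 = 500L, side3 = "left")
  clusters <- data.frame(cluster = 1:2, chrom = c("chr1", "chr2"),
                         start = c(580L, 500L), end = c(700L, 620L),
                         side = c("right", "left"), n = 1L,
                         bp = c(700L, 500L), approx = FALSE,
                         stringsAsFactors = FALSE)
  out <- compute_homology_score(make_fus(f_true, support_row("F1", "s1"),
                                         clusters), db, gidx)
  expect_lt(out$fusions$homology_score, 0.7)
  expect_gt(out$fusions$homology_score, 0.3)
  # a "junction" that is contiguous reference sequence scores ~ 1 and is
  # filtered (retro-copy style artifact)
  f_art <- fusion_row("F2", chrom5 = "chr1", bp5 = 1000L, side5 = "right",
                      chrom3 = "chr1", bp3 = 1001L, side3 = "left",
                      n_split = 3L)
  cl_art <- data.frame(cluster = 1:2, chrom = "chr1",
                       start = c(880L, 1001L), end = c(1000L, 1121L),
                       side = c("right", "left"), n = 1L,
                       bp = c(1000L, 1001L), approx = FALSE,
                       stringsAsFactors = FALSE)
  out2 <- compute_homology_score(make_fus(f_art, support_row("F2", "s1"),
                                          cl_art), db, gidx)
  expect_gt(out2$fusions$homology_score, 0.9)
  v <- apply_filters(out2)
  expect_match(v$fusions$fail_reasons, "max_homology_score")
})

test_that("insert validity applies the 3-sigma rule across the junction", {
  model <- structure(list(mu = 300, sigma = 80, n = 1000),
                     class = "insert_model")
  db <- tiny_db()
  # intergenic partners so mate-to-breakpoint distances stay genomic
  mk <- function(inserts) {
    f <- fusion_row("F1", chrom5 = "chr1", bp5 = 1700L, side5 = "right",
                    chrom3 = "chr2", bp3 = 1600L, side3 = "left",
                    gene5 = "", gene3 = "", gs5 = NA, gs3 = NA,
                    n_split = 0L, n_bridge = length(inserts))
    s <- do.call(rbind, lapply(seq_along(inserts), function(i) {
      d5 <- inserts[i] %/% 2; d3 <- inserts[i] - d5
      support_row("F1", paste0("b", i), type = "bridge",
                  read = paste0("b", i), c1 = 1L, c2 = 2L,
                  st1 = 1700L - d5 + 1L, en1 = 1700L - d5 + 75L,
                  st2 = 1600L, en2 = 1600L + d3 - 1L)
    }))
    make_fus(f, s)
  }
  # mu=300, sigma=80: insert 540 is on the 3-sigma boundary (valid), 541 not
  out <- compute_insert_validity(mk(c(540L, 541L)), model, db)
  expect_equal(out$fusions$valid_insert_ratio, 0.5)
  out2 <- compute_insert_validity(mk(rep(300L, 5)), model, db)
  expect_equal(out2$fusions$valid_insert_ratio, 1)
  # no bridge support: feature not applicable, ratio 1
  f0 <- fusion_row("F0", n_split = 2L, n_bridge = 0L)
  out3 <- compute_insert_validity(make_fus(f0, support_row("F0", "s1")),
                                  model, db)
  expect_equal(out3$fusions$valid_insert_ratio, 1)
})

test_that("strand concordance flags antisense partners, inert unstranded", {
  f <- fusion_row("F1", gs5 = "+", gs3 = "+")
  s <- rbind(support_row("F1", "s1", read = "a", s1 = "+", s2 = "+",
                         mate = 1L),
             support_row("F1", "s2", read = "b", s1 = "+", s2 = "+",
                         mate = 1L))
  # forward protocol, mate 1 aligned to the annotated strand: concordant
  out <- compute_strand_concordance(make_fus(f, s), protocol = "forward")
  expect_equal(out$fusions$strand_concordance_5p, 1)
  expect_false(out$fusions$antisense_5p)
  # all supports opposite for partner B: antisense flag
  s2 <- s; s2$strand_r2 <- "-"
  out2 <- compute_strand_concordance(make_fus(f, s2), protocol = "forward")
  expect_equal(out2$fusions$strand_concordance_3p, 0)
  expect_true(out2$fusions$antisense_3p)
  expect_false(out2$fusions$antisense_5p)
  # consistency stays high for a uniformly antisense partner
  expect_equal(out2$fusions$strand_consistency, 1)
  # unstranded: inert
  out3 <- compute_strand_concordance(make_fus(f, s2), protocol = "none")
  expect_equal(out3$fusions$strand_consistency, 1)
  expect_false(out3$fusions$antisense_3p)
})

test_that("final filtering enumerates violations and honors biotypes", {
  db <- tiny_db()
  good <- fusion_row("F1", n_split = 4L, n_bridge = 2L)
  good$homogeneity_weight <- 1
  good$unique_split_fraction <- 0.8
  good$breakpoint_offset_dev <- 0.05
  good$has_unique_split <- TRUE
  good$homology_score <- 0.5
  good$valid_insert_ratio <- 1
  out <- apply_filters(make_fus(good, support_row("F1", "s1")))
  expect_true(out$fusions$pass)
  expect_equal(out$fusions$fail_reasons, "")
  # one multimapped SPLIT only: support and unique-split rules both fire
  bad <- fusion_row("F2", n_split = 1L, n_bridge = 0L)
  bad$has_unique_split <- FALSE
  out2 <- apply_filters(make_fus(bad, support_row("F2", "m1", multi = TRUE)))
  expect_false(out2$fusions$pass)
  expect_match(out2$fusions$fail_reasons, "min_support")
  expect_match(out2$fusions$fail_reasons, "has_unique_split")
  # pseudogene partner: discarded by default, kept with the override
  pdb <- local({
    d <- tiny_db()
    d$genes["GB", "biotype"] <- "processed_pseudogene"
    d
  })
  pg <- fusion_row("F3", gene3 = "GB", n_split = 4L, n_bridge = 0L)
  pg$has_unique_split <- TRUE
  out3 <- apply_filters(make_fus(pg, support_row("F3", "s1")), db = pdb)
  expect_match(out3$fusions$fail_reasons, "biotype")
  out4 <- apply_filters(make_fus(pg, support_row("F3", "s1")),
                        filter_thresholds(allow_biotype_override = TRUE),
                        db = pdb)
  expect_true(out4$fusions$pass)
})

test_that("relaxing any threshold never shrinks the pass set", {
  set.seed(2024)
  n <- 40L
  f <- do.call(rbind, lapply(seq_len(n), function(i)
    fusion_row(sprintf("F%02d", i), n_split = sample(0:6, 1),
               n_bridge = sample(0:4, 1))))
  f <- f[f$n_split + f$n_bridge > 0, ]
  f$homogeneity_weight <- runif(nrow(f))
  f$unique_split_fraction <- runif(nrow(f))
  f$breakpoint_offset_dev <- runif(nrow(f), 0, 0.5)
  f$has_unique_split <- sample(c(TRUE, FALSE), nrow(f), TRUE)
  f$homology_score <- runif(nrow(f), 0.4, 1)
  f$valid_insert_ratio <- runif(nrow(f))
  fus <- make_fus(f, support_row("F01", "s1"))
  base <- filter_thresholds()
  pass0 <- apply_filters(fus, base)$fusions$pass
  relaxed <- list(
    filter_thresholds(min_support = 1L),
    filter_thresholds(min_homogeneity = 0.1),
    filter_thresholds(min_unique_split_fraction = 0),
    filter_thresholds(max_breakpoint_offset_dev = 0.5),
    filter_thresholds(max_homology_score = 0.95),
    filter_thresholds(min_valid_insert_ratio = 0.2))
  for (th in relaxed) {
    pass1 <- apply_filters(fus, th)$fusions$pass
    expect_true(all(pass1[pass0]))
  }
})

test_that("duplicate fusions within the merge radius collapse to one", {
  f <- rbind(fusion_row("F1", c5 = 1L, c3 = 2L, n_split = 7L, n_bridge = 1L),
             fusion_row("F2", c5 = 3L, c3 = 4L, bp5 = 1013L, bp3 = 5013L,
                        n_split = 5L, n_bridge = 9L))
  s <- rbind(
    do.call(rbind, lapply(1:7, function(i)
      support_row("F1", paste0("a", i), read = paste0("a", i)))),
    support_row("F1", "ab", type = "bridge", read = "ab"),
    do.call(rbind, lapply(1:5, function(i)
      support_row("F2", paste0("c", i), read = paste0("c", i)))),
    do.call(rbind, lapply(1:9, function(i)
      support_row("F2", paste0("cb", i), type = "bridge",
                  read = paste0("cb", i)))))
  out <- merge_duplicate_fusions(make_fus(f, s))
  expect_equal(nrow(out$fusions), 1L)
  # the SPLIT-richer breakpoint pair wins
  expect_equal(out$fusions$fusion_id, "F1")
  expect_equal(out$fusions$n_split, 12L)
  expect_equal(out$fusions$n_bridge, 10L)
  # far-apart fusions are untouched
  f2 <- f; f2$bp_5p[2] <- 3000L
  expect_equal(nrow(merge_duplicate_fusions(make_fus(f2, s))$fusions), 2L)
})
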