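drp_at <- function(pos, strand = "+", sample = "S1", cons = "ALU") {
  data.table::data.table(
    sample = sample, qname = sprintf("q%06d", seq_along(pos) + sample(1e5, 1L)),
    chrom = "chr1", pos = as.integer(pos), end = as.integer(pos) + 100L,
    strand = rep_len(strand, length(pos)), mapq = 60L, seq = strrep("A", 100L),
    cons = cons, c_start = 0L, c_end = 100L, c_strand = "+",
    identity = 1, score = 200L, qstart = 0L, qend = 100L,
    aln = substring(TEST_LIB$ALU$seq, 1L, 100L))
}

test_that("cluster_drps implements the >= 4 DRP single-linkage rule", {
  r1 <- cluster_drps(drp_at(c(100, 150, 220, 380)), window = 500L)
  expect_equal(nrow(r1$sites), 1L)
  expect_equal(r1$sites$n_drp, 4L)
  r2 <- cluster_drps(drp_at(c(100, 150, 220)), window = 500L)
  expect_equal(nrow(r2$sites), 0L)
  r3 <- cluster_drps(drp_at(c(100, 150, 200, 260, 1500, 1540, 1600, 1680)),
                     window = 500L)
  ## gap 1500 - 260 > 500 splits; both halves reach 4
  expect_equal(nrow(r3$sites), 2L)
  expect_equal(r3$sites$n_drp, c(4L, 4L))
})

test_that("clustering matches a brute-force single-linkage oracle", {
  set.seed(77)
  for (rep in 1:25) {
    n <- sample(2:50, 1L)
    pos <- sort(sample.int(20000L, n))
    window <- sample(c(100L, 300L, 500L), 1L)
    got <- cluster_drps(drp_at(pos), window = window, min_drp = 1L)
    oracle <- oracle_single_linkage(pos, window)
    ## same partition: sizes of clusters in position order must agree
    got_sizes <- got$drp[, .N, by = site_id][order(site_id)]$N
    oracle_sizes <- as.integer(table(factor(oracle, levels = unique(oracle))))
    expect_equal(sort(got_sizes), sort(oracle_sizes))
  }
})

mk_summary <- function(len = 100000L, depth = 30L) {
  list(S1 = list(coverage = list(chr1 = S4Vectors::Rle(depth, len)),
                 median_depth = c(chr1 = depth),
                 frag_mean = 500, frag_sd = 50, read_len = 100L))
}

test_that("filter_candidates flags refME, depth and clean sites", {
  cl <- cluster_drps(rbind(drp_at(c(4600, 4650), "+"), drp_at(c(5120, 5180), "-")))
  site <- cl$sites
  ## same-class reference Alu 30 bp from the insertion interval
  near_me <- data.table::data.table(chrom = "chr1", start = 5150L, end = 5450L,
                                    label = "ALU")
  expect_equal(filter_candidates(site, near_me, NULL, mk_summary()), "refME")
  ## different class does not trigger the flag
  near_l1 <- data.table::copy(near_me)[, label := "LINE1"]
  expect_equal(filter_candidates(site, near_l1, NULL, mk_summary()), "")
  ## no annotations at median depth: retained
  expect_equal(filter_candidates(site, NULL, NULL, mk_summary()), "")
  ## 3x median depth over the window
  hot <- mk_summary(); hot$S1$coverage$chr1 <- S4Vectors::Rle(90L, 100000L)
  expect_equal(filter_candidates(site, NULL, NULL, hot), "depth")
  ## gap mask padded by a fragment length
  gap <- data.table::data.table(chrom = "chr1", start = 5400L, end = 6000L,
                                label = "gap")
  expect_equal(filter_candidates(site, NULL, gap, mk_summary()), "mask")
  expect_error(filter_candidates(site, NULL, NULL, NULL), "coverage")
})

sr_at <- function(pos, side, n = 3L, clip_seq = strrep("A", 30L)) {
  data.table::data.table(
    sample = "S1", qname = sprintf("s%06d", sample(1e5, n)), chrom = "chr1",
    clip_pos = as.integer(rep(pos, n)), side = side, clip_seq = clip_seq,
    cons = NA_character_, c_start = NA_integer_, c_end = NA_integer_,
    c_strand = NA_character_, identity = NA_real_, score = NA_integer_,
    qstart = NA_integer_, qend = NA_integer_, aln = NA_character_)
}

test_that("refine_breakpoint recovers TSDs, blunt joints and midpoints", {
  ref <- c(chr1 = random_dna_str(20000L, seed = 5))
  cl <- cluster_drps(rbind(drp_at(c(9500, 9550), "+"), drp_at(c(10050, 10100), "-")))
  site <- cl$sites; drps <- cl$drp
  ## left SR cluster at 10,015, right at 10,003: 12-bp duplication
  srs <- rbind(sr_at(10015L, "R"), sr_at(10003L, "L"))
  srs[, site_id := site$site_id]
  got <- refine_breakpoint(site, drps, srs, ref)
  expect_equal(got$pos, 10003L)
  expect_equal(got$tsd, substring(ref[["chr1"]], 10004L, 10015L))
  expect_equal(nchar(got$tsd), 12L)
  ## bpL = bpR: blunt
  srs2 <- rbind(sr_at(7000L, "R"), sr_at(7000L, "L"))
  srs2[, site_id := site$site_id]
  got2 <- refine_breakpoint(site, drps, srs2, ref)
  expect_equal(got2$pos, 7000L)
  expect_true(got2$blunt)
  expect_equal(got2$tsd, "")
  ## bpL < bpR: target-site deletion
  srs3 <- rbind(sr_at(9995L, "R"), sr_at(10003L, "L"))
  srs3[, site_id := site$site_id]
  got3 <- refine_breakpoint(site, drps, srs3, ref)
  expect_equal(got3$pos, 9995L)
  expect_equal(got3$tsdel, 8L)
  ## no SRs: midpoint between innermost anchors
  site2 <- data.table::copy(site)
  site2[, `:=`(left_max_end = 10000L, right_min_start = 10040L)]
  got4 <- refine_breakpoint(site2, drps, srs[0L], ref)
  expect_equal(got4$pos, 10020L)
  expect_error(refine_breakpoint(site, drps[0L], srs, ref), "no DRPs")
})

test_that("assess_tranche maps evidence to the 0-5 scale", {
  ref5 <- list(n_srL = 3L, n_srR = 3L, tsd = "ACGTACGTACGT", tsdel = 0L,
               agreeL = 1, agreeR = 1)
  expect_equal(assess_tranche(ref5, 2L, 2L), 5L)
  ref4 <- list(n_srL = 3L, n_srR = 3L, tsd = "", tsdel = 0L,
               agreeL = 1, agreeR = 1)
  expect_equal(assess_tranche(ref4, 2L, 2L), 4L)
  ref3 <- list(n_srL = 3L, n_srR = 0L, tsd = "", tsdel = 0L,
               agreeL = 1, agreeR = NA_real_)
  expect_equal(assess_tranche(ref3, 2L, 2L), 3L)
  ref2 <- list(n_srL = 0L, n_srR = 0L, tsd = "", tsdel = 0L,
               agreeL = NA_real_, agreeR = NA_real_)
  expect_equal(assess_tranche(ref2, 2L, 2L), 2L)
  expect_equal(assess_tranche(ref2, 2L, 0L), 1L)
  expect_equal(assess_tranche(ref2, 0L, 0L), 0L)
})

test_that("merge_samples pools evidence and rejects duplicate samples", {
  ev1 <- list(sample = "S1", drp = drp_at(c(100, 160), sample = "S1"),
              sr = sr_at(150L, "R", 1L)[, sample := "S1"],
              summary = mk_summary()$S1)
  ev2 <- list(sample = "S2", drp = drp_at(c(130, 190), sample = "S2"),
              sr = sr_at(150L, "L", 1L)[, sample := "S2"],
              summary = mk_summary()$S1)
  pool <- merge_samples(list(ev1, ev2))
  expect_equal(nrow(pool$drp), 4L)
  ## pooled evidence reaches the 4-DRP threshold; each sample alone does not
  expect_equal(nrow(cluster_drps(pool$drp)$sites), 1L)
  expect_equal(nrow(cluster_drps(ev1$drp)$sites), 0L)
  expect_equal(nrow(cluster_drps(ev2$drp)$sites), 0L)
  ## one sample: identity
  one <- merge_samples(list(ev1))
  expect_equal(one$drp, ev1$drp[order(chrom, pos)])
  expect_error(merge_samples(list(ev1, ev1)), "duplicate")
})

test_that("TSD strings are exact reference substrings at the breakpoint", {
  sm <- small_sim()
  ref <- sm$ref$seqs[["chr1"]]
  with_tsd <- sm$disc$calls[nzchar(tsd)]
  expect_gt(nrow(with_tsd), 0L)
  for (i in seq_len(nrow(with_tsd))) {
    cl <- with_tsd[i]
    expect_equal(cl$tsd, substring(ref, cl$pos + 1L, cl$pos + nchar(cl$tsd)))
  }
})

test_that("adding a DRP to a retained site never removes it", {
  base <- drp_at(c(100, 150, 220, 380))
  r1 <- cluster_drps(base)
  expect_equal(nrow(r1$sites), 1L)
  for (extra_pos in c(50L, 250L, 700L)) {
    r2 <- cluster_drps(rbind(base, drp_at(extra_pos)))
    expect_gte(nrow(r2$sites), 1L)
    expect_gte(max(r2$sites$n_drp), 4L)
  }
})
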