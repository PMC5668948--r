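test_that("synthesize_element applies features deterministically", {
  spec <- manual_specs(1000L, class = "ALU", subfamily = "AluY", polya = 20L)
  el <- synthesize_element(as.list(spec[1L]), TEST_LIB)
  expect_equal(el, paste0(TEST_LIB$ALU$seq, strrep("A", 20L)))
  ## truncation arithmetic on the 6019-bp consensus
  spec2 <- manual_specs(1000L, class = "LINE1", subfamily = "L1",
                        trunc = 4000L, polya = 15L)
  el2 <- synthesize_element(as.list(spec2[1L]), TEST_LIB)
  expect_equal(nchar(el2), 2019L + 15L)
  ## invalid: junction inside the truncated part
  spec3 <- manual_specs(1000L, class = "LINE1", subfamily = "L1",
                        trunc = 1000L, junction = 900L)
  expect_error(synthesize_element(as.list(spec3[1L]), TEST_LIB), "junction")
})

test_that("5' inversion reverse-complements [trunc, junction)", {
  spec <- manual_specs(1000L, class = "LINE1", subfamily = "L1",
                       trunc = 1000L, junction = 2500L, polya = 10L)
  el <- synthesize_element(as.list(spec[1L]), TEST_LIB)
  ## independent re-derivation by direct string operations
  cons <- TEST_LIB$LINE1$seq
  kept <- substring(cons, 1001L, 6019L)
  seg <- substring(kept, 1L, 1500L)        # [1000, 2500) of the consensus
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", seg), "")[[1L]]), collapse = "")
  expected <- paste0(rc, substring(kept, 1501L), strrep("A", 10L))
  expect_equal(el, expected)
})

test_that("planting realises TSDs and is byte-identical under a fixed seed", {
  cfg <- sim_config(ref_len = 200000L, counts = c(ALU = 3), seed = 31,
                    n_ref_alu = 0L, n_ref_l1 = 0L, n_fl_l1 = 0L)
  ref <- make_reference(cfg, TEST_LIB)
  specs <- manual_specs(pos = c(20000L, 60000L, 100000L), tsd_len = 12L,
                        zygosity = "hom")
  p1 <- plant_insertions(ref, specs, TEST_LIB)
  p2 <- plant_insertions(ref, specs, TEST_LIB)
  expect_identical(p1$haps[[1L]]$seq, p2$haps[[1L]]$seq)
  expect_identical(p1$haps[[1L]]$seq, p1$haps[[2L]]$seq)  # hom: both haplotypes
  ## the 12-bp flank appears twice, bracketing the element
  flank <- substring(ref$seqs[["chr1"]], 20001L, 20012L)
  el_len <- p1$truth$elem_len[1L]
  hap <- p1$haps[[1L]]$seq
  i1 <- regexpr(flank, hap, fixed = TRUE)[[1L]]
  expect_equal(i1, 20001L - 12L + 12L)  # first copy ends the left flank
  expect_equal(substring(hap, 20001L, 20012L), flank)
  expect_equal(substring(hap, 20001L + 12L + el_len, 20012L + 12L + el_len), flank)
  ## determinism of the full generator
  s1 <- simulate_dataset(sim_config(ref_len = 100000L, counts = c(ALU = 2),
                                    seed = 77))
  s2 <- simulate_dataset(sim_config(ref_len = 100000L, counts = c(ALU = 2),
                                    seed = 77))
  expect_identical(s1$planted$haps[[1L]]$seq, s2$planted$haps[[1L]]$seq)
  expect_identical(s1$aln$seq, s2$aln$seq)
})

test_that("simulated coverage and error-free substring property hold", {
  cfg <- sim_config(ref_len = 150000L, counts = c(ALU = 1), coverage = 30,
                    seed = 41)
  sim <- simulate_dataset(cfg)
  total_bases <- nrow(sim$aln) * cfg$read_len
  ## diploid genome: total sequenced bases over one haploid length
  cov <- total_bases / nchar(sim$ref$seqs[["chr1"]])
  expect_gte(cov, 29); expect_lte(cov, 31)
  ## every stored sequence is an exact substring of a haplotype or its
  ## reverse complement (zero base error)
  haps <- c(sim$planted$haps[[1L]]$seq, sim$planted$haps[[2L]]$seq)
  idx <- seq(1L, nrow(sim$aln), length.out = 200L)
  for (s in sim$aln$seq[idx]) {
    hitf <- any(vapply(haps, function(h) grepl(s, h, fixed = TRUE), NA))
    hitr <- any(vapply(haps, function(h) grepl(revcomp(s), h, fixed = TRUE), NA))
    expect_true(hitf || hitr)
  }
})

test_that("down-sampling 60x to 7.5x keeps ~1/8 of fragments", {
  cfg <- sim_config(ref_len = 400000L, counts = c(ALU = 1), coverage = 60,
                    seed = 51)
  ref <- make_reference(cfg, TEST_LIB)
  planted <- plant_insertions(ref, manual_specs(50000L), TEST_LIB)
  frags <- simulate_reads(planted, cfg)
  kept <- downsample_fragments(frags, 60, 7.5, seed = 51)
  expect_lte(abs(nrow(kept) / nrow(frags) - 0.125), 0.01)
  expect_error(simulate_reads(planted, sim_config(frag_mean = 150L)), "twice")
})

test_that("project_alignments lifts reads and clips at breakpoints", {
  cfg <- sim_config(ref_len = 120000L, counts = c(ALU = 1), seed = 61,
                    n_ref_alu = 0L, n_ref_l1 = 0L, n_fl_l1 = 0L)
  ref <- make_reference(cfg, TEST_LIB)
  specs <- manual_specs(pos = 50000L, tsd_len = 10L, zygosity = "hom")
  planted <- plant_insertions(ref, specs, TEST_LIB)
  ## fragment fully left of the insertion: 100M at the identity coordinate
  frags <- data.table::data.table(hap = 1L, fstart = 10000L, fend = 10500L,
                                  qname = "f1")
  al <- project_alignments(frags, planted, ref, TEST_LIB, cfg)
  expect_equal(al$cigar, c("100M", "100M"))
  expect_equal(sort(al$pos), c(10000L, 10400L))
  expect_true(all(al$proper))
  ## read crossing the left breakpoint with 40 element bases: 60M40S
  ## donor left junction is at pos + tsd = 50,010
  bp <- 50010L
  frags2 <- data.table::data.table(hap = 1L, fstart = bp - 60L,
                                   fend = bp - 60L + 500L, qname = "f2")
  al2 <- project_alignments(frags2, planted, ref, TEST_LIB, cfg)
  r1 <- al2[al2$first == TRUE]
  expect_equal(r1$cigar, "60M40S")
  expect_equal(r1$pos, bp - 60L)
  ## independent liftover check of the mate: element is 281 + 20 polyA + TSD;
  ## fragment end lands back in reference sequence
  elem_len <- planted$truth$elem_len[1L]
  mate <- al2[al2$first == FALSE]
  if (mate$chrom == "chr1") {
    donor_end <- bp - 60L + 500L
    expected_ref <- donor_end - 100L - elem_len - 10L  # unwind insert + TSD copy
    expect_equal(mate$pos, as.integer(expected_ref))
  }
  ## straddling pair: anchor on chr1, mate on the decoy => DRP candidate
  frags3 <- data.table::data.table(hap = 1L, fstart = bp - 220L,
                                   fend = bp - 220L + 500L, qname = "f3")
  al3 <- project_alignments(frags3, planted, ref, TEST_LIB, cfg)
  expect_setequal(al3$chrom, c("chr1", "ALU"))
  a <- as.list(al3[1L]); b <- as.list(al3[2L])
  expect_equal(classify_pair(a, b), "DRP_CANDIDATE")
})

test_that("evaluate_calls applies the +/- 500 bp class-matched rule", {
  truth <- data.table::data.table(chrom = "chr1", pos = c(1e4L, 5e4L),
                                  class = "ALU")
  exact <- data.table::data.table(chrom = "chr1", pos = c(1e4L, 5e4L),
                                  class = "ALU")
  r <- evaluate_calls(exact, truth)
  expect_equal(r[class == "ALU"]$FNR, 0)
  expect_equal(r[class == "ALU"]$FDR, 0)
  ## 499 bp away: still a TP
  near <- data.table::data.table(chrom = "chr1", pos = c(1e4L + 499L), class = "ALU")
  r2 <- evaluate_calls(near, truth)
  expect_equal(r2[class == "ALU"]$TP, 1L)
  ## 501 bp away: one FP and one FN
  far <- data.table::data.table(chrom = "chr1", pos = c(1e4L + 501L), class = "ALU")
  r3 <- evaluate_calls(far, truth)
  expect_equal(r3[class == "ALU"]$FP, 1L)
  expect_equal(r3[class == "ALU"]$FN, 2L)
  ## class mismatch never matches
  wrong <- data.table::data.table(chrom = "chr1", pos = 1e4L, class = "LINE1")
  r4 <- evaluate_calls(wrong, truth)
  expect_equal(r4[class == "LINE1"]$FP, 1L)
})
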