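test_that("genotype_likelihoods matches the closed form on the spec cases", {
  ## a=0, b=10: L(0) = 0.99^10 dominates L(1) = 0.5^10
  g <- genotype_likelihoods(0L, 10L, e = 0.01)
  expect_equal(g$gt, "0/0")
  o <- oracle_genotype(0, 10, 0.01)
  expect_equal(as.numeric(strsplit(g$gl, ",")[[1L]]), round(o$ll, 2))
  expect_equal(o$ll[1L], 0)
  expect_equal(10^(o$ll[2L] - o$ll[1L]), 0.5^10 / 0.99^10, tolerance = 1e-6)
  ## a=5, b=5: the heterozygote dominates
  expect_equal(genotype_likelihoods(5L, 5L, e = 0.01)$gt, "0/1")
  ## no evidence: no-call
  g0 <- genotype_likelihoods(0L, 0L)
  expect_equal(g0$gt, "./.")
  expect_equal(g0$gl, "0,0,0")
})

test_that("genotype_likelihoods equals the oracle over an (a, b, e) grid", {
  grid <- expand.grid(a = c(0L, 1L, 2L, 5L, 10L, 30L),
                      b = c(0L, 1L, 2L, 5L, 10L, 30L),
                      e = c(0.005, 0.01, 0.05))
  for (i in seq_len(nrow(grid))) {
    a <- grid$a[i]; b <- grid$b[i]; e <- grid$e[i]
    got <- genotype_likelihoods(a, b, e)
    if (a + b < 2L) {
      expect_equal(got$gt, "./.")
      next
    }
    o <- oracle_genotype(a, b, e)
    expect_equal(got$gt, o$gt, info = sprintf("a=%d b=%d e=%g", a, b, e))
    expect_equal(as.numeric(strsplit(got$gl, ",")[[1L]]), round(o$ll, 2))
    expect_equal(max(as.numeric(strsplit(got$gl, ",")[[1L]])), 0)
  }
})

test_that("with b fixed, increasing a never reduces the called alt copies", {
  rank_gt <- c("0/0" = 0L, "0/1" = 1L, "1/1" = 2L)
  for (b in c(0L, 3L, 10L, 25L)) {
    prev <- -1L
    for (a in 0:40) {
      g <- genotype_likelihoods(a, b, e = 0.01, min_informative = 0L)
      expect_gte(rank_gt[[g$gt]], prev)
      prev <- rank_gt[[g$gt]]
    }
  }
})

test_that("count_evidence separates het, hom and absent sites", {
  zs <- zygosity_sim()
  disc <- discover_sites(merge_samples(list(zs$ev)), zs$ref$seqs, NULL, NULL)
  cnt <- count_evidence(disc$calls, zs$aln, disc$drp, disc$sr)
  near <- vapply(disc$calls$pos, function(p)
    which.min(abs(zs$specs$pos - p)), 0L)
  zyg <- zs$specs$zygosity[near]
  ## hom-alt: no clean spanners (b ~ 0 within noise)
  expect_lte(max(cnt$b[zyg == "hom"]), 2L)
  ## het: both alleles sampled at every site
  expect_true(all(cnt$a[zyg == "het"] > 0L))
  expect_true(all(cnt$b[zyg == "het"] > 0L))
  ## a sample without the insertions has zero alt support
  cfg0 <- zs$cfg
  planted0 <- plant_insertions(zs$ref, manual_specs(pos = integer(0)), TEST_LIB)
  aln0 <- project_alignments(simulate_reads(planted0, cfg0), planted0, zs$ref,
                             TEST_LIB, cfg0, sample = "S2")
  cnt0 <- count_evidence(disc$calls, aln0,
                         disc$drp[sample == "S2"], disc$sr[sample == "S2"])
  expect_true(all(cnt0$a == 0L))
  expect_true(all(cnt0$b > 0L))
})

test_that("site filters: hNC, noSR, lc and PASS semantics", {
  calls <- data.table::data.table(
    site_id = c("m1", "m2", "m3"), chrom = "chr1", pos = c(1e3L, 2e3L, 3e3L),
    filters = "", n_left = c(3L, 3L, 3L), n_right = c(3L, 3L, 0L),
    n_srL = c(0L, 4L, 4L), n_srR = c(0L, 4L, 0L))
  gts <- data.table::CJ(site_id = calls$site_id, sample = sprintf("S%d", 1:4))
  gts[, gt := "0/1"]
  gts[site_id == "m1" & sample %in% c("S1", "S2"), gt := "./."]
  got <- apply_site_filters(calls, gts)
  expect_setequal(strsplit(got$filters[1L], ",")[[1L]], c("hNC", "noSR"))
  expect_equal(got$filters[2L], "")          # PASS
  expect_equal(got$filters[3L], "lc")
})

test_that("reference-ME deletions genotype correctly by zygosity", {
  dcfg <- sim_del_config(ref_len = 400000L, del_counts = c(ALU = 6, LINE1 = 2),
                         seed = 5)
  dsim <- simulate_deletion_dataset(dcfg)
  dg <- genotype_deletions(dsim$ref$ref_me, list(S1 = dsim$aln))
  gt <- dg$genotypes
  truth_gt <- rep("0/0", nrow(dsim$ref$ref_me))
  idx <- match(dsim$truth$start, dsim$ref$ref_me$start)
  truth_gt[idx] <- ifelse(dsim$truth$zygosity == "het", "0/1", "1/1")
  expect_equal(gt$gt, truth_gt)
  ## intervals shorter than two read lengths are not assessable
  short <- list(chrom = "chr1", start = 1000L, end = 1150L)
  expect_warning(g <- genotype_deletion(short, dsim$aln), "not assessable")
  expect_equal(g$gt, "./.")
})

test_that("het deletions are recovered at 30x across many seeded sites", {
  ## >= 50 seeded site x sample pairs, all het
  dcfg <- sim_del_config(ref_len = 1500000L, del_counts = c(ALU = 52),
                         het_frac = 1, seed = 13)
  dsim <- simulate_deletion_dataset(dcfg)
  dels <- dsim$ref$ref_me[dsim$truth, on = c("chrom", "start", "end")]
  dg <- genotype_deletions(dsim$truth[, .(chrom, start, end, label)],
                           list(S1 = dsim$aln))
  expect_gte(nrow(dg$genotypes), 50L)
  expect_gte(mean(dg$genotypes$gt == "0/1"), 0.95)
})
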