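test_that("SAM round trip is the identity on modeled fields", {
  rows <- c(pair_rows("r1", "chr1", 100L, 400L),
            pair_rows("r2", "chr1", 150L, 450L),
            pair_rows("r3", "chr1", 900L, 1200L))
  aln <- tiny_aln(rows)
  path <- withr::local_tempfile(fileext = ".sam")
  write_sam(aln, path)
  back <- read_alignments(path)
  expect_equal(nrow(back), 6L)
  for (cn in c("qname", "chrom", "pos", "strand", "mapq", "cigar", "seq",
               "mchrom", "mpos", "proper", "unmapped", "first"))
    expect_equal(back[[cn]], aln[[cn]], info = cn)
  expect_equal(attr(back, "seqlengths"), attr(aln, "seqlengths"))
  ## position order
  expect_true(!is.unsorted(back$pos))
})

test_that("read_alignments honours a region restriction", {
  rows <- c(pair_rows("r1", "chr1", 50L, 400L),
            pair_rows("r2", "chr1", 5000L, 5300L))
  path <- withr::local_tempfile(fileext = ".sam")
  write_sam(tiny_aln(rows), path)
  got <- read_alignments(path, region = list(chrom = "chr1", start = 100L, end = 200L))
  ## only r1's first mate (50..150) overlaps [100, 200)
  expect_equal(got$qname, "r1")
  expect_equal(got$pos, 50L)
})

test_that("CIGAR/sequence mismatch is a parse error naming the record", {
  path <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate", "@SQ\tSN:chr1\tLN:1000",
               paste("bad", 0, "chr1", 1, 60, "90M", "*", 0, 0,
                     strrep("A", 100), "*", sep = "\t")), path)
  expect_error(read_alignments(path), "record 1")
})

test_that("BED conventions: half-open intervals, labels, errors", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t10\t20\tAluYa5", path)
  iv <- read_intervals(path)
  expect_equal(iv, data.table::data.table(chrom = "chr1", start = 10L,
                                          end = 20L, label = "AluYa5"))
  writeLines(character(0), path)
  expect_equal(nrow(read_intervals(path)), 0L)
  writeLines("chr1\t20\t10", path)
  expect_error(read_intervals(path), "start >= end")
})

make_call_row <- function(pos = 5000L, tsd = "ACTG") data.table::data.table(
  site_id = "mei_0001", chrom = "chr1", pos = pos, class = "ALU",
  orientation = "+", cons_start = 0L, cons_stop = 281L, svlen = 300L,
  tsd = tsd, tsdel = 0L, tranche = 5L, filters = "", subfamily = "AluYa5s",
  mutations = "c12t,g40a*", inv5 = FALSE, inv_junction = NA_integer_,
  tdn_locus = "", tdn_source = "", gene_impact = "intergenic")

make_gt_rows <- function(samples) data.table::data.table(
  site_id = "mei_0001", sample = samples, gt = c("0/1", "0/0")[seq_along(samples)],
  gl = "0,-5.2,-20.1", gq = 52L, ad_ref = 10L, ad_alt = 8L)

test_that("VCF writer: shape, TSD round trip, empty file", {
  calls <- make_call_row()
  gts <- make_gt_rows(c("S1", "S2"))
  lines <- write_vcf(calls, gts, c("S1", "S2"))
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, 1L)
  expect_length(strsplit(body, "\t")[[1L]], 11L)
  expect_match(body, "TSD=ACTG")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(lines, path)
  back <- read_vcf(path)
  expect_equal(back$samples, c("S1", "S2"))
  for (cn in names(calls))
    expect_equal(back$calls[[cn]], calls[[cn]], info = cn)
  expect_equal(back$genotypes$gt, gts$gt)
  expect_equal(back$genotypes$ad_alt, gts$ad_alt)
  ## zero calls: valid header-only VCF
  empty <- write_vcf(calls[0L], gts[0L], c("S1", "S2"))
  expect_true(all(startsWith(empty, "#")))
  expect_match(empty[1L], "fileformat=VCFv4.2", fixed = TRUE)
})

test_that("VCF writer rejects unsorted calls and genotype mismatches", {
  calls <- rbind(make_call_row(pos = 9000L),
                 make_call_row(pos = 100L)[, site_id := "mei_0002"])
  gts <- make_gt_rows("S1")
  expect_error(write_vcf(calls, gts, "S1"), "sorted")
  expect_error(write_vcf(make_call_row(), make_gt_rows("S1"), c("S1", "S2")),
               "every call")
})

test_that("written VCF parses under an independent VCF 4.2 reader", {
  skip_if_not_installed("VariantAnnotation")
  sm <- small_sim()
  cfg <- mei_config(list(S1 = sm$aln), sm$ref$seqs, library = TEST_LIB,
                    ref_mes = sm$ref$ref_me)
  res <- run_pipeline(cfg)
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(res$vcf, path)
  v <- VariantAnnotation::readVcf(path)
  expect_equal(nrow(v), nrow(res$calls))
  expect_equal(as.character(SummarizedExperiment::rowRanges(v)$ALT@unlistData),
               sprintf("<INS:ME:%s>", res$calls$class))
  gt <- VariantAnnotation::geno(v)$GT
  expect_equal(unname(gt[, "S1"]), res$genotypes$gt)
})

test_that("evidence bundles round-trip through their TSV serialisation", {
  sm <- small_sim()
  stem <- withr::local_tempfile()
  write_evidence(sm$ev, stem)
  back <- read_evidence(stem)
  expect_equal(back$sample, sm$ev$sample)
  expect_equal(back$drp$pos, sm$ev$drp$pos)
  expect_equal(back$sr$clip_pos, sm$ev$sr$clip_pos)
  expect_equal(back$summary$median_depth[["chr1"]],
               sm$ev$summary$median_depth[["chr1"]])
  expect_equal(as.integer(S4Vectors::runValue(back$summary$coverage$chr1)),
               as.integer(S4Vectors::runValue(sm$ev$summary$coverage$chr1)))
})
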