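## build consensus-space evidence rows directly (alignment strings laid out
## in consensus coordinates)
ev_rows <- function(entry, c_start, c_end, c_strand = "+", mut = NULL,
                    tail = "") {
  n <- length(c_start)
  aln <- vapply(seq_len(n), function(i) {
    s <- substring(entry$seq, c_start[i] + 1L, c_end[i])
    if (!is.null(mut)) {
      ch <- strsplit(s, "")[[1L]]
      for (k in seq_len(nrow(mut))) {
        o <- mut$pos[k] - c_start[i]
        if (o >= 0L && o < length(ch)) ch[o + 1L] <- mut$alt[k]
      }
      s <- paste(ch, collapse = "")
    }
    s
  }, "")
  data.table::data.table(
    sample = "S1", qname = sprintf("e%05d", seq_len(n)), chrom = "chr1",
    pos = 1000L, end = 1100L, strand = "+", mapq = 60L,
    seq = paste0(aln, rep_len(tail, n)), cons = entry$name,
    c_start = as.integer(c_start), c_end = as.integer(c_end),
    c_strand = rep_len(c_strand, n), identity = 1, score = 200L,
    qstart = 0L, qend = nchar(aln), aln = aln)
}

no_sr <- function() empty_sr_tbl()
empty_sr_tbl <- function() {
  s <- sr_fixture(0L)
  s
}
sr_fixture <- function(n) data.table::data.table(
  sample = character(n), qname = character(n), chrom = character(n),
  clip_pos = integer(n), side = character(n), clip_seq = character(n),
  cons = character(n), c_start = integer(n), c_end = integer(n),
  c_strand = character(n), identity = numeric(n), score = integer(n),
  qstart = integer(n), qend = integer(n), aln = character(n))

test_that("build_pileup reports span, truncation and single-alignment width", {
  l1 <- TEST_LIB$LINE1
  pu <- build_pileup(ev_rows(l1, c(500, 3000, 5919), c(600, 3100, 6019)),
                     no_sr(), l1)
  expect_equal(pu$span, c(500L, 6019L))
  expect_true(pu$truncated5)
  pu2 <- build_pileup(ev_rows(l1, 0, 100), no_sr(), l1)
  expect_false(pu2$truncated5)
  pu3 <- build_pileup(ev_rows(l1, 1000, 1050), no_sr(), l1)
  expect_equal(pu3$svlen, 50L)
})

test_that("interior mutations need depth >= 3 and alt fraction >= 0.7", {
  alu <- TEST_LIB$ALU
  mut <- data.table::data.table(pos = 104L, alt = "T")
  stopifnot(substring(alu$seq, 105L, 105L) != "T")
  ## 30 reads covering the mutation
  drps <- ev_rows(alu, rep(50L, 30L), rep(180L, 30L), mut = mut)
  prof <- call_interior_mutations(build_pileup(drps, no_sr(), alu), alu)
  expect_equal(prof$pos, 104L)
  expect_equal(prof$alt, "T")
  expect_equal(prof$ref, substring(alu$seq, 105L, 105L))
  ## no mutations planted: empty profile
  clean <- call_interior_mutations(
    build_pileup(ev_rows(alu, rep(0L, 10L), rep(281L, 10L)), no_sr(), alu), alu)
  expect_equal(nrow(clean), 0L)
  ## depth 2 with alt fraction 1.0: below the depth threshold
  thin <- call_interior_mutations(
    build_pileup(ev_rows(alu, rep(50L, 2L), rep(180L, 2L), mut = mut),
                 no_sr(), alu), alu)
  expect_equal(nrow(thin), 0L)
})

test_that("assign_subfamily scores diagnostics and handles missing depth", {
  alu <- TEST_LIB$ALU
  ya <- alu$profiles$AluYa5s   # 5 diagnostics
  full <- data.table::data.table(pos = ya$pos, ref = ya$ref, alt = ya$alt,
                                 cpg = FALSE)
  got <- assign_subfamily(full, alu)
  expect_equal(got$subfamily, "AluYa5s")
  expect_equal(got$score, 5)
  ## empty profile: root family
  emptyp <- full[0L]
  expect_equal(assign_subfamily(emptyp, alu)$subfamily, "AluY")
  ## 3 of 5 present, other 2 at zero depth: score stays 3
  part <- full[1:3]
  assessable <- setdiff(0:280, ya$pos[4:5])
  got3 <- assign_subfamily(part, alu, assessable = assessable)
  expect_equal(got3$subfamily, "AluYa5s")
  expect_equal(got3$score, 3)
  ## with those positions assessable the penalty applies
  got4 <- assign_subfamily(part, alu, assessable = 0:280)
  expect_equal(got4$score, 3 - 0.5 * 2)
})

test_that("novel subfamilies need >= 5 copies of a non-CpG key", {
  mk_calls <- function(n, muts) data.table::data.table(
    site_id = sprintf("mei_%02d", seq_len(n)), class = "ALU", chrom = "chr1",
    pos = seq_len(n) * 10000L, mutations = muts)
  key <- "c103t,g201a"   # not a diagnostic of any bundled subfamily
  alu <- TEST_LIB$ALU
  stopifnot(!any(c("103>T", "201>A") %in% meiscan:::known_diagnostics(alu)))
  got5 <- discover_novel_subfamilies(mk_calls(5L, key), TEST_LIB)
  expect_equal(nrow(got5), 1L)
  expect_equal(got5$n, 5L)
  expect_equal(nrow(discover_novel_subfamilies(mk_calls(4L, key), TEST_LIB)), 0L)
  ## an extra CpG-site mutation in two calls does not split the group
  cpg_pos <- alu$cpg[10L]
  muts6 <- c(rep(key, 4L),
             rep(sprintf("%s,a%dg*", key, cpg_pos), 2L))
  got6 <- discover_novel_subfamilies(mk_calls(6L, muts6), TEST_LIB)
  expect_equal(nrow(got6), 1L)
  expect_equal(got6$n, 6L)
})

test_that("detect_inversion finds twin-priming junctions and assessability", {
  l1 <- TEST_LIB$LINE1
  ## inverted 5' segment [0, 2500) on the opposite strand
  drps <- rbind(ev_rows(l1, c(2100, 2200, 2300), c(2400, 2450, 2500), "-"),
                ev_rows(l1, c(2500, 2600, 5000), c(2700, 2800, 5200), "+"))
  got <- detect_inversion(drps, no_sr(), l1, orientation = "+")
  expect_true(got$assessable)
  expect_true(got$inverted)
  expect_lte(abs(got$junction - 2500L), 50L)
  ## all alignments on one strand: not inverted
  one <- detect_inversion(ev_rows(l1, c(0, 100, 3000, 5900), c(200, 300, 3200, 6019)),
                          no_sr(), l1, "+")
  expect_false(one$inverted)
  expect_true(one$assessable)
  ## element covering only 4000-6019: no 5' evidence, not assessable
  tr <- detect_inversion(ev_rows(l1, c(4000, 4500, 5000, 5500), c(4200, 4700, 5200, 5700)),
                         no_sr(), l1, "+")
  expect_false(tr$assessable)
  expect_true(is.na(tr$junction))
})

test_that("detect_transduction maps unique tags and rejects poly(A)/ambiguity", {
  l1 <- TEST_LIB$LINE1
  ref <- c(chr1 = random_dna_str(60000L, seed = 9))
  src <- data.table::data.table(chrom = "chr1", start = 20000L, end = 26019L,
                                label = "src1", strand = "+")
  tag <- substring(ref[["chr1"]], 26061L, 26180L)   # 120 bp, 40 bp downstream
  tail <- paste0(strrep("A", 15L), tag, strrep("A", 12L))
  drps <- ev_rows(l1, rep(5900L, 4L), rep(6019L, 4L), tail = tail)
  got <- detect_transduction(drps, no_sr(), l1, ref, src, "+")
  expect_equal(got$source, "src1")
  expect_equal(got$locus$start, 26060L)
  expect_true(got$second_polya)
  ## pure poly(A) tail: no call
  pa <- ev_rows(l1, rep(5900L, 4L), rep(6019L, 4L), tail = strrep("A", 40L))
  expect_null(detect_transduction(pa, no_sr(), l1, ref, src, "+"))
  ## tag occurring twice in the reference: ambiguous, no call
  ref2 <- ref
  ref2[["chr1"]] <- paste0(ref2[["chr1"]], tag)
  expect_null(detect_transduction(drps, no_sr(), l1, ref2, src, "+"))
})

test_that("gene impact picks the most severe overlapping feature", {
  genes <- data.table::data.table(
    chrom = "chr1",
    start = c(10000L, 12000L, 14000L),
    end = c(10500L, 12500L, 14500L),
    gene = "g1", strand = "+",
    feature = c("5UTR", "exon", "3UTR"))
  expect_equal(annotate_gene_impact("chr1", 12100L, genes), "exon")
  expect_equal(annotate_gene_impact("chr1", 9500L, genes), "promoter")
  expect_equal(annotate_gene_impact("chr1", 14800L, genes), "terminator")
  expect_equal(annotate_gene_impact("chr1", 11000L, genes), "intron")
  expect_equal(annotate_gene_impact("chr1", 50000L, genes), "intergenic")
  expect_equal(annotate_gene_impact("chr1", 12100L, NULL), "intergenic")
})
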