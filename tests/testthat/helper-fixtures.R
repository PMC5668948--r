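## Shared fixtures: everything is generated in code at test time.
## Expensive simulations are memoised for the session so several test files
## (and several acceptance criteria) reuse one build.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

TEST_LIB <- default_me_library()

## a small end-to-end world: 0.5 Mbp, 8 Alu + 3 L1 + 1 SVA at 30x
small_sim <- function() cached("small_sim", function() {
  cfg <- sim_config(ref_len = 500000L, counts = c(ALU = 8, LINE1 = 3, SVA = 1),
                    coverage = 30, seed = 7)
  sim <- simulate_dataset(cfg)
  ev <- extract_evidence(sim$aln, TEST_LIB)
  disc <- discover_sites(merge_samples(list(ev)), sim$ref$seqs,
                         sim$ref$ref_me, NULL)
  c(sim, list(ev = ev, disc = disc))
})

## a zygosity-controlled world: 10 het + 10 hom Alu, fixed positions
zygosity_sim <- function() cached("zygosity_sim", function() {
  cfg <- sim_config(ref_len = 400000L, counts = c(ALU = 0), coverage = 30,
                    n_ref_alu = 0L, n_ref_l1 = 0L, n_fl_l1 = 0L, seed = 21)
  ref <- make_reference(cfg, TEST_LIB)
  specs <- manual_specs(pos = seq(15000L, by = 18000L, length.out = 20L),
                        class = "ALU",
                        zygosity = rep(c("het", "hom"), each = 10L))
  planted <- plant_insertions(ref, specs, TEST_LIB)
  frags <- simulate_reads(planted, cfg)
  aln <- project_alignments(frags, planted, ref, TEST_LIB, cfg)
  ev <- extract_evidence(aln, TEST_LIB)
  list(cfg = cfg, ref = ref, specs = specs, planted = planted, aln = aln,
       ev = ev)
})

## hand-built insertion specs with full control over features
manual_specs <- function(pos, class = "ALU", zygosity = "het",
                         subfamily = NULL, tsd_len = 12L, polya = 20L,
                         trunc = 0L, junction = NA_integer_,
                         orientation = "+", extra_mut = "",
                         tdn_source = "", tdn_tag = "", polya2 = 0L,
                         haplotype = NULL) {
  n <- length(pos)
  class <- rep_len(class, n); zygosity <- rep_len(zygosity, n)
  if (is.null(subfamily))
    subfamily <- vapply(class, function(cl) names(TEST_LIB[[cl]]$profiles)[1L], "")
  if (is.null(haplotype))
    haplotype <- ifelse(zygosity == "hom", 0L, rep_len(c(1L, 2L), n))
  data.table::data.table(
    class = class, subfamily = rep_len(subfamily, n),
    extra_mut = rep_len(extra_mut, n), trunc = rep_len(as.integer(trunc), n),
    junction = rep_len(as.integer(junction), n),
    tsd_len = rep_len(as.integer(tsd_len), n),
    polya = rep_len(as.integer(polya), n),
    tdn_source = rep_len(tdn_source, n), tdn_tag = rep_len(tdn_tag, n),
    polya2 = rep_len(as.integer(polya2), n),
    zygosity = zygosity, haplotype = haplotype,
    orientation = rep_len(orientation, n),
    chrom = "chr1", pos = as.integer(pos),
    id = sprintf("ins_%04d", seq_len(n)))
}

## minimal hand-built alignment table (paired, proper, 100M unless stated)
tiny_aln <- function(rows, seqlengths = c(chr1 = 100000L)) {
  dt <- data.table::rbindlist(rows, fill = TRUE)
  aln_table(dt, seqlengths)
}

pair_rows <- function(qname, chrom, pos1, pos2, seq1 = strrep("A", 100L),
                      seq2 = strrep("C", 100L), cigar1 = "100M",
                      cigar2 = "100M", proper = TRUE, mapq = 60L,
                      chrom2 = chrom, strand1 = "+", strand2 = "-",
                      unmapped2 = FALSE, sample = "S1") {
  list(
    data.table::data.table(qname = qname, sample = sample, chrom = chrom,
      pos = pos1, strand = strand1, mapq = mapq, cigar = cigar1, seq = seq1,
      mchrom = chrom2, mpos = pos2, mstrand = strand2, first = TRUE,
      proper = proper, unmapped = FALSE, munmapped = unmapped2),
    data.table::data.table(qname = qname, sample = sample, chrom = chrom2,
      pos = pos2, strand = strand2, mapq = mapq, cigar = cigar2, seq = seq2,
      mchrom = chrom, mpos = pos1, mstrand = strand1, first = FALSE,
      proper = proper, unmapped = unmapped2, munmapped = FALSE))
}

## independent single-linkage clustering oracle: merge-any-pair-until-stable
oracle_single_linkage <- function(pos, window) {
  n <- length(pos)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (comp[i] != comp[j] && abs(pos[i] - pos[j]) <= window) {
        comp[comp == comp[j]] <- comp[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

## independent closed-form genotype likelihood oracle
oracle_genotype <- function(a, b, e) {
  p <- c(e, 0.5, 1 - e)
  ll <- a * log10(p) + b * log10(1 - p)
  list(gt = c("0/0", "0/1", "1/1")[which.max(ll)], ll = ll - max(ll))
}

random_dna_str <- function(n, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## the benchmark world of the acceptance criteria: 5 Mbp, default
## NA12878-like scaled counts (200 Alu / 32 L1 / 10 SVA), 30x, zero error
benchmark_sim <- function() cached("benchmark_sim", function() {
  cfg <- sim_config(seed = 1L)
  sim <- simulate_dataset(cfg)
  ev <- extract_evidence(sim$aln, TEST_LIB)
  disc <- discover_sites(merge_samples(list(ev)), sim$ref$seqs,
                         sim$ref$ref_me, NULL)
  ann <- annotate_calls(disc, TEST_LIB, sim$ref$seqs, sim$ref$fl_l1, NULL)
  evs <- list(S1 = list(drp = disc$drp, sr = disc$sr,
                        frag_mean = ev$summary$frag_mean,
                        frag_sd = ev$summary$frag_sd))
  gts <- genotype_samples(ann, evs, list(S1 = sim$aln))
  c(sim, list(ev = ev, disc = disc, ann = ann, gts = gts))
})

## the same genomes down-sampled to 7.5x
benchmark75_sim <- function() cached("benchmark75_sim", function() {
  bm <- benchmark_sim()
  fr <- downsample_fragments(bm$frags, 30, 7.5, seed = 1L)
  cfg <- bm$config; cfg$coverage <- 7.5
  aln <- project_alignments(fr, bm$planted, bm$ref, TEST_LIB, cfg)
  ev <- extract_evidence(aln, TEST_LIB)
  disc <- discover_sites(merge_samples(list(ev)), bm$ref$seqs,
                         bm$ref$ref_me, NULL)
  ann <- annotate_calls(disc, TEST_LIB, bm$ref$seqs, bm$ref$fl_l1, NULL)
  evs <- list(S1 = list(drp = disc$drp, sr = disc$sr,
                        frag_mean = ev$summary$frag_mean,
                        frag_sd = ev$summary$frag_sd))
  gts <- genotype_samples(ann, evs, list(S1 = aln))
  list(aln = aln, ev = ev, disc = disc, ann = ann, gts = gts)
})

## feature-forced world: full-length L1 with inversions and transductions
feature_sim <- function() cached("feature_sim", function() {
  cfg <- sim_config(ref_len = 1000000L, counts = c(LINE1 = 12), coverage = 40,
                    p_l1_full = 1, p_inv = 1, p_tdn = 1, n_fl_l1 = 2L,
                    seed = 11)
  sim <- simulate_dataset(cfg)
  ev <- extract_evidence(sim$aln, TEST_LIB)
  disc <- discover_sites(merge_samples(list(ev)), sim$ref$seqs,
                         sim$ref$ref_me, NULL)
  ann <- annotate_calls(disc, TEST_LIB, sim$ref$seqs, sim$ref$fl_l1, NULL)
  c(sim, list(ev = ev, disc = disc, ann = ann))
})

## match calls to truth records (nearest same-chromosome site within 500 bp)
match_truth <- function(calls, truth) {
  near <- vapply(seq_len(nrow(calls)), function(i)
    which.min(abs(truth$pos - calls$pos[i]) +
                ifelse(truth$chrom == calls$chrom[i], 0, 1e9)), 0L)
  m <- cbind(calls, truth[near, .(tid = id, tpos = pos, tclass = class,
                                  tsubfamily = subfamily, tzyg = zygosity,
                                  ttrunc = trunc, tjunction = junction,
                                  ttsd_len = tsd_len, ttdn = tdn_source,
                                  torient = orientation)])
  m[abs(pos - tpos) <= 500L & class == tclass]
}
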