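## Readers/writers for the external formats the tool touches.
## Convention: every internal coordinate is 0-based half-open; conversion to
## 1-based happens exactly once, in the VCF writer (and back in the reader).

ALN_COLS <- c("qname", "sample", "chrom", "pos", "strand", "mapq", "cigar",
              "seq", "mchrom", "mpos", "mstrand", "first", "proper",
              "unmapped", "munmapped", "dup")

#' Build an alignment table
#'
#' The in-memory model of a coordinate-sorted BAM/SAM: one row per read with
#' mate, CIGAR and MAPQ fields. Used both by the simulator (which emits it
#' directly) and by the SAM/BAM readers.
#'
#' @param dt a data.frame/data.table with (a subset of) the columns
#'   `qname, sample, chrom, pos, strand, mapq, cigar, seq, mchrom, mpos,
#'   mstrand, first, proper, unmapped, munmapped, dup`; `pos`/`mpos` are
#'   0-based leftmost positions.
#' @param seqlengths named integer vector of contig lengths.
#' @return a `data.table` with class `aln_table` and attribute `seqlengths`,
#'   sorted by (chrom, pos).
#' @export
aln_table <- function(dt, seqlengths) {
  dt <- as.data.table(dt)
  defaults <- list(sample = "S1", mchrom = NA_character_, mpos = NA_integer_,
                   mstrand = NA_character_, first = TRUE, proper = FALSE,
                   unmapped = FALSE, munmapped = FALSE, dup = FALSE)
  for (cn in names(defaults)) if (!cn %in% names(dt)) dt[[cn]] <- defaults[[cn]]
  miss <- setdiff(ALN_COLS, names(dt))
  if (length(miss)) stopf("alignment table missing columns: %s", paste(miss, collapse = ", "))
  dt <- dt[, ALN_COLS, with = FALSE]
  dt[, pos := as.integer(pos)][, mapq := as.integer(mapq)][, mpos := as.integer(mpos)]
  bad <- !dt$unmapped & (dt$pos < 0L | dt$mapq < 0L | dt$mapq > 60L)
  if (any(bad)) stopf("invalid pos/mapq in %d alignment rows", sum(bad))
  qlen <- cigar_qlen(dt$cigar)
  bad <- !dt$unmapped & dt$cigar != "*" & qlen != nchar(dt$seq)
  if (any(bad))
    stopf("CIGAR/sequence length mismatch at record %d", which(bad)[1L])
  setorder(dt, chrom, pos, qname, na.last = TRUE)
  setattr(dt, "seqlengths", seqlengths)
  setattr(dt, "class", c("aln_table", class(dt)))
  dt[]
}

## query- and reference-consumed CIGAR lengths (vectorised, C-backed)
cigar_qlen <- function(cigar) {
  out <- integer(length(cigar))
  ok <- cigar != "*" & !is.na(cigar)
  if (any(ok)) out[ok] <- GenomicAlignments::cigarWidthAlongQuerySpace(
    cigar[ok], after.soft.clipping = FALSE)
  out
}

cigar_rlen <- function(cigar) {
  out <- integer(length(cigar))
  ok <- cigar != "*" & !is.na(cigar)
  if (any(ok)) out[ok] <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar[ok])
  out
}

## leading/trailing soft-clip lengths
clip_lens <- function(cigar) {
  lead <- suppressWarnings(as.integer(sub("^([0-9]+)S.*$", "\\1", cigar)))
  lead[!grepl("^[0-9]+S", cigar)] <- 0L
  trail <- suppressWarnings(as.integer(sub("^.*?([0-9]+)S$", "\\1", cigar)))
  trail[!grepl("[0-9]+S$", cigar)] <- 0L
  lead[is.na(lead)] <- 0L; trail[is.na(trail)] <- 0L
  list(lead = lead, trail = trail)
}

sam_flag <- function(dt) {
  f <- rep(1L, nrow(dt))                                   # paired
  f <- f + ifelse(dt$proper, 2L, 0L)
  f <- f + ifelse(dt$unmapped, 4L, 0L)
  f <- f + ifelse(dt$munmapped, 8L, 0L)
  f <- f + ifelse(!dt$unmapped & dt$strand == "-", 16L, 0L)
  f <- f + ifelse(!dt$munmapped & !is.na(dt$mstrand) & dt$mstrand == "-", 32L, 0L)
  f <- f + ifelse(dt$first, 64L, 128L)
  f + ifelse(dt$dup, 1024L, 0L)
}

#' Write an alignment table as SAM text
#'
#' @param aln an [aln_table()].
#' @param path output path (`.sam`).
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, path) {
  sl <- attr(aln, "seqlengths")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(sl), as.integer(sl)),
           sprintf("@RG\tID:%s\tSM:%s", unique(aln$sample), unique(aln$sample)))
  flag <- sam_flag(aln)
  rname <- ifelse(is.na(aln$chrom), "*", aln$chrom)
  rnext <- ifelse(is.na(aln$mchrom), "*",
                  ifelse(!is.na(aln$chrom) & aln$mchrom == aln$chrom, "=", aln$mchrom))
  body <- paste(aln$qname, flag, rname,
                ifelse(is.na(aln$pos), 0L, aln$pos + 1L),
                aln$mapq, ifelse(is.na(aln$cigar), "*", aln$cigar), rnext,
                ifelse(is.na(aln$mpos), 0L, aln$mpos + 1L), 0L,
                aln$seq, "*", paste0("RG:Z:", aln$sample), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read alignments from SAM text or BAM
#'
#' SAM text is parsed directly (hard clips are normalised away at parse: an
#' `H` op is dropped from the CIGAR since it consumes neither query nor
#' reference bases we model). BAM files are delegated to
#' [Rsamtools::scanBam()] when that package is installed.
#'
#' @param path `.sam` or `.bam` file, coordinate-sorted.
#' @param region optional `list(chrom=, start=, end=)` (0-based half-open);
#'   only reads overlapping it are returned.
#' @param sample sample id to stamp on the records; defaults to the SAM
#'   read-group sample, else the file stem.
#' @return an [aln_table()].
#' @export
read_alignments <- function(path, region = NULL, sample = NULL) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    aln <- read_bam_file(path, sample)
  } else {
    aln <- read_sam_file(path, sample)
  }
  if (!is.null(region)) {
    end <- aln$pos + cigar_rlen(aln$cigar)
    keep <- !is.na(aln$chrom) & aln$chrom == region$chrom &
      aln$pos < region$end & end > region$start
    aln <- aln[keep]
  }
  aln
}

read_sam_file <- function(path, sample = NULL) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  sq <- hdr[startsWith(hdr, "@SQ")]
  sl <- setNames(as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq)),
                 sub(".*\tSN:([^\t]+).*", "\\1", sq))
  if (is.null(sample)) {
    rg <- hdr[startsWith(hdr, "@RG")]
    sample <- if (length(rg) && grepl("\tSM:", rg[1L]))
      sub(".*\tSM:([^\t]+).*", "\\1", rg[1L])
    else sub("\\.[sb]am$", "", basename(path), ignore.case = TRUE)
  }
  if (length(body) == 0L)
    return(aln_table(data.table(qname = character(0), sample = character(0),
      chrom = character(0), pos = integer(0), strand = character(0),
      mapq = integer(0), cigar = character(0), seq = character(0)), sl))
  f <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 11L)) stopf("malformed SAM record %d: fewer than 11 fields", which(nf < 11L)[1L])
  field <- function(i) vapply(f, `[[`, "", i)
  flag <- as.integer(field(2L))
  cigar <- field(6L)
  cigar <- gsub("[0-9]+H", "", cigar)          # normalise hard clips away
  cigar[cigar == ""] <- "*"
  seqs <- field(10L)
  qlen <- cigar_qlen(cigar)
  bad <- cigar != "*" & seqs != "*" & qlen != nchar(seqs)
  if (any(bad))
    stopf("malformed SAM record %d: CIGAR query length %d != sequence length %d",
          which(bad)[1L], qlen[which(bad)[1L]], nchar(seqs)[which(bad)[1L]])
  rname <- field(3L); rnext <- field(7L)
  unmapped <- bitwAnd(flag, 4L) > 0L
  dt <- data.table(
    qname = field(1L), sample = sample,
    chrom = ifelse(rname == "*" | unmapped, NA_character_, rname),
    pos = ifelse(unmapped, NA_integer_, as.integer(field(4L)) - 1L),
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    mapq = as.integer(field(5L)), cigar = cigar, seq = seqs,
    mchrom = ifelse(rnext == "*", NA_character_, ifelse(rnext == "=", rname, rnext)),
    mpos = suppressWarnings(as.integer(field(8L))) - 1L,
    mstrand = ifelse(bitwAnd(flag, 32L) > 0L, "-", "+"),
    first = bitwAnd(flag, 64L) > 0L, proper = bitwAnd(flag, 2L) > 0L,
    unmapped = unmapped, munmapped = bitwAnd(flag, 8L) > 0L,
    dup = bitwAnd(flag, 1024L) > 0L)
  dt[unmapped == TRUE, `:=`(pos = mpos, chrom = mchrom)]  # SAM placement rule
  aln_table(dt, sl)
}

read_bam_file <- function(path, sample = NULL) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stopf("BAM input requires the Rsamtools package")
  b <- Rsamtools::scanBam(path)[[1L]]
  hdr <- Rsamtools::scanBamHeader(path)[[1L]]
  sl <- hdr$targets
  if (is.null(sample)) sample <- sub("\\.bam$", "", basename(path), ignore.case = TRUE)
  flag <- b$flag
  dt <- data.table(
    qname = b$qname, sample = sample, chrom = as.character(b$rname),
    pos = b$pos - 1L, strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    mapq = as.integer(b$mapq), cigar = ifelse(is.na(b$cigar), "*", b$cigar),
    seq = as.character(b$seq),
    mchrom = as.character(b$mrnm), mpos = b$mpos - 1L,
    mstrand = ifelse(bitwAnd(flag, 32L) > 0L, "-", "+"),
    first = bitwAnd(flag, 64L) > 0L, proper = bitwAnd(flag, 2L) > 0L,
    unmapped = bitwAnd(flag, 4L) > 0L, munmapped = bitwAnd(flag, 8L) > 0L,
    dup = bitwAnd(flag, 1024L) > 0L)
  dt[unmapped == TRUE & is.na(pos), `:=`(pos = mpos, chrom = mchrom)]
  aln_table(dt, sl)
}

#' Read a BED file of genome intervals
#'
#' @param path 3+ column BED (0-based half-open).
#' @return data.table with columns `chrom, start, end, label` (and `strand`
#'   when a 6th column is present).
#' @export
read_intervals <- function(path) {
  empty <- data.table(chrom = character(0), start = integer(0),
                      end = integer(0), label = character(0))
  if (file.size(path) == 0L) return(empty)
  dt <- fread(path, header = FALSE, sep = "\t", fill = TRUE)
  if (nrow(dt) == 0L) return(empty)
  if (ncol(dt) < 3L) stopf("BED file needs >= 3 columns")
  out <- data.table(chrom = as.character(dt[[1L]]),
                    start = as.integer(dt[[2L]]), end = as.integer(dt[[3L]]),
                    label = if (ncol(dt) >= 4L) as.character(dt[[4L]]) else "")
  if (ncol(dt) >= 6L) out[, strand := as.character(dt[[6L]])]
  if (any(out$start < 0L | out$start >= out$end))
    stopf("BED interval with start >= end at line %d",
          which(out$start < 0L | out$start >= out$end)[1L])
  out
}

#' Write genome intervals as BED
#' @param dt data.table with `chrom, start, end` and optional `label`, `strand`.
#' @param path output path.
#' @export
write_intervals <- function(dt, path) {
  cols <- list(dt$chrom, dt$start, dt$end)
  if (!is.null(dt$label)) {
    cols <- c(cols, list(dt$label))
    if (!is.null(dt$strand)) cols <- c(cols, list(0L, dt$strand))
  }
  fwrite(as.data.table(cols), path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a minimal gene model
#'
#' Tab-separated, BED-like: `chrom start end gene score strand feature`,
#' 0-based half-open, one row per exon/UTR feature
#' (`feature` in `exon, 5UTR, 3UTR`). Transcript extent per gene is the range
#' of its features; promoter/terminator/intron intervals are derived from it.
#'
#' @param path TSV path.
#' @return data.table of features.
#' @export
read_gene_model <- function(path) {
  if (file.size(path) == 0L)
    return(data.table(chrom = character(0), start = integer(0), end = integer(0),
                      gene = character(0), strand = character(0), feature = character(0)))
  dt <- fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 7L) stopf("gene model needs 7 columns (chrom start end gene score strand feature)")
  data.table(chrom = as.character(dt[[1L]]), start = as.integer(dt[[2L]]),
             end = as.integer(dt[[3L]]), gene = as.character(dt[[4L]]),
             strand = as.character(dt[[6L]]), feature = as.character(dt[[7L]]))
}

## ---- VCF 4.2 ---------------------------------------------------------------

VCF_INFO_HEADER <- c(
  '##INFO=<ID=MEINFO,Number=4,Type=String,Description="Mobile element info of the form NAME,START,STOP,POLARITY (consensus coordinates, 0-based)">',
  '##INFO=<ID=TSD,Number=1,Type=String,Description="Target site duplication sequence, or null">',
  '##INFO=<ID=TSDEL,Number=1,Type=Integer,Description="Target site deletion length">',
  '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="Estimated length of the inserted element">',
  '##INFO=<ID=ASSESS,Number=1,Type=Integer,Description="Breakpoint evidence quality tranche (0-5)">',
  '##INFO=<ID=DIFF,Number=1,Type=String,Description="Subfamily assignment and interior mutations vs the class consensus (0-based positions; trailing * marks CpG-associated)">',
  '##INFO=<ID=INV5,Number=1,Type=Integer,Description="5-prime inversion junction on the consensus (twin priming); absent if not inverted">',
  '##INFO=<ID=TDN,Number=1,Type=String,Description="3-prime transduction: mapped donor locus and source element id">',
  '##INFO=<ID=GENEIMPACT,Number=1,Type=String,Description="Most severe overlapped gene feature">')

VCF_ALT_HEADER <- c(
  '##ALT=<ID=INS:ME:ALU,Description="Insertion of ALU element">',
  '##ALT=<ID=INS:ME:LINE1,Description="Insertion of LINE1 element">',
  '##ALT=<ID=INS:ME:SVA,Description="Insertion of SVA element">',
  '##ALT=<ID=DEL:ME:ALU,Description="Deletion of ALU element">',
  '##ALT=<ID=DEL:ME:LINE1,Description="Deletion of LINE1 element">',
  '##ALT=<ID=DEL:ME:SVA,Description="Deletion of SVA element">')

vcf_info_string <- function(cl) {
  info <- sprintf("MEINFO=%s,%d,%d,%s;SVLEN=%d;ASSESS=%d;TSD=%s",
                  cl$class, cl$cons_start, cl$cons_stop, cl$orientation,
                  cl$svlen, cl$tranche,
                  ifelse(nzchar(cl$tsd), cl$tsd, "null"))
  info <- paste0(info, ifelse(cl$tsdel > 0L, sprintf(";TSDEL=%d", cl$tsdel), ""))
  diff <- ifelse(nzchar(cl$subfamily),
                 sprintf("DIFF=%s:%s", cl$subfamily,
                         ifelse(nzchar(cl$mutations), cl$mutations, ".")), "")
  info <- paste0(info, ifelse(nzchar(diff), paste0(";", diff), ""))
  info <- paste0(info, ifelse(!is.na(cl$inv5) & cl$inv5,
                              sprintf(";INV5=%d", cl$inv_junction), ""))
  info <- paste0(info, ifelse(nzchar(cl$tdn_locus),
                              sprintf(";TDN=%s|%s", cl$tdn_locus, cl$tdn_source), ""))
  paste0(info, ifelse(nzchar(cl$gene_impact),
                      sprintf(";GENEIMPACT=%s", cl$gene_impact), ""))
}

#' Write MEI calls and genotypes as VCF 4.2
#'
#' POS is the base immediately 5-prime of the insertion point (anchor-base
#' convention for symbolic alleles); this is the single place internal
#' 0-based coordinates become 1-based.
#'
#' @param calls call table (one row per site; see [discover_sites()]).
#' @param genotypes long genotype table (`site_id, sample, gt, gl, gq,
#'   ad_ref, ad_alt`), one row per site x sample.
#' @param samples character vector of sample ids (column order).
#' @param path output path, or `NULL` to return the lines.
#' @param reference optional named character vector of chromosome sequences,
#'   used to fill the REF anchor base (else "N").
#' @param svtype "INS" (default) or "DEL" for reference-ME deletion records.
#' @return the VCF lines, invisibly if written to a file.
#' @export
write_vcf <- function(calls, genotypes, samples, path = NULL,
                      reference = NULL, svtype = "INS") {
  calls <- as.data.table(calls)
  if (nrow(calls) > 1L) {
    o <- order(calls$chrom, calls$pos)
    if (!identical(o, seq_len(nrow(calls)))) stopf("calls must be sorted by (chrom, pos)")
  }
  genotypes <- as.data.table(genotypes)
  if (nrow(calls)) {
    cnt <- genotypes[, .N, by = site_id]
    if (!setequal(cnt$site_id, calls$site_id) || any(cnt$N != length(samples)))
      stopf("genotypes must cover every call x sample exactly once")
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##source=meiscan",
           VCF_ALT_HEADER, VCF_INFO_HEADER,
           '##FILTER=<ID=lc,Description="Evidence on one side only">',
           '##FILTER=<ID=noSR,Description="No split-read support across samples">',
           '##FILTER=<ID=hNC,Description="Fraction of no-call genotypes above threshold">',
           '##FILTER=<ID=depth,Description="Local depth outside accepted range">',
           '##FILTER=<ID=mask,Description="Within padded reference gap/mask">',
           '##FILTER=<ID=refME,Description="Near a same-class reference mobile element">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=GL,Number=3,Type=Float,Description="Log10 genotype likelihoods (0/0,0/1,1/1), max 0">',
           '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
           '##FORMAT=<ID=AD,Number=2,Type=Integer,Description="Reference, alternate supporting fragments">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  rows <- character(0)
  if (nrow(calls)) {
    ref_base <- rep("N", nrow(calls))
    if (!is.null(reference)) {
      p <- pmax(calls$pos, 1L)  # anchor base, 0-based pos - 1
      ref_base <- toupper(substring(reference[calls$chrom], p, p))
    }
    alt <- sprintf("<%s:ME:%s>", svtype, calls$class)
    filt <- ifelse(nzchar(calls$filters), gsub(",", ";", calls$filters), "PASS")
    info <- vcf_info_string(calls)
    g <- genotypes[, .(fmt = sprintf("%s:%s:%d:%d,%d", gt, gl, gq, ad_ref, ad_alt)),
                   by = .(site_id, sample)]
    gw <- dcast(g, site_id ~ sample, value.var = "fmt")
    gw <- gw[match(calls$site_id, gw$site_id)]
    gcols <- do.call(paste, c(as.list(gw[, samples, with = FALSE]), sep = "\t"))
    rows <- paste(calls$chrom, calls$pos, calls$site_id, ref_base, alt, ".",
                  filt, info, "GT:GL:GQ:AD", gcols, sep = "\t")
  }
  lines <- c(hdr, rows)
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

## parse an INFO string into a named character vector
parse_info <- function(s) {
  kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1L]], "=", fixed = TRUE)
  setNames(vapply(kv, function(x) if (length(x) > 1L) x[[2L]] else "", ""),
           vapply(kv, `[[`, "", 1L))
}

#' Read a meiscan VCF back into call and genotype tables
#'
#' Companion reader to [write_vcf()]; the pair round-trips losslessly on the
#' modeled fields.
#'
#' @param path VCF path.
#' @return list with `calls`, `genotypes`, `samples`.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  chead <- lines[startsWith(lines, "#CHROM")]
  samples <- tail(strsplit(chead, "\t")[[1L]], -9L)
  body <- lines[!startsWith(lines, "#")]
  empty_calls <- data.table(site_id = character(0), chrom = character(0), pos = integer(0))
  if (length(body) == 0L)
    return(list(calls = empty_calls, genotypes = data.table(), samples = samples))
  f <- strsplit(body, "\t", fixed = TRUE)
  field <- function(i) vapply(f, `[[`, "", i)
  info <- lapply(field(8L), parse_info)
  gi <- function(k, default = "") vapply(info, function(x) x[k][[1L]] %||% default, "")
  meinfo <- strsplit(gi("MEINFO"), ",", fixed = TRUE)
  tsd <- gi("TSD"); tsd[tsd == "null" | is.na(tsd)] <- ""
  diff <- gi("DIFF"); diff[is.na(diff)] <- ""
  dparts <- strsplit(diff, ":", fixed = TRUE)
  inv5 <- gi("INV5"); tdn <- gi("TDN"); tdn[is.na(tdn)] <- ""
  tdnp <- strsplit(tdn, "|", fixed = TRUE)
  filt <- field(7L)
  calls <- data.table(
    site_id = field(3L), chrom = field(1L), pos = as.integer(field(2L)),
    class = vapply(meinfo, `[[`, "", 1L),
    orientation = vapply(meinfo, `[[`, "", 4L),
    cons_start = as.integer(vapply(meinfo, `[[`, "", 2L)),
    cons_stop = as.integer(vapply(meinfo, `[[`, "", 3L)),
    svlen = as.integer(gi("SVLEN", NA)), tranche = as.integer(gi("ASSESS", NA)),
    tsd = tsd,
    tsdel = {x <- as.integer(gi("TSDEL", NA)); x[is.na(x)] <- 0L; x},
    filters = ifelse(filt == "PASS" | filt == ".", "", gsub(";", ",", filt)),
    subfamily = vapply(dparts, function(x) if (length(x)) x[[1L]] else "", ""),
    mutations = vapply(dparts, function(x) if (length(x) > 1L && x[[2L]] != ".") x[[2L]] else "", ""),
    inv5 = !is.na(suppressWarnings(as.integer(inv5))),
    inv_junction = suppressWarnings(as.integer(inv5)),
    tdn_locus = vapply(tdnp, function(x) if (length(x)) x[[1L]] else "", ""),
    tdn_source = vapply(tdnp, function(x) if (length(x) > 1L) x[[2L]] else "", ""),
    gene_impact = gi("GENEIMPACT"))
  calls[is.na(gene_impact), gene_impact := ""]
  gts <- rbindlist(lapply(seq_along(f), function(i) {
    vals <- strsplit(tail(f[[i]], length(samples)), ":", fixed = TRUE)
    ad <- strsplit(vapply(vals, `[[`, "", 4L), ",", fixed = TRUE)
    data.table(site_id = f[[i]][[3L]], sample = samples,
               gt = vapply(vals, `[[`, "", 1L), gl = vapply(vals, `[[`, "", 2L),
               gq = as.integer(vapply(vals, `[[`, "", 3L)),
               ad_ref = as.integer(vapply(ad, `[[`, "", 1L)),
               ad_alt = as.integer(vapply(ad, `[[`, "", 2L)))
  }))
  list(calls = calls, genotypes = gts, samples = samples)
}

## ---- evidence serialisation (typed TSV, for the multi-sample split mode) ---

#' Write an evidence bundle to TSV files
#'
#' Serialises the output of [extract_evidence()] as `<stem>.drp.tsv`,
#' `<stem>.sr.tsv`, `<stem>.cov.tsv` (run-length encoded depth) and
#' `<stem>.meta.json`.
#'
#' @param ev evidence bundle from [extract_evidence()].
#' @param stem output path stem.
#' @export
write_evidence <- function(ev, stem) {
  fwrite(ev$drp, paste0(stem, ".drp.tsv"), sep = "\t")
  fwrite(ev$sr, paste0(stem, ".sr.tsv"), sep = "\t")
  cov <- rbindlist(lapply(names(ev$summary$coverage), function(ch) {
    r <- ev$summary$coverage[[ch]]
    data.table(chrom = ch, runlen = S4Vectors::runLength(r),
               value = S4Vectors::runValue(r))
  }))
  fwrite(cov, paste0(stem, ".cov.tsv"), sep = "\t")
  jsonlite::write_json(
    list(sample = ev$sample, median_depth = as.list(ev$summary$median_depth),
         frag_mean = ev$summary$frag_mean, frag_sd = ev$summary$frag_sd,
         read_len = ev$summary$read_len,
         seqlengths = as.list(attr(ev, "seqlengths") %||% ev$summary$seqlengths)),
    paste0(stem, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' Read an evidence bundle written by [write_evidence()]
#' @param stem path stem.
#' @return evidence bundle (list with `sample`, `drp`, `sr`, `summary`).
#' @export
read_evidence <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".meta.json"), simplifyVector = TRUE)
  drp <- fread(paste0(stem, ".drp.tsv"),
               colClasses = list(character = c("sample", "chrom")))
  sr <- fread(paste0(stem, ".sr.tsv"),
              colClasses = list(character = c("sample", "chrom")))
  covdt <- fread(paste0(stem, ".cov.tsv"))
  coverage <- lapply(split(covdt, by = "chrom", sorted = TRUE), function(d)
    S4Vectors::Rle(d$value, d$runlen))
  list(sample = meta$sample, drp = drp, sr = sr,
       summary = list(coverage = coverage,
                      median_depth = unlist(meta$median_depth),
                      frag_mean = meta$frag_mean, frag_sd = meta$frag_sd,
                      read_len = meta$read_len,
                      seqlengths = unlist(meta$seqlengths)))
}
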