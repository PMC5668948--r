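## Ground-truth simulator: diploid genomes carrying synthetic mobile-element
## insertions with realistic features, error-free paired reads, and
## truth-aware projection of those reads into BWA-like alignments (soft
## clips at breakpoints, decoy-contig mappings for element-interior reads so
## straddling pairs satisfy the different-chromosome DRP definition).

#' Simulation configuration
#'
#' Defaults state the benchmark world: an NA12878-like class distribution
#' (Alu:L1:SVA = 922:146:46) scaled to the synthetic reference, 95%
#' heterozygous / 5% homozygous insertions, 100-bp pairs at 500 +/- 50 bp
#' fragments with zero base error, and a 60/30/15/7.5x coverage ladder
#' (`coverage` picks one rung).
#'
#' @param ref_len reference length (bp).
#' @param counts named insertion counts per class; default scales the
#'   922/146/46 distribution by `scale`.
#' @param scale scaling of the NA12878-like counts (default 10/46 so the
#'   rarest class keeps 10 copies at benchmark size).
#' @param coverage total (diploid) sequencing depth.
#' @param het_frac fraction of heterozygous insertions.
#' @param read_len,frag_mean,frag_sd,base_error read simulation parameters.
#' @param n_ref_alu,n_ref_l1,n_fl_l1 reference-embedded ME copies (the FL-L1
#'   copies double as annotated transduction sources).
#' @param p_l1_full,p_inv,p_tdn LINE1 feature rates: full-length fraction,
#'   5' inversion rate among L1 (the 18.2% germline estimate), 3'
#'   transduction rate.
#' @param tsd_neg_frac fraction of insertions with a target-site deletion
#'   instead of a duplication.
#' @param seed integer seed; all randomness derives from it.
#' @return named list.
#' @export
sim_config <- function(ref_len = 5e6L, counts = NULL, scale = 10 / 46,
                       coverage = 30, het_frac = 0.95, read_len = 100L,
                       frag_mean = 500L, frag_sd = 50L, base_error = 0,
                       n_ref_alu = 10L, n_ref_l1 = 2L, n_fl_l1 = 2L,
                       p_l1_full = 0.3, p_inv = 0.182, p_tdn = 0.1,
                       tsd_neg_frac = 0.05, seed = 1L) {
  if (is.null(counts))   # NA12878-like proportions, scaled to the reference
    counts <- round(c(ALU = 922, LINE1 = 146, SVA = 46) * scale * ref_len / 5e6)
  as.list(environment())
}

#' Build a synthetic reference with embedded reference-ME copies
#'
#' Random DNA with full-length consensus copies embedded at spaced positions
#' and annotated (BED-style tables); `n_fl_l1` of the L1 copies are
#' annotated as full-length source elements for transduction tracking.
#'
#' @param config [sim_config()].
#' @param library an [me_library()].
#' @return list: `seqs` (named character), `ref_me`, `fl_l1`, `accessible`.
#' @export
make_reference <- function(config, library) {
  with_seed(derive_seed(config$seed, "reference"), {
    len <- as.integer(config$ref_len)
    base <- paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
    n_l1 <- config$n_ref_l1 + config$n_fl_l1
    classes <- c(rep("ALU", config$n_ref_alu), rep("LINE1", n_l1))
    n <- length(classes)
    ref_me <- data.table(chrom = character(0), start = integer(0),
                         end = integer(0), label = character(0),
                         strand = character(0))
    fl_l1 <- copy(ref_me)
    if (n > 0L) {
      ## keep embedded copies apart; spacing adapts to the genome size
      spacing <- max(2000L, min(8000L, (len - 10000L) %/% (n + 1L)))
      if ((n + 1L) * spacing > len - 10000L)
        stopf("reference too short for %d embedded ME copies", n)
      draw <- function() sort(sample.int(len - 20000L, n) + 5000L)
      slots <- draw()
      tries <- 0L
      while (any(diff(slots) < spacing)) {
        slots <- draw()
        tries <- tries + 1L
        if (tries > 200L) {  # deterministic fallback: evenly spread jittered
          slots <- sort(as.integer(seq(8000L, len - 12000L, length.out = n) +
                                     sample.int(1000L, n)))
          break
        }
      }
      classes <- sample(classes)
      strands <- sample(c("+", "-"), n, replace = TRUE)
      pieces <- character(0); cur <- 0L; out <- list()
      for (i in seq_len(n)) {
        el <- library[[classes[i]]]$seq
        if (strands[i] == "-") el <- revcomp(el)
        pieces <- c(pieces, substring(base, cur + 1L, slots[i]), el)
        out[[i]] <- data.table(chrom = "chr1", start = slots[i],
                               end = slots[i] + nchar(el), label = classes[i],
                               strand = strands[i])
        cur <- slots[i]
      }
      pieces <- c(pieces, substring(base, cur + 1L, len))
      seq <- paste(pieces, collapse = "")
      ann <- rbindlist(out)
      ## embedding shifts downstream coordinates; recompute cumulatively
      shift <- cumsum(c(0L, ann$end - ann$start))[seq_len(n)]
      ann[, `:=`(start = start + shift, end = end + shift)]
      l1s <- which(ann$label == "LINE1")
      fl <- head(l1s, config$n_fl_l1)
      fl_l1 <- ann[fl][, label := sprintf("src%d", seq_along(fl))]
      ref_me <- ann
      seqs <- c(chr1 = seq)
    } else seqs <- c(chr1 = base)
    acc <- data.table(chrom = "chr1", start = 2000L,
                      end = nchar(seqs[["chr1"]]) - 2000L, label = "accessible")
    list(seqs = seqs, ref_me = ref_me, fl_l1 = fl_l1, accessible = acc)
  })
}

#' Draw insertion specifications
#'
#' Realises the stated world: class counts from the config; subfamily drawn
#' from the library profiles (root 20%, derived subfamilies equal shares);
#' 0-4 extra private interior mutations; L1 5' truncation (30% full length,
#' else uniform), 5' inversion at `p_inv` with a uniform junction, 3'
#' transduction at `p_tdn` tagged from downstream of an annotated source;
#' TSD length uniform 4-20 (or a 1-10 bp target-site deletion at
#' `tsd_neg_frac`); poly(A) 10-40; 95% heterozygous.
#'
#' @param config [sim_config()].
#' @param library an [me_library()].
#' @param ref a [make_reference()] result.
#' @return data.table of insertion specs (one row per insertion).
#' @export
draw_insertion_specs <- function(config, library, ref) {
  with_seed(derive_seed(config$seed, "specs"), {
    rows <- list()
    for (cls in names(config$counts)) {
      k <- config$counts[[cls]]
      if (k == 0L) next
      entry <- library[[cls]]
      L <- entry$length
      subfams <- names(entry$profiles)
      roots <- vapply(entry$profiles, nrow, 0L) == 0L
      pr <- ifelse(roots, 0.2 / max(1, sum(roots)),
                   0.8 / max(1, sum(!roots)))
      if (all(roots)) pr <- rep(1 / length(subfams), length(subfams))
      for (i in seq_len(k)) {
        subfam <- sample(subfams, 1L, prob = pr)
        n_extra <- rpois(1L, 2)
        diag_pos <- entry$profiles[[subfam]]$pos
        ok <- setdiff(seq_len(L) - 1L, c(entry$cpg, diag_pos))
        extra <- sort(sample(ok, min(n_extra, length(ok))))
        if (length(extra)) {
          eref <- substring(entry$seq, extra + 1L, extra + 1L)
          ealt <- vapply(eref, function(b) sample(setdiff(DNA_BASES, b), 1L), "")
        } else ealt <- character(0)
        trunc <- 0L
        if (cls == "LINE1" && runif(1) > config$p_l1_full)
          trunc <- sample.int(L - 500L, 1L)
        junction <- NA_integer_
        if (cls == "LINE1" && runif(1) < config$p_inv && trunc < L - 400L)
          junction <- trunc + sample.int(L - trunc - 300L, 1L) + 150L
        tsd_len <- if (runif(1) < config$tsd_neg_frac) -sample.int(10L, 1L)
                   else sample(4:20, 1L)
        polya <- sample(10:40, 1L)
        tdn_src <- ""; tdn_tag <- ""; polya2 <- 0L
        if (cls == "LINE1" && runif(1) < config$p_tdn && nrow(ref$fl_l1)) {
          src <- ref$fl_l1[sample.int(nrow(ref$fl_l1), 1L)]
          off <- sample.int(80L, 1L)
          tlen <- sample(60:150, 1L)
          if (src$strand == "+")
            tag <- substring(ref$seqs[[src$chrom]], src$end + off + 1L,
                             src$end + off + tlen)
          else
            tag <- revcomp(substring(ref$seqs[[src$chrom]],
                                     src$start - off - tlen + 1L, src$start - off))
          tdn_src <- src$label; tdn_tag <- tag
          polya2 <- sample(10:30, 1L)
        }
        het <- runif(1) < config$het_frac
        rows[[length(rows) + 1L]] <- data.table(
          class = cls, subfamily = subfam,
          extra_mut = paste(sprintf("%d:%s", extra, ealt), collapse = ";"),
          trunc = trunc, junction = junction, tsd_len = tsd_len,
          polya = polya, tdn_source = tdn_src, tdn_tag = tdn_tag,
          polya2 = polya2, zygosity = if (het) "het" else "hom",
          haplotype = if (het) sample(1:2, 1L) else 0L,
          orientation = sample(c("+", "-"), 1L))
      }
    }
    specs <- rbindlist(rows)
    ## positions: uniform over accessible intervals, >= 1 kb apart, clear of
    ## embedded reference MEs
    acc <- ref$accessible
    avoid <- ref$ref_me
    attempts <- 0L
    repeat {
      attempts <- attempts + 1L
      if (attempts > 50L) stopf("insufficient accessible space for %d insertions",
                                nrow(specs))
      pos <- sort(sample(acc$start[1L]:acc$end[1L], nrow(specs) * 3L))
      keep <- c(TRUE, diff(pos) >= 1000L)
      pos <- pos[keep]
      if (nrow(avoid)) {
        bad <- vapply(pos, function(p)
          any(avoid$start - 600L < p & avoid$end + 600L > p), NA)
        pos <- pos[!bad]
      }
      if (length(pos) >= nrow(specs)) break
    }
    specs[, `:=`(chrom = acc$chrom[1L],
                 pos = sort(sample(pos, nrow(specs))), id = sprintf("ins_%04d", .I))]
    specs[]
  })
}

#' Synthesize an inserted element sequence from its specification
#'
#' Applies subfamily diagnostics and extra interior mutations to the class
#' consensus, truncates 5' of `trunc`, reverse-complements
#' `[trunc, junction)` when a twin-priming junction is set, then appends the
#' poly(A) tail and, for transductions, the tag plus a second poly(A).
#' Deterministic given the spec. The insertion `orientation` is applied at
#' planting time, not here.
#'
#' @param spec one spec row (list-like).
#' @param library an [me_library()].
#' @return element sequence (donor-forward, orientation not applied).
#' @export
synthesize_element <- function(spec, library) {
  entry <- library[[spec$class]]
  if (is.null(entry)) stopf("unknown class '%s'", spec$class)
  L <- entry$length
  if (!is.na(spec$junction) && spec$junction <= spec$trunc)
    stopf("inversion junction (%d) must exceed truncation start (%d)",
          spec$junction, spec$trunc)
  if (spec$trunc >= L) stopf("truncation start beyond consensus")
  seq <- strsplit(entry$seq, "")[[1L]]
  diag <- entry$profiles[[spec$subfamily]]
  if (!is.null(diag) && nrow(diag)) seq[diag$pos + 1L] <- diag$alt
  if (nzchar(spec$extra_mut %||% "")) {
    for (tok in strsplit(spec$extra_mut, ";", fixed = TRUE)[[1L]]) {
      kv <- strsplit(tok, ":", fixed = TRUE)[[1L]]
      seq[as.integer(kv[1L]) + 1L] <- kv[2L]
    }
  }
  core <- seq[(spec$trunc + 1L):L]
  if (!is.na(spec$junction)) {
    k <- spec$junction - spec$trunc  # first k bases of the kept core invert
    core <- c(strsplit(revcomp(paste(core[seq_len(k)], collapse = "")), "")[[1L]],
              core[(k + 1L):length(core)])
  }
  out <- paste(core, collapse = "")
  out <- paste0(out, strrep("A", spec$polya))
  if (nzchar(spec$tdn_tag %||% ""))
    out <- paste0(out, spec$tdn_tag, strrep("A", spec$polya2))
  out
}

#' Plant insertions into the reference, producing two haplotypes
#'
#' The TSD is realised by duplicating the `tsd_len` reference bases starting
#' at the insertion point (negative lengths delete bases instead);
#' heterozygous specs go to one haplotype, homozygous to both. Block tables
#' recording the donor-to-reference mapping are kept for truth-aware
#' alignment projection.
#'
#' @param ref [make_reference()] result.
#' @param specs spec table from [draw_insertion_specs()].
#' @param library an [me_library()].
#' @return list: `haps` (per haplotype: `seq` and `blocks`), `truth` table.
#' @export
plant_insertions <- function(ref, specs, library) {
  chrom <- "chr1"
  base <- ref$seqs[[chrom]]
  elems <- vapply(seq_len(nrow(specs)), function(i) {
    el <- synthesize_element(as.list(specs[i]), library)
    if (specs$orientation[i] == "-") revcomp(el) else el
  }, "")
  build_hap <- function(hi) {
    use <- which(specs$zygosity == "hom" | specs$haplotype == hi)
    use <- use[order(specs$pos[use])]
    pieces <- character(0)
    blocks <- list()
    cur_ref <- 0L; cur_d <- 0L
    for (i in use) {
      p <- specs$pos[i]; t <- specs$tsd_len[i]
      left_end <- if (t >= 0L) p + t else p           # ref prefix [cur_ref, left_end)
      resume <- if (t >= 0L) p else p - t             # ref resumes here after insert
      pieces <- c(pieces, substring(base, cur_ref + 1L, left_end))
      blen <- left_end - cur_ref
      blocks[[length(blocks) + 1L]] <- data.table(
        d_start = cur_d, d_end = cur_d + blen, type = "ref",
        ref_start = cur_ref, ins = NA_integer_)
      cur_d <- cur_d + blen
      pieces <- c(pieces, elems[i])
      elen <- nchar(elems[i])
      blocks[[length(blocks) + 1L]] <- data.table(
        d_start = cur_d, d_end = cur_d + elen, type = "ins",
        ref_start = NA_integer_, ins = i)
      cur_d <- cur_d + elen
      cur_ref <- resume
    }
    pieces <- c(pieces, substring(base, cur_ref + 1L, nchar(base)))
    blocks[[length(blocks) + 1L]] <- data.table(
      d_start = cur_d, d_end = cur_d + nchar(base) - cur_ref, type = "ref",
      ref_start = cur_ref, ins = NA_integer_)
    list(seq = paste(pieces, collapse = ""), blocks = rbindlist(blocks),
         chrom = chrom)
  }
  haps <- list(build_hap(1L), build_hap(2L))
  truth <- data.table(specs[, .(id, class, subfamily, chrom, pos, zygosity,
                                haplotype, orientation, trunc, junction,
                                tsd_len, polya, tdn_source, tdn_tag)],
                      elem_len = nchar(elems))
  list(haps = haps, truth = truth)
}

#' Simulate error-free inward-facing read pairs from the haplotypes
#'
#' Fragment starts uniform over each haplotype, lengths normal
#' (`frag_mean`, `frag_sd`) truncated at twice the read length; `coverage`
#' is the total diploid depth, split evenly between haplotypes. Per-base
#' errors are applied at `base_error` (default 0, matching the stated
#' zero-error design).
#'
#' @param planted [plant_insertions()] result.
#' @param config [sim_config()].
#' @return fragment table with provenance: `qname, hap, fstart, fend`.
#' @export
simulate_reads <- function(planted, config) {
  if (config$frag_mean < 2L * config$read_len)
    stopf("fragment mean must be at least twice the read length")
  if (config$coverage <= 0) stopf("coverage must be positive")
  with_seed(derive_seed(config$seed, "reads"), {
    rows <- lapply(1:2, function(hi) {
      hlen <- nchar(planted$haps[[hi]]$seq)
      nfrag <- round(config$coverage / 2 * hlen / (2L * config$read_len))
      flen <- pmax(2L * config$read_len,
                   as.integer(round(rnorm(nfrag, config$frag_mean, config$frag_sd))))
      flen <- pmin(flen, hlen)
      fstart <- floor(runif(nfrag, 0, hlen - flen + 1))
      data.table(hap = hi, fstart = as.integer(fstart),
                 fend = as.integer(fstart + flen))
    })
    frags <- rbindlist(rows)
    frags[, qname := sprintf("frag_%07d", .I)]
    frags[]
  })
}

#' Down-sample fragments to a lower coverage
#'
#' Keeps each fragment independently with probability `target / source`.
#'
#' @param frags fragment table.
#' @param source,target source and target coverages.
#' @param seed seed for the thinning draw.
#' @return subset fragment table.
#' @export
downsample_fragments <- function(frags, source, target, seed = 1L) {
  stopifnot(target <= source)
  with_seed(derive_seed(seed, "downsample"),
            frags[as.logical(rbinom(nrow(frags), 1L, target / source))])
}

## substring both reads of every fragment from its haplotype
fragment_reads <- function(frags, planted, read_len) {
  out <- list()
  for (hi in 1:2) {
    d <- frags[hap == hi]
    if (nrow(d) == 0L) next
    hseq <- planted$haps[[hi]]$seq
    out[[hi]] <- data.table(
      qname = rep(d$qname, 2L), hap = hi,
      a = c(d$fstart, d$fend - read_len),
      b = c(d$fstart + read_len, d$fend),
      fwd = rep(c(TRUE, FALSE), each = nrow(d)),
      first = rep(c(TRUE, FALSE), each = nrow(d)))
  }
  reads <- rbindlist(out)
  reads
}

#' Project simulated reads into truth-aware alignments
#'
#' Emulates a BWA-style aligner without running one: reads wholly inside
#' unmodified sequence map at the lifted reference coordinate with a
#' full-match CIGAR at MAPQ 60; reads crossing an insertion boundary map to
#' the flank with the element-derived part soft-clipped (flank anchor of at
#' least 20 bp required); reads wholly inside an inserted element map onto a
#' decoy contig named after the element class at the corresponding consensus
#' offset, so straddling pairs satisfy the different-chromosome DRP
#' definition. Deletion-haplotype reads crossing the removed interval are
#' clipped at the junction. Mates' fields are mutually consistent; output is
#' coordinate-sorted.
#'
#' @param frags fragment table from [simulate_reads()].
#' @param planted [plant_insertions()] result (blocks provide provenance).
#' @param ref [make_reference()] result.
#' @param library an [me_library()].
#' @param config [sim_config()].
#' @param sample sample id for the alignment table.
#' @return an [aln_table()] including decoy contigs in its seqlengths.
#' @export
project_alignments <- function(frags, planted, ref, library, config,
                               sample = "S1") {
  rl <- config$read_len
  reads <- fragment_reads(frags, planted, rl)
  specs_trunc <- planted$truth$trunc
  parts <- list()
  for (hi in 1:2) {
    d <- reads[hap == hi]
    if (nrow(d) == 0L) next
    hp <- planted$haps[[hi]]
    blocks <- hp$blocks
    hseq <- hp$seq
    bi_a <- findInterval(d$a, blocks$d_start)
    bi_b <- findInterval(d$b - 1L, blocks$d_start)
    d[, `:=`(ba = bi_a, bb = bi_b)]
    d[, raw := substring(hseq, a + 1L, b)]   # donor-forward read bases
    ta <- blocks$type[bi_a]; tb <- blocks$type[bi_b]
    ins_a <- blocks$ins[bi_a]; ins_b <- blocks$ins[bi_b]
    rs_a <- blocks$ref_start[bi_a]; rs_b <- blocks$ref_start[bi_b]
    ds_a <- blocks$d_start[bi_a]; de_a <- blocks$d_end[bi_a]
    ds_b <- blocks$d_start[bi_b]
    chrom <- rep(NA_character_, nrow(d)); pos <- rep(NA_integer_, nrow(d))
    cig <- rep(NA_character_, nrow(d)); seqs <- d$raw
    strand <- ifelse(d$fwd, "+", "-")
    same <- bi_a == bi_b
    ## case 1: wholly inside one ref block
    c1 <- which(same & ta == "ref")
    chrom[c1] <- hp$chrom
    pos[c1] <- rs_a[c1] + (d$a[c1] - ds_a[c1])
    cig[c1] <- sprintf("%dM", rl)
    ## case 2: wholly inside one insertion -> decoy contig
    c2 <- which(same & ta == "ins")
    if (length(c2)) {
      cls <- planted$truth$class[ins_a[c2]]
      Lc <- vapply(library[cls], `[[`, 0L, "length")
      off <- specs_trunc[ins_a[c2]] + (d$a[c2] - ds_a[c2])
      chrom[c2] <- cls
      pos[c2] <- pmax(0L, pmin(off, Lc - rl))
      cig[c2] <- sprintf("%dM", rl)
      strand[c2] <- "+"
      seqs[c2] <- ifelse(d$fwd[c2], d$raw[c2], revcomp(d$raw[c2]))
    }
    ## case 3: boundary-crossing reads
    c3 <- which(!same)
    for (i in c3) {
      lpart <- de_a[i] - d$a[i]       # bases in the left block
      rpart <- rl - lpart
      left_ref <- ta[i] == "ref"; right_ref <- tb[i] == "ref"
      if (left_ref && right_ref) {          # deletion jump: larger part anchors
        if (lpart >= rpart) {
          chrom[i] <- hp$chrom; pos[i] <- rs_a[i] + (d$a[i] - ds_a[i])
          cig[i] <- sprintf("%dM%dS", lpart, rpart)
        } else {
          chrom[i] <- hp$chrom; pos[i] <- rs_b[i]
          cig[i] <- sprintf("%dS%dM", lpart, rpart)
        }
      } else if (left_ref && lpart >= 20L) {
        chrom[i] <- hp$chrom; pos[i] <- rs_a[i] + (d$a[i] - ds_a[i])
        cig[i] <- sprintf("%dM%dS", lpart, rpart)
      } else if (right_ref && rpart >= 20L) {
        chrom[i] <- hp$chrom; pos[i] <- rs_b[i]
        cig[i] <- sprintf("%dS%dM", lpart, rpart)
      } else {
        ## anchor too short: treat as element-interior
        ii <- if (!left_ref) ins_a[i] else ins_b[i]
        cls <- planted$truth$class[ii]
        Lc <- library[[cls]]$length
        off <- if (!left_ref) specs_trunc[ii] + (d$a[i] - ds_a[i])
               else specs_trunc[ii]
        chrom[i] <- cls
        pos[i] <- max(0L, min(off, Lc - rl))
        cig[i] <- sprintf("%dM", rl)
        seqs[i] <- if (d$fwd[i]) d$raw[i] else revcomp(d$raw[i])
        strand[i] <- "+"
      }
    }
    parts[[hi]] <- data.table(qname = d$qname, chrom = chrom, pos = pos,
                              strand = strand, cigar = cig, seq = seqs,
                              first = d$first)
  }
  al <- rbindlist(parts)
  if (config$base_error > 0) al[, seq := apply_errors(seq, config$base_error,
                                                      derive_seed(config$seed, "err"))]
  ## mate fields
  mates <- al[, .(qname, m_chrom = chrom, m_pos = pos, m_strand = strand,
                  m_first = first)]
  al <- merge(al, mates[, .(qname, first2 = !m_first, m_chrom, m_pos, m_strand)],
              by.x = c("qname", "first"), by.y = c("qname", "first2"))
  rlen_ref <- cigar_rlen(al$cigar)
  ## properness: both on the reference chromosome, inward, sane span
  ref_chrom <- planted$haps[[1L]]$chrom
  span_lo <- pmin(al$pos, al$m_pos)
  span_hi <- pmax(al$pos + rlen_ref, al$m_pos + rl)
  al[, proper := chrom == ref_chrom & m_chrom == ref_chrom &
       strand != m_strand &
       (span_hi - span_lo) <= config$frag_mean + 4 * config$frag_sd &
       (span_hi - span_lo) >= rl]
  al[, `:=`(mchrom = m_chrom, mpos = m_pos, mstrand = m_strand,
            mapq = 60L, unmapped = FALSE, munmapped = FALSE,
            sample = sample)]
  sl <- c(setNames(nchar(ref$seqs), names(ref$seqs)),
          vapply(library, `[[`, 0L, "length"))
  aln_table(al[, .(qname, sample, chrom, pos, strand, mapq, cigar, seq,
                   mchrom, mpos, mstrand, first, proper, unmapped,
                   munmapped)], sl)
}

apply_errors <- function(seqs, rate, seed) {
  with_seed(seed, {
    vapply(seqs, function(s) {
      n <- nchar(s)
      k <- rbinom(1L, n, rate)
      if (k == 0L) return(s)
      pos <- sample.int(n, k)
      ch <- strsplit(s, "")[[1L]]
      ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(DNA_BASES, b), 1L), "")
      paste(ch, collapse = "")
    }, "", USE.NAMES = FALSE)
  })
}

#' Simulate a complete single-sample data set
#'
#' Reference construction, insertion drawing, planting, read simulation and
#' truth-aware projection in one call.
#'
#' @param config [sim_config()].
#' @param library an [me_library()]; default [default_me_library()].
#' @param sample sample id.
#' @return list: `config, library, ref, specs, planted, truth, frags, aln`.
#' @export
simulate_dataset <- function(config = sim_config(), library = default_me_library(),
                             sample = "S1") {
  ref <- make_reference(config, library)
  specs <- draw_insertion_specs(config, library, ref)
  planted <- plant_insertions(ref, specs, library)
  frags <- simulate_reads(planted, config)
  aln <- project_alignments(frags, planted, ref, library, config, sample)
  list(config = config, library = library, ref = ref, specs = specs,
       planted = planted, truth = planted$truth, frags = frags, aln = aln)
}

#' Compare calls against simulated truth
#'
#' Greedy one-to-one matching by distance: a call is correct if it lies
#' within `window` bp (default 500) of a truth site of the same class.
#'
#' @param calls call table (`chrom, pos, class`).
#' @param truth truth table (`chrom, pos, class`).
#' @param window matching window (bp).
#' @return data.table per class (plus `ALL`): TP, FP, FN, FNR, FDR.
#' @export
evaluate_calls <- function(calls, truth, window = 500L) {
  calls <- as.data.table(calls); truth <- as.data.table(truth)
  classes <- sort(unique(c(calls$class, truth$class)))
  rows <- lapply(classes, function(cls) {
    cc <- calls[class == cls]; tt <- truth[class == cls]
    matched_c <- rep(FALSE, nrow(cc)); matched_t <- rep(FALSE, nrow(tt))
    if (nrow(cc) && nrow(tt)) {
      pairs <- CJ(ci = seq_len(nrow(cc)), ti = seq_len(nrow(tt)))
      pairs[, dist := abs(cc$pos[ci] - tt$pos[ti]) +
              ifelse(cc$chrom[ci] == tt$chrom[ti], 0L, NA_integer_)]
      pairs <- pairs[!is.na(dist) & dist <= window][order(dist, ci, ti)]
      for (k in seq_len(nrow(pairs))) {
        ci <- pairs$ci[k]; ti <- pairs$ti[k]
        if (!matched_c[ci] && !matched_t[ti]) {
          matched_c[ci] <- TRUE; matched_t[ti] <- TRUE
        }
      }
    }
    tp <- sum(matched_c); fp <- nrow(cc) - tp; fn <- nrow(tt) - sum(matched_t)
    data.table(class = cls, TP = tp, FP = fp, FN = fn,
               FNR = if (tp + fn > 0) fn / (tp + fn) else 0,
               FDR = if (tp + fp > 0) fp / (tp + fp) else 0)
  })
  res <- rbindlist(rows)
  tot <- res[, .(class = "ALL", TP = sum(TP), FP = sum(FP), FN = sum(FN))]
  tot[, `:=`(FNR = ifelse(TP + FN > 0, FN / (TP + FN), 0),
             FDR = ifelse(TP + FP > 0, FP / (TP + FP), 0))]
  rbind(res, tot)
}

#' Deletion-mode simulation configuration
#'
#' Mirrors the insertion benchmark but removes annotated reference-ME copies
#' from the simulated donor instead: the design scales the 400 Alu / 50 L1
#' polymorphic reference-deletion layout by `scale`.
#'
#' @param ref_len reference length.
#' @param scale scaling of the 400/50 deletion counts.
#' @param del_counts explicit deletion counts, overriding `scale`.
#' @param coverage,read_len,frag_mean,frag_sd,base_error read parameters.
#' @param het_frac heterozygous fraction (95%).
#' @param seed integer seed.
#' @return named list.
#' @export
sim_del_config <- function(ref_len = 2e6L, scale = 0.1, del_counts = NULL,
                           coverage = 30, het_frac = 0.95, read_len = 100L,
                           frag_mean = 500L, frag_sd = 50L, base_error = 0,
                           seed = 1L) {
  if (is.null(del_counts))
    del_counts <- round(c(ALU = 400, LINE1 = 50) * scale)
  as.list(environment())
}

#' Simulate a reference-ME deletion data set
#'
#' Embeds enough reference-ME copies for the configured deletion counts,
#' removes a subset from the donor haplotypes (het to one haplotype, hom to
#' both), simulates reads and projects them (reads crossing a removed
#' interval are soft-clipped at the junction; jumping pairs get long
#' apparent inserts).
#'
#' @param config [sim_del_config()].
#' @param library an [me_library()].
#' @param sample sample id.
#' @return list: `ref`, `truth` (deleted intervals with zygosity), `aln`,
#'   `config`.
#' @export
simulate_deletion_dataset <- function(config = sim_del_config(),
                                      library = default_me_library(),
                                      sample = "S1") {
  n_del_alu <- if ("ALU" %in% names(config$del_counts))
    config$del_counts[["ALU"]] else 0L
  n_del_l1 <- if ("LINE1" %in% names(config$del_counts))
    config$del_counts[["LINE1"]] else 0L
  refcfg <- sim_config(ref_len = config$ref_len, counts = c(ALU = 0),
                       n_ref_alu = n_del_alu + 4L,
                       n_ref_l1 = n_del_l1 + 2L,
                       n_fl_l1 = 0L, seed = config$seed)
  ref <- make_reference(refcfg, library)
  truth <- with_seed(derive_seed(config$seed, "del_specs"), {
    picks <- list()
    for (cls in names(config$del_counts)) {
      k <- config$del_counts[[cls]]
      avail <- which(ref$ref_me$label == cls)
      picks[[cls]] <- sample(avail, min(k, length(avail)))
    }
    idx <- sort(unlist(picks))
    d <- ref$ref_me[idx]
    d[, `:=`(zygosity = ifelse(runif(.N) < config$het_frac, "het", "hom"),
             id = sprintf("del_%04d", .I))]
    d[, haplotype := ifelse(zygosity == "hom", 0L, sample(1:2, .N, replace = TRUE))]
    d[]
  })
  base <- ref$seqs[["chr1"]]
  build_hap <- function(hi) {
    use <- truth[zygosity == "hom" | haplotype == hi][order(start)]
    pieces <- character(0); blocks <- list(); cur <- 0L; cur_d <- 0L
    for (i in seq_len(nrow(use))) {
      s <- use$start[i]; e <- use$end[i]
      pieces <- c(pieces, substring(base, cur + 1L, s))
      blocks[[length(blocks) + 1L]] <- data.table(
        d_start = cur_d, d_end = cur_d + s - cur, type = "ref",
        ref_start = cur, ins = NA_integer_)
      cur_d <- cur_d + s - cur
      cur <- e
    }
    pieces <- c(pieces, substring(base, cur + 1L, nchar(base)))
    blocks[[length(blocks) + 1L]] <- data.table(
      d_start = cur_d, d_end = cur_d + nchar(base) - cur, type = "ref",
      ref_start = cur, ins = NA_integer_)
    list(seq = paste(pieces, collapse = ""), blocks = rbindlist(blocks),
         chrom = "chr1")
  }
  planted <- list(haps = list(build_hap(1L), build_hap(2L)),
                  truth = data.table(class = character(0), trunc = integer(0)))
  frags <- simulate_reads(planted, config)
  aln <- project_alignments(frags, planted, ref, library, config, sample)
  list(ref = ref, truth = truth, aln = aln, config = config)
}
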