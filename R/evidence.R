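## Evidence extraction: discordant read pairs (DRPs) and split reads (SRs).

#' Classify a mate pair
#'
#' A pair is a discordant-read-pair candidate when the mates are aligned to
#' different chromosomes or are separated by at least `min_separation`
#' (default 1 Mbp, inclusive). Symmetric in its arguments.
#'
#' @param a,b mate records: lists/rows with `chrom`, `pos`, `unmapped`,
#'   `proper`.
#' @param min_separation inclusive same-chromosome separation bound.
#' @return one of `"CONCORDANT"`, `"DRP_CANDIDATE"`, `"ONE_END_UNMAPPED"`,
#'   `"UNINFORMATIVE"`.
#' @export
classify_pair <- function(a, b, min_separation = 1000000L) {
  ua <- isTRUE(a$unmapped); ub <- isTRUE(b$unmapped)
  if (ua && ub) return("UNINFORMATIVE")
  if (ua || ub) return("ONE_END_UNMAPPED")
  if (a$chrom != b$chrom || abs(a$pos - b$pos) >= min_separation)
    return("DRP_CANDIDATE")
  if (isTRUE(a$proper) && isTRUE(b$proper)) return("CONCORDANT")
  "UNINFORMATIVE"
}

## vectorised version over a paired table (columns *.1 / *.2)
classify_pairs_vec <- function(pp, min_separation) {
  cls <- rep("UNINFORMATIVE", nrow(pp))
  u1 <- pp$unmapped.1; u2 <- pp$unmapped.2
  cls[xor(u1, u2)] <- "ONE_END_UNMAPPED"
  mapped <- !u1 & !u2
  drp <- mapped & (pp$chrom.1 != pp$chrom.2 |
                     abs(pp$pos.1 - pp$pos.2) >= min_separation)
  cls[drp] <- "DRP_CANDIDATE"
  conc <- mapped & !drp & pp$proper.1 & pp$proper.2
  cls[conc] <- "CONCORDANT"
  cls
}

## orient a mate's stored sequence to the donor-forward strand of the
## insertion, so that consensus alignment strand reflects element polarity:
## revcomp when anchor and mate share the stored strand (unmapped mates are
## treated as stored on "+")
donor_forward <- function(seq, anchor_strand, mate_strand, mate_unmapped) {
  ms <- ifelse(mate_unmapped, "+", mate_strand)
  flip <- anchor_strand == ms
  out <- seq
  if (any(flip)) out[flip] <- revcomp(seq[flip])
  out
}

#' Extract DRP and split-read evidence from one sample's alignments
#'
#' Scans a coordinate-sorted alignment table, classifies mate pairs, and
#' realigns the non-anchor mate of each discordant/one-end-unmapped pair (and
#' every soft-clip tail of at least `min_clip` bases) against the consensus
#' library. One-end-unmapped pairs are admitted as DRP candidates because
#' reads lying wholly inside a novel insertion may be unmapped; set
#' `strict = TRUE` to restrict to the mapped-mapped definition.
#'
#' @param aln an [aln_table()] for one sample.
#' @param library an [me_library()].
#' @param params [mei_params()].
#' @param strict drop one-end-unmapped pairs (mapped-mapped definition only).
#' @return evidence bundle: list with `sample`, `drp` (anchor + consensus
#'   alignment per discordant fragment), `sr` (split reads), and `summary`
#'   (per-chromosome coverage and median depth, fragment stats).
#' @export
extract_evidence <- function(aln, library, params = mei_params(), strict = FALSE) {
  sl <- attr(aln, "seqlengths")
  sample <- if (nrow(aln)) aln$sample[1L] else "S1"
  aln <- aln[dup == FALSE]
  rlen <- cigar_rlen(aln$cigar)
  aln[, `:=`(.end = pos + rlen, .row = .I)]

  ## ---- coverage summary
  mapped <- aln[unmapped == FALSE]
  coverage <- lapply(names(sl), function(ch) {
    d <- mapped[chrom == ch]
    if (nrow(d) == 0L) return(S4Vectors::Rle(0L, sl[[ch]]))
    IRanges::coverage(IRanges::IRanges(d$pos + 1L, pmin(d$.end, sl[[ch]])),
                      width = sl[[ch]])
  })
  names(coverage) <- names(sl)
  median_depth <- vapply(coverage, function(r) as.numeric(median(r)), 0)

  ## ---- pair up mates
  p1 <- aln[first == TRUE]
  p2 <- aln[first == FALSE]
  pp <- merge(p1, p2, by = "qname", suffixes = c(".1", ".2"))
  cls <- classify_pairs_vec(pp, params$min_separation)

  ## fragment stats from concordant pairs
  conc <- pp[cls == "CONCORDANT"]
  if (nrow(conc) >= 50L) {
    span <- pmax(conc$.end.1, conc$.end.2) - pmin(conc$pos.1, conc$pos.2)
    frag_mean <- as.numeric(median(span))
    frag_sd <- max(10, as.numeric(mad(span)))
  } else {
    frag_mean <- as.numeric(params$frag_len); frag_sd <- 50
  }
  read_len <- if (nrow(aln)) as.integer(median(nchar(aln$seq))) else 100L

  ## ---- DRP candidates: each adequately mapped mate may anchor the pair
  keep <- cls == "DRP_CANDIDATE" | (!strict & cls == "ONE_END_UNMAPPED")
  cand <- pp[keep]
  drp <- empty_drp()
  if (nrow(cand)) {
    half <- function(a, m) data.table(
      qname = cand$qname,
      anchor_chrom = cand[[paste0("chrom", a)]], anchor_pos = cand[[paste0("pos", a)]],
      anchor_end = cand[[paste0(".end", a)]], anchor_strand = cand[[paste0("strand", a)]],
      anchor_mapq = cand[[paste0("mapq", a)]], anchor_unmapped = cand[[paste0("unmapped", a)]],
      mate_seq = cand[[paste0("seq", m)]], mate_strand = cand[[paste0("strand", m)]],
      mate_unmapped = cand[[paste0("unmapped", m)]])
    h <- rbind(half(".1", ".2"), half(".2", ".1"))
    ## anchors live on the genome: alignments onto the consensus/decoy
    ## contigs themselves never anchor a site
    h <- h[anchor_unmapped == FALSE & anchor_mapq >= params$min_anchor_mapq &
             !anchor_chrom %in% names(library)]
    if (nrow(h)) {
      h[, dseq := donor_forward(mate_seq, anchor_strand, mate_strand, mate_unmapped)]
      ma <- align_to_consensus(h$dseq, library, params)
      hit <- !is.na(ma$cons)
      if (any(hit)) {
        drp <- data.table(sample = sample, qname = h$qname[hit],
                          chrom = h$anchor_chrom[hit], pos = h$anchor_pos[hit],
                          end = h$anchor_end[hit], strand = h$anchor_strand[hit],
                          mapq = h$anchor_mapq[hit], seq = h$dseq[hit],
                          ma[hit])
        setorder(drp, chrom, pos)
      }
    }
  }

  ## ---- split reads: soft clips >= min_clip on adequately mapped reads
  cl <- clip_lens(aln$cigar)
  sr <- empty_sr()
  srrows <- list()
  base <- aln[, .(qname, sample, chrom, pos, .end, mapq, seq, unmapped)]
  on_genome <- !aln$unmapped & !aln$chrom %in% names(library)
  lead <- which(on_genome & aln$mapq >= params$min_anchor_mapq &
                  cl$lead >= params$min_clip)
  if (length(lead))
    srrows$L <- data.table(base[lead], side = "L", clip_pos = aln$pos[lead],
                           clip_seq = substring(aln$seq[lead], 1L, cl$lead[lead]))
  trail <- which(on_genome & aln$mapq >= params$min_anchor_mapq &
                   cl$trail >= params$min_clip)
  if (length(trail))
    srrows$R <- data.table(base[trail], side = "R", clip_pos = aln$.end[trail],
                           clip_seq = substring(aln$seq[trail],
                                                nchar(aln$seq[trail]) - cl$trail[trail] + 1L,
                                                nchar(aln$seq[trail])))
  if (length(srrows)) {
    sr <- rbindlist(srrows)
    ## clips can be as short as min_clip; relax the aligned-length floor so a
    ## clean 20-25 bp clip still gets its consensus placement attached
    clip_params <- params
    clip_params$min_aln_len <- min(params$min_aln_len, params$min_clip)
    ma <- align_to_consensus(sr$clip_seq, library, clip_params)
    sr <- data.table(sample = sr$sample, qname = sr$qname, chrom = sr$chrom,
                     clip_pos = sr$clip_pos, side = sr$side,
                     clip_seq = sr$clip_seq, ma)
    setorder(sr, chrom, clip_pos)
  }

  aln[, c(".end", ".row") := NULL]
  structure(list(sample = sample, drp = drp, sr = sr,
                 summary = list(coverage = coverage, median_depth = median_depth,
                                frag_mean = frag_mean, frag_sd = frag_sd,
                                read_len = read_len, seqlengths = sl)),
            class = "mei_evidence")
}

empty_drp <- function() data.table(
  sample = character(0), qname = character(0), chrom = character(0),
  pos = integer(0), end = integer(0), strand = character(0), mapq = integer(0),
  seq = character(0), cons = character(0), c_start = integer(0),
  c_end = integer(0), c_strand = character(0), identity = numeric(0),
  score = integer(0), qstart = integer(0), qend = integer(0), aln = character(0))

empty_sr <- function() data.table(
  sample = character(0), qname = character(0), chrom = character(0),
  clip_pos = integer(0), side = character(0), clip_seq = character(0),
  cons = character(0), c_start = integer(0), c_end = integer(0),
  c_strand = character(0), identity = numeric(0), score = integer(0),
  qstart = integer(0), qend = integer(0), aln = character(0))

#' @export
print.mei_evidence <- function(x, ...) {
  cat(sprintf("sample %s: %d DRPs, %d split reads; median depth %s\n",
              x$sample, nrow(x$drp), nrow(x$sr),
              paste(sprintf("%s=%.1f", names(x$summary$median_depth),
                            x$summary$median_depth), collapse = " ")))
  invisible(x)
}
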