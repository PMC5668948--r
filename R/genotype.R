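## Per-sample genotype likelihoods for non-reference insertions and
## reference-ME deletions: diploid binomial mixture with per-read error e.
## For g alt copies, p(g) = (g/2)(1-e) + (1-g/2)e and
## L(g) = p(g)^a * (1-p(g))^b over a alt-supporting and b ref-supporting
## fragments, flat prior, log10-scaled likelihoods normalised to max 0.

#' Genotype likelihoods from evidence counts
#'
#' @param a alt-supporting fragment count(s).
#' @param b ref-supporting fragment count(s).
#' @param e per-read error rate (0 < e < 0.5).
#' @param min_informative below `a + b` of this, the call is `./.`.
#' @return data.table `gt`, `gl` (three comma-joined log10 likelihoods,
#'   max exactly 0), `gq`, `ad_ref`, `ad_alt`.
#' @export
genotype_likelihoods <- function(a, b, e = 0.01, min_informative = 2L) {
  stopifnot(e > 0, e < 0.5, all(a >= 0), all(b >= 0))
  if (length(a) == 0L && length(b) == 0L)
    return(data.table(gt = character(0), gl = character(0), gq = integer(0),
                      ad_ref = integer(0), ad_alt = integer(0)))
  n <- max(length(a), length(b))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  p <- c(e, 0.5, 1 - e)
  ll <- sapply(p, function(pg) a * log10(pg) + b * log10(1 - pg))
  ll <- matrix(ll, nrow = n)
  best <- max.col(ll, ties.method = "first")
  ll0 <- ll - apply(ll, 1L, max)
  second <- vapply(seq_len(n), function(i) max(ll[i, -best[i]]), 0)
  gq <- as.integer(pmin(99, round(10 * (apply(ll, 1L, max) - second))))
  gt <- c("0/0", "0/1", "1/1")[best]
  nocall <- (a + b) < min_informative
  gt[nocall] <- "./."
  gq[nocall] <- 0L
  gl <- apply(round(ll0, 2L), 1L, paste, collapse = ",")
  gl[nocall] <- "0,0,0"
  data.table(gt = gt, gl = gl, gq = gq,
             ad_ref = as.integer(b), ad_alt = as.integer(a))
}

## pair reads of one sample near sites into fragment spans with clip info
sample_fragments <- function(aln) {
  rlen <- cigar_rlen(aln$cigar)
  cl <- clip_lens(aln$cigar)
  dt <- data.table(qname = aln$qname, chrom = aln$chrom, pos = aln$pos,
                   end = aln$pos + rlen, proper = aln$proper,
                   unmapped = aln$unmapped,
                   maxclip = pmax(cl$lead, cl$trail))
  dt <- dt[unmapped == FALSE]
  dt[, .(chrom = chrom[1L], lo = min(pos), hi = max(end),
         same = uniqueN(chrom) == 1L, proper = all(proper), n = .N,
         maxclip = max(maxclip)), by = qname]
}

#' Count genotyping evidence for calls in one sample
#'
#' Alt support `a` is the sample's discordant fragments assigned to the site
#' plus split reads clipped within `sr_bp_slack` of the breakpoint; ref
#' support `b` is proper pairs whose fragment span cleanly covers the
#' breakpoint window (+/- `ref_span_pad`), with no soft clip of 5 bp or
#' more and a fragment length within 3 SD of the sample mean (which
#' excludes pairs that actually jump the inserted sequence). A fragment
#' contributes at most one unit.
#'
#' @param calls call table.
#' @param aln the sample's [aln_table()].
#' @param drp,sr the sample's evidence (with `site_id`).
#' @param params [mei_params()].
#' @param frag_mean,frag_sd fragment-length statistics for the sample.
#' @return data.table `site_id`, `a`, `b`.
#' @export
count_evidence <- function(calls, aln, drp, sr, params = mei_params(),
                           frag_mean = 500, frag_sd = 50) {
  frags <- sample_fragments(aln)
  out <- data.table(site_id = calls$site_id, a = 0L, b = 0L)
  if (nrow(calls) == 0L) return(out)
  lo_ok <- frag_mean - 3 * frag_sd
  hi_ok <- frag_mean + 3 * frag_sd
  for (i in seq_len(nrow(calls))) {
    sid <- calls$site_id[i]; bp <- calls$pos[i]; ch <- calls$chrom[i]
    alt_q <- unique(c(
      drp[!is.na(site_id) & site_id == sid]$qname,
      sr[!is.na(site_id) & site_id == sid &
           abs(clip_pos - bp) <= params$sr_bp_slack]$qname))
    span <- frags[chrom == ch & same & proper & n == 2L &
                    lo <= bp - params$ref_span_pad &
                    hi >= bp + params$ref_span_pad &
                    maxclip < 5L &
                    (hi - lo) >= lo_ok & (hi - lo) <= hi_ok]
    ref_q <- setdiff(unique(span$qname), alt_q)
    set(out, i, c("a", "b"), list(length(alt_q), length(ref_q)))
  }
  out
}

#' Genotype all samples at all called sites
#'
#' @param calls call table.
#' @param evidence_by_sample named list of per-sample evidence bundles (with
#'   site-assigned `drp`/`sr`, see [discover_sites()] pooling).
#' @param aln_by_sample named list of per-sample [aln_table()]s.
#' @param params [mei_params()].
#' @return long genotype table (`site_id, sample, gt, gl, gq, ad_ref,
#'   ad_alt, a, b`).
#' @export
genotype_samples <- function(calls, evidence_by_sample, aln_by_sample,
                             params = mei_params()) {
  rows <- lapply(names(aln_by_sample), function(sm) {
    ev <- evidence_by_sample[[sm]]
    cnt <- count_evidence(calls, aln_by_sample[[sm]], ev$drp, ev$sr, params,
                          ev$frag_mean %||% 500, ev$frag_sd %||% 50)
    gl <- genotype_likelihoods(cnt$a, cnt$b, params$err, params$min_informative)
    data.table(site_id = cnt$site_id, sample = sm, gl, a = cnt$a, b = cnt$b)
  })
  rbindlist(rows)
}

#' Post-genotyping site filters
#'
#' Adds `lc` when DRP evidence is single-sided, `hNC` when the no-call
#' fraction exceeds `nc_max`, `noSR` when there is no split read across all
#' samples; a site is PASS iff it carries no flag (including discovery
#' flags).
#'
#' @param calls call table.
#' @param genotypes long genotype table.
#' @param params [mei_params()].
#' @return `calls` with updated `filters`.
#' @export
apply_site_filters <- function(calls, genotypes, params = mei_params()) {
  calls <- copy(calls)
  if (nrow(calls) == 0L) return(calls)
  nc <- genotypes[, .(frac = mean(gt == "./.")), by = site_id]
  for (i in seq_len(nrow(calls))) {
    f <- if (nzchar(calls$filters[i])) strsplit(calls$filters[i], ",")[[1L]] else character(0)
    if (calls$n_left[i] == 0L || calls$n_right[i] == 0L) f <- union(f, "lc")
    fr <- nc[site_id == calls$site_id[i]]$frac
    if (length(fr) && fr > params$nc_max) f <- union(f, "hNC")
    if (calls$n_srL[i] + calls$n_srR[i] == 0L) f <- union(f, "noSR")
    set(calls, i, "filters", paste(f, collapse = ","))
  }
  calls
}

#' Genotype a reference mobile-element interval for deletion
#'
#' Alt (deletion) support: fragments whose mates jump the interval — both
#' reads outside it with the implied fragment (reference span minus interval
#' length) within 3 SD of the fragment mean — plus reads soft-clipped at
#' either interval edge joining the flanks. Ref support: reads mapped
#' wholly inside the interval with MAPQ >= `min_anchor_mapq`. Same
#' likelihood model as insertion genotyping. Intervals shorter than two
#' read lengths are not assessable (`./.`).
#'
#' @param interval list/row with `chrom`, `start`, `end` (0-based half-open).
#' @param aln the sample's [aln_table()].
#' @param params [mei_params()].
#' @param frag_mean,frag_sd,read_len sample statistics.
#' @return one-row data.table as from [genotype_likelihoods()], plus
#'   `a`, `b`.
#' @export
genotype_deletion <- function(interval, aln, params = mei_params(),
                              frag_mean = 500, frag_sd = 50, read_len = 100L) {
  s <- interval$start; e <- interval$end; ch <- interval$chrom
  if (e - s < 2L * read_len) {
    warning(sprintf("interval %s:%d-%d shorter than two read lengths: not assessable",
                    ch, s, e))
    return(data.table(gt = "./.", gl = "0,0,0", gq = 0L,
                      ad_ref = 0L, ad_alt = 0L, a = 0L, b = 0L))
  }
  near <- aln[unmapped == FALSE & chrom == ch &
                pos < e + 2L * frag_mean & pos + 200L > s - 2L * frag_mean]
  rlen <- cigar_rlen(near$cigar)
  cl <- clip_lens(near$cigar)
  rd <- data.table(qname = near$qname, pos = near$pos, end = near$pos + rlen,
                   mapq = near$mapq, lead = cl$lead, trail = cl$trail)
  ## deletion-supporting: jumping pairs ...
  pr <- rd[, .(lo = min(pos), hi = max(end), inner_lo = min(end),
               inner_hi = max(pos), n = .N), by = qname]
  jump <- pr[n == 2L & inner_lo <= s + 5L & inner_hi >= e - 5L &
               abs((hi - lo) - (e - s) - frag_mean) <= 3 * frag_sd]
  ## ... plus reads clipped at an interval edge
  clipped <- rd[(abs(end - s) <= 3L & trail >= 5L) |
                  (abs(pos - e) <= 3L & lead >= 5L)]
  alt_q <- unique(c(jump$qname, clipped$qname))
  ## reference-supporting: reads wholly inside the interval; restricted to
  ## within one fragment length of an edge so ref counts scale with fragment
  ## length (like the jumping-pair alt counts) rather than interval length
  inside <- rd[pos >= s & end <= e & mapq >= params$min_anchor_mapq &
                 lead < 5L & trail < 5L &
                 (pos <= s + frag_mean | end >= e - frag_mean)]
  ref_q <- setdiff(unique(inside$qname), alt_q)
  g <- genotype_likelihoods(length(alt_q), length(ref_q),
                            params$err, params$min_informative)
  data.table(g, a = length(alt_q), b = length(ref_q))
}

#' Genotype reference-ME deletions across samples
#'
#' @param ref_mes interval table (`chrom,start,end,label`).
#' @param aln_by_sample named list of per-sample [aln_table()]s.
#' @param params [mei_params()].
#' @param frag_mean,frag_sd,read_len fragment statistics.
#' @return list with `calls` (one row per interval, `<DEL:ME:*>`-style) and
#'   `genotypes` (long table), ready for [write_vcf()] with `svtype="DEL"`.
#' @export
genotype_deletions <- function(ref_mes, aln_by_sample, params = mei_params(),
                               frag_mean = 500, frag_sd = 50, read_len = 100L) {
  ref_mes <- as.data.table(ref_mes)
  calls <- data.table(
    site_id = sprintf("del_%04d", seq_len(nrow(ref_mes))),
    chrom = ref_mes$chrom, pos = ref_mes$start, class = toupper(ref_mes$label),
    orientation = "+", cons_start = 0L,
    cons_stop = ref_mes$end - ref_mes$start,
    svlen = -(ref_mes$end - ref_mes$start), tsd = "", tsdel = 0L,
    tranche = NA_integer_, filters = "", subfamily = "", mutations = "",
    inv5 = NA, inv_junction = NA_integer_, tdn_locus = "", tdn_source = "",
    gene_impact = "")
  calls[, tranche := 0L]
  gts <- rbindlist(lapply(names(aln_by_sample), function(sm) {
    g <- rbindlist(lapply(seq_len(nrow(ref_mes)), function(i)
      suppressWarnings(genotype_deletion(as.list(ref_mes[i]), aln_by_sample[[sm]],
                                         params, frag_mean, frag_sd, read_len))))
    data.table(site_id = calls$site_id, sample = sm, g)
  }))
  list(calls = calls, genotypes = gts)
}
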