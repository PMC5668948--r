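## Candidate-site discovery: single-linkage clustering of DRP anchors across
## samples, annotation-based filters, split-read breakpoint/TSD refinement,
## orientation assignment and the 0-5 quality tranche.

#' Cluster DRP anchors into candidate sites
#'
#' Single-linkage clustering of anchor positions per chromosome with maximum
#' gap `window`; clusters reaching `min_drp` fragments (summed over all
#' samples) become candidate sites. Anchors on the `+` strand point into the
#' site from the left, `-` anchors from the right.
#'
#' @param drp pooled DRP table (see [extract_evidence()]).
#' @param window maximum gap between consecutive anchors (bp).
#' @param min_drp cluster admission threshold.
#' @return list with `sites` (one row per candidate) and `drp` (input with a
#'   `site_id` column; NA for anchors not in any admitted cluster).
#' @export
cluster_drps <- function(drp, window = 500L, min_drp = 4L) {
  drp <- copy(as.data.table(drp))
  if (nrow(drp) == 0L)
    return(list(sites = empty_sites(), drp = drp[, site_id := character(0)]))
  setorder(drp, chrom, pos)
  drp[, cluster := cumsum(c(1L, (diff(pos) > window) | (chrom[-1L] != chrom[-.N])))]
  drp[, n := .N, by = cluster]
  drp[, site_id := ifelse(n >= min_drp, paste0("site_", chrom, "_", cluster), NA_character_)]
  sites <- summarize_sites(drp)
  drp[, c("cluster", "n") := NULL]
  list(sites = sites, drp = drp)
}

## per-site summary from site-assigned DRPs
summarize_sites <- function(drp) {
  if (nrow(drp) == 0L || !any(!is.na(drp$site_id))) return(empty_sites())
  sites <- drp[!is.na(site_id), {
    left <- strand == "+"
    .(chrom = chrom[1L], win_start = min(pos), win_end = max(end),
      n_drp = .N, n_left = sum(left), n_right = sum(!left),
      left_max_end = if (any(left)) max(end[left]) else NA_integer_,
      right_min_start = if (any(!left)) min(pos[!left]) else NA_integer_,
      class = class_vote(cons), n_samples = uniqueN(sample))
  }, by = site_id]
  if (nrow(sites)) setorder(sites, chrom, win_start)
  sites
}

#' Split merged candidate sites at well-separated split-read groups
#'
#' Two insertions slightly more than a cluster window apart can chain into
#' one anchor cluster. When a site's clip positions form groups separated by
#' more than `gap` bp (far beyond any plausible target-site duplication),
#' the site's evidence is partitioned at the midpoints between groups and
#' each part re-admitted against the DRP threshold.
#'
#' @param sites,drp,sr clustering output.
#' @param min_drp cluster admission threshold.
#' @param gap minimum separation (bp) between clip groups to trigger a split.
#' @return list(`sites`, `drp`, `sr`) with updated site assignments.
#' @export
split_merged_sites <- function(sites, drp, sr, min_drp = 4L, gap = 150L) {
  if (nrow(sites) == 0L || nrow(sr) == 0L)
    return(list(sites = sites, drp = drp, sr = sr))
  drp <- copy(drp); sr <- copy(sr)
  for (sid in sites$site_id) {
    cp <- sort(sr[!is.na(site_id) & site_id == sid]$clip_pos)
    if (length(cp) < 4L) next
    grp <- cumsum(c(1L, diff(cp) > gap))
    if (max(grp) < 2L) next
    sizes <- tabulate(grp)
    if (any(sizes < 2L)) next
    centres <- vapply(seq_len(max(grp)), function(g) mean(cp[grp == g]), 0)
    bounds <- (head(centres, -1L) + tail(centres, -1L)) / 2
    ## anchors vote with the position they point at
    di <- which(!is.na(drp$site_id) & drp$site_id == sid)
    dpt <- ifelse(drp$strand[di] == "+", drp$end[di], drp$pos[di])
    drp$site_id[di] <- paste0(sid, letters[findInterval(dpt, bounds) + 1L])
    si <- which(!is.na(sr$site_id) & sr$site_id == sid)
    sr$site_id[si] <- paste0(sid, letters[findInterval(sr$clip_pos[si], bounds) + 1L])
  }
  ## re-admit against the threshold
  drp[, .n := .N, by = site_id]
  tiny <- !is.na(drp$site_id) & drp$.n < min_drp
  drop_ids <- unique(drp$site_id[tiny])
  drp[site_id %in% drop_ids, site_id := NA_character_]
  drp[, .n := NULL]
  sr[site_id %in% drop_ids, site_id := NA_character_]
  list(sites = summarize_sites(drp), drp = drp, sr = sr)
}

empty_sites <- function() data.table(
  site_id = character(0), chrom = character(0), win_start = integer(0),
  win_end = integer(0), n_drp = integer(0), n_left = integer(0),
  n_right = integer(0), left_max_end = integer(0), right_min_start = integer(0),
  class = character(0), n_samples = integer(0))

## majority consensus class among a site's DRP mate alignments
class_vote <- function(cons) {
  cons <- cons[!is.na(cons)]
  if (length(cons) == 0L) return(NA_character_)
  tb <- sort(table(cons), decreasing = TRUE)
  names(tb)[1L]
}

#' Attach split reads to candidate sites
#'
#' A split read is assigned to the admitted site whose anchor window,
#' padded by one fragment length, contains its clip position (nearest window
#' centre on ties).
#'
#' @param sites site table from [cluster_drps()].
#' @param sr pooled split-read table.
#' @param pad window padding (bp), nominally one fragment length.
#' @return `sr` with a `site_id` column.
#' @export
attach_splitreads <- function(sites, sr, pad = 500L) {
  sr <- copy(as.data.table(sr))
  sr[, site_id := NA_character_]
  if (nrow(sr) == 0L || nrow(sites) == 0L) return(sr)
  for (i in seq_len(nrow(sites))) {
    s <- sites[i]
    hit <- which(sr$chrom == s$chrom & sr$clip_pos >= s$win_start - pad &
                   sr$clip_pos <= s$win_end + pad)
    if (!length(hit)) next
    centre <- (s$win_start + s$win_end) / 2
    cur <- sr$site_id[hit]
    takes <- is.na(cur)
    if (any(!takes)) {  # nearer centre wins
      prev <- sites[match(cur[!takes], sites$site_id)]
      prevd <- abs(sr$clip_pos[hit[!takes]] - (prev$win_start + prev$win_end) / 2)
      takes[!takes] <- abs(sr$clip_pos[hit[!takes]] - centre) < prevd
    }
    sr$site_id[hit[takes]] <- s$site_id
  }
  sr
}

## mean of an Rle coverage vector over [from, to) clamped to the chromosome
window_depth <- function(cov, from, to) {
  n <- length(cov)
  from <- max(1L, from + 1L); to <- min(n, to)
  if (from > to) return(0)
  mean(S4Vectors::window(cov, from, to))
}

#' Annotation and depth filters for candidate sites
#'
#' Adds `refME` when the provisional insertion interval overlaps or lies
#' within `refme_pad` bp of a same-class reference mobile element, `mask`
#' when it falls inside a reference gap/mask interval padded by one fragment
#' length, and `depth` when mean depth over the anchor window is above
#' `depth_hi` x or below `depth_lo` x the chromosome median. An empty flag
#' set means the site is retained; flags annotate rather than delete.
#'
#' @param sites site table.
#' @param ref_mes reference-ME intervals (`chrom,start,end,label` = class).
#' @param gaps gap/mask intervals.
#' @param summaries list of per-sample evidence summaries (for coverage).
#' @param params [mei_params()].
#' @return character vector of comma-joined flags, one per site.
#' @export
filter_candidates <- function(sites, ref_mes, gaps, summaries, params = mei_params()) {
  if (is.null(summaries) || length(summaries) == 0L)
    stopf("filter_candidates needs at least one coverage summary")
  flags <- character(nrow(sites))
  if (nrow(sites) == 0L) return(flags)
  ## provisional insertion interval per site
  lo <- pmin(sites$left_max_end, sites$right_min_start, na.rm = TRUE)
  hi <- pmax(sites$left_max_end, sites$right_min_start, na.rm = TRUE)
  lo[is.na(lo)] <- sites$win_start[is.na(lo)]
  hi[is.na(hi)] <- sites$win_end[is.na(hi)]
  for (i in seq_len(nrow(sites))) {
    f <- character(0)
    if (!is.null(ref_mes) && nrow(ref_mes)) {
      near <- ref_mes$chrom == sites$chrom[i] &
        toupper(ref_mes$label) == toupper(sites$class[i]) &
        ref_mes$start - params$refme_pad < hi[i] &
        ref_mes$end + params$refme_pad > lo[i]
      if (any(near)) f <- c(f, "refME")
    }
    if (!is.null(gaps) && nrow(gaps)) {
      near <- gaps$chrom == sites$chrom[i] &
        gaps$start - params$frag_len < hi[i] & gaps$end + params$frag_len > lo[i]
      if (any(near)) f <- c(f, "mask")
    }
    ## pooled depth over the anchor window vs pooled chromosome median
    ch <- sites$chrom[i]
    dep <- 0; med <- 0
    for (sm in summaries) {
      if (!ch %in% names(sm$coverage)) next
      dep <- dep + window_depth(sm$coverage[[ch]], sites$win_start[i], sites$win_end[i])
      med <- med + sm$median_depth[[ch]]
    }
    if (med > 0 && (dep > params$depth_hi * med || dep < params$depth_lo * med))
      f <- c(f, "depth")
    flags[i] <- paste(f, collapse = ",")
  }
  flags
}

## orientation of the inserted element; see vignette. Split-read clips carry
## the poly(A) signal (leading clips at the right junction end A-rich for "+"
## insertions; trailing clips at the left junction start T-rich for "-");
## mate alignments vote with their consensus strand, using the 3'-biased half
## so 5' inversions cannot flip the call.
site_orientation <- function(drps, srs, params) {
  votes <- character(0)
  if (nrow(srs)) {
    for (i in which(srs$side == "L")) {
      tailseq <- substring(srs$clip_seq[i], max(1L, nchar(srs$clip_seq[i]) - 14L),
                           nchar(srs$clip_seq[i]))
      fr <- mean(strsplit(tailseq, "")[[1L]] == "A")
      if (fr >= 0.7) votes <- c(votes, "+")
      if (mean(strsplit(substring(srs$clip_seq[i], 1L, 15L), "")[[1L]] == "T") >= 0.7)
        votes <- c(votes, "-")
    }
    for (i in which(srs$side == "R")) {
      headseq <- substring(srs$clip_seq[i], 1L, 15L)
      if (mean(strsplit(headseq, "")[[1L]] == "T") >= 0.7) votes <- c(votes, "-")
      tailseq <- substring(srs$clip_seq[i], max(1L, nchar(srs$clip_seq[i]) - 14L),
                           nchar(srs$clip_seq[i]))
      if (mean(strsplit(tailseq, "")[[1L]] == "A") >= 0.7) votes <- c(votes, "+")
    }
  }
  tie <- FALSE
  if (length(votes) && sum(votes == "+") != sum(votes == "-")) {
    ori <- if (sum(votes == "+") > sum(votes == "-")) "+" else "-"
    return(list(orientation = ori, tie = FALSE))
  }
  ## fall back to mate consensus strands, 3'-biased half first
  ma <- drps[!is.na(cons)]
  if (nrow(ma)) {
    mid <- (min(ma$c_start) + max(ma$c_end)) / 2
    three <- ma[c_start >= mid]
    st <- if (nrow(three)) three$c_strand else ma$c_strand
    np <- sum(st == "+"); nm <- sum(st == "-")
    if (np != nm) return(list(orientation = if (np > nm) "+" else "-", tie = FALSE))
    tie <- TRUE
  }
  list(orientation = "+", tie = tie)
}

#' Refine a site's breakpoint, TSD and orientation from split reads
#'
#' The modal clip position of left-side split reads (trailing clips, aligned
#' on the left flank) gives `bpL`; the modal position of right-side (leading)
#' clips gives `bpR`. With both present the insertion point is `min(bpL,
#' bpR)`; `bpL > bpR` implies a target-site duplication equal to the
#' reference sequence in `[bpR, bpL)`, `bpL < bpR` a target-site deletion of
#' `bpR - bpL` bases, equality a blunt joint. With no split reads the
#' insertion point is the midpoint between the innermost anchor ends. Modal
#' ties break toward the smaller coordinate.
#'
#' @param site one site row.
#' @param drps,srs this site's DRP and split-read evidence.
#' @param reference named character vector of chromosome sequences.
#' @param params [mei_params()].
#' @return list: `pos`, `tsd`, `tsdel`, `blunt`, `orientation`, `tie`,
#'   `bpL`, `bpR`, per-side SR counts and modal agreement fractions.
#' @export
refine_breakpoint <- function(site, drps, srs, reference, params = mei_params()) {
  if (nrow(drps) == 0L) stopf("refine_breakpoint on a site with no DRPs")
  srL <- srs[side == "R"]  # trailing clips: aligned part on left flank
  srR <- srs[side == "L"]  # leading clips: aligned part on right flank
  bpL <- modal_min(srL$clip_pos)
  bpR <- modal_min(srR$clip_pos)
  agreeL <- if (nrow(srL)) mean(srL$clip_pos == bpL) else NA_real_
  agreeR <- if (nrow(srR)) mean(srR$clip_pos == bpR) else NA_real_
  tsd <- ""; tsdel <- 0L; blunt <- FALSE
  if (!is.na(bpL) && !is.na(bpR)) {
    pos <- min(bpL, bpR)
    if (bpL > bpR) {
      tsd <- substring(reference[[site$chrom]], bpR + 1L, bpL)
    } else if (bpL < bpR) {
      tsdel <- bpR - bpL
    } else blunt <- TRUE
  } else if (!is.na(bpL)) {
    pos <- bpL; blunt <- TRUE
  } else if (!is.na(bpR)) {
    pos <- bpR; blunt <- TRUE
  } else {
    le <- site$left_max_end; rs <- site$right_min_start
    pos <- if (!is.na(le) && !is.na(rs)) as.integer(floor((le + rs) / 2))
           else if (!is.na(le)) le else rs
    blunt <- TRUE
  }
  ori <- site_orientation(drps, srs, params)
  list(pos = as.integer(pos), tsd = tsd, tsdel = tsdel, blunt = blunt,
       orientation = ori$orientation, tie = ori$tie,
       bpL = bpL, bpR = bpR, n_srL = nrow(srL), n_srR = nrow(srR),
       agreeL = agreeL, agreeR = agreeR)
}

#' Breakpoint evidence quality tranche (0-5)
#'
#' 5 = split reads on both sides agreeing on a duplication/deletion joint;
#' 4 = split reads on both sides, blunt or inconsistent; 3 = split reads on
#' one side plus DRPs on both; 2 = DRPs on both sides only; 1 = DRPs on one
#' side only; 0 = otherwise.
#'
#' @param refined output of [refine_breakpoint()].
#' @param n_left,n_right DRP counts on each side.
#' @param params [mei_params()].
#' @return integer tranche.
#' @export
assess_tranche <- function(refined, n_left, n_right, params = mei_params()) {
  srL <- refined$n_srL > 0L; srR <- refined$n_srR > 0L
  both_drp <- n_left > 0L && n_right > 0L
  if (srL && srR) {
    consistent <- (nzchar(refined$tsd) || refined$tsdel > 0L) &&
      !is.na(refined$agreeL) && refined$agreeL >= params$tsd_consistency &&
      !is.na(refined$agreeR) && refined$agreeR >= params$tsd_consistency
    return(if (consistent) 5L else 4L)
  }
  if ((srL || srR) && both_drp) return(3L)
  if (both_drp) return(2L)
  if (n_left > 0L || n_right > 0L) return(1L)
  0L
}

#' Pool evidence bundles from multiple samples
#'
#' Multi-sample (split-mode) semantics: discovery operates on the union of
#' all samples' DRPs and split reads, so sites below the cluster threshold in
#' every single sample can still be discovered jointly.
#'
#' @param evidence list of evidence bundles ([extract_evidence()] outputs or
#'   paths readable by [read_evidence()]).
#' @return pooled bundle: `drp`, `sr` (position-sorted, sample ids kept),
#'   `summaries` (per sample), `samples`.
#' @export
merge_samples <- function(evidence) {
  if (length(evidence) == 0L) stopf("no evidence to merge")
  evidence <- lapply(evidence, function(e)
    if (is.character(e)) read_evidence(e) else e)
  ids <- vapply(evidence, `[[`, "", "sample")
  if (anyDuplicated(ids)) stopf("duplicate sample id: %s", ids[duplicated(ids)][1L])
  drp <- rbindlist(lapply(evidence, `[[`, "drp"))
  sr <- rbindlist(lapply(evidence, `[[`, "sr"))
  if (nrow(drp)) setorder(drp, chrom, pos)
  if (nrow(sr)) setorder(sr, chrom, clip_pos)
  summaries <- lapply(evidence, `[[`, "summary")
  names(summaries) <- ids
  list(drp = drp, sr = sr, summaries = summaries, samples = ids)
}

#' Discover candidate MEI sites from pooled evidence
#'
#' Drives clustering, split-read attachment, annotation filters, breakpoint
#' refinement and tranche assignment, producing the call table that
#' annotation and genotyping then complete.
#'
#' @param pool pooled evidence from [merge_samples()].
#' @param reference named character vector of chromosome sequences.
#' @param ref_mes,gaps optional annotation interval tables.
#' @param params [mei_params()].
#' @return list: `calls` (one row per site), `drp`, `sr` (with `site_id`).
#' @export
discover_sites <- function(pool, reference, ref_mes = NULL, gaps = NULL,
                           params = mei_params()) {
  cl <- cluster_drps(pool$drp, params$cluster_window, params$min_drp)
  sr <- attach_splitreads(cl$sites, pool$sr, params$frag_len)
  sp <- split_merged_sites(cl$sites, cl$drp, sr, params$min_drp)
  sites <- sp$sites
  cl$drp <- sp$drp; sr <- sp$sr
  calls <- empty_calls()
  if (nrow(sites) == 0L)
    return(list(calls = calls, drp = cl$drp, sr = sr))
  flags <- filter_candidates(sites, ref_mes, gaps, pool$summaries, params)
  rows <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    s <- sites[i]
    sdrp <- cl$drp[site_id == s$site_id]
    ssr <- sr[site_id == s$site_id]
    ref <- refine_breakpoint(s, sdrp, ssr, reference, params)
    tranche <- assess_tranche(ref, s$n_left, s$n_right, params)
    f <- flags[i]
    if (ref$tie || tranche <= 1L)
      f <- paste(c(if (nzchar(f)) strsplit(f, ",")[[1L]], "lc"), collapse = ",")
    rows[[i]] <- data.table(
      site_id = s$site_id, chrom = s$chrom, pos = ref$pos, class = s$class,
      orientation = ref$orientation, cons_start = NA_integer_,
      cons_stop = NA_integer_, svlen = NA_integer_, tsd = ref$tsd,
      tsdel = ref$tsdel, tranche = tranche, filters = f,
      subfamily = "", mutations = "", inv5 = NA, inv_junction = NA_integer_,
      tdn_locus = "", tdn_source = "", gene_impact = "",
      n_drp = s$n_drp, n_left = s$n_left, n_right = s$n_right,
      n_srL = ref$n_srL, n_srR = ref$n_srR, blunt = ref$blunt)
  }
  calls <- rbindlist(rows)
  setorder(calls, chrom, pos)
  old_ids <- calls$site_id
  calls[, site_id := sprintf("mei_%04d", .I)]  # stable, position-ordered ids
  map <- setNames(calls$site_id, old_ids)      # propagate to evidence tables
  drp <- cl$drp; srx <- sr
  drp[!is.na(site_id), site_id := unname(map[site_id])]
  srx[!is.na(site_id), site_id := unname(map[site_id])]
  list(calls = calls, drp = drp, sr = srx)
}

empty_calls <- function() data.table(
  site_id = character(0), chrom = character(0), pos = integer(0),
  class = character(0), orientation = character(0), cons_start = integer(0),
  cons_stop = integer(0), svlen = integer(0), tsd = character(0),
  tsdel = integer(0), tranche = integer(0), filters = character(0),
  subfamily = character(0), mutations = character(0), inv5 = logical(0),
  inv_junction = integer(0), tdn_locus = character(0), tdn_source = character(0),
  gene_impact = character(0), n_drp = integer(0), n_left = integer(0),
  n_right = integer(0), n_srL = integer(0), n_srR = integer(0), blunt = logical(0))
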