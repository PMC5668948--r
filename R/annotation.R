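## Consensus-space annotation of called sites: pileup, interior mutations,
## subfamily assignment, novel-subfamily discovery, 5' inversions,
## 3' transductions, gene impact.

#' Build a consensus-space pileup from a site's evidence
#'
#' Every accepted consensus alignment of a mate or clip contributes its
#' aligned bases (laid out in consensus coordinates by the aligner).
#'
#' @param drps,srs the site's evidence rows (class-consistent alignments are
#'   selected by `cons`).
#' @param entry the consensus library entry for the site's class.
#' @return list: `cons`, `depth` (length-L integer), `counts` (4 x L base
#'   counts), `strands` (2 x L), `span` (0-based half-open covered extent),
#'   `truncated5` (span starts after position 50), `polya` (estimated
#'   poly(A) length), `svlen` (span length + poly(A) estimate).
#' @export
build_pileup <- function(drps, srs, entry) {
  L <- entry$length
  ev <- rbind(
    drps[!is.na(cons) & cons == entry$name,
         .(c_start, c_end, c_strand, qstart, qend, aln, seq)],
    srs[!is.na(cons) & cons == entry$name,
        .(c_start, c_end, c_strand, qstart, qend, aln, seq = clip_seq)])
  depth <- integer(L)
  counts <- matrix(0L, 4L, L, dimnames = list(DNA_BASES, NULL))
  strands <- matrix(0L, 2L, L, dimnames = list(c("+", "-"), NULL))
  if (nrow(ev) == 0L)
    return(list(cons = entry$name, depth = depth, counts = counts,
                strands = strands, span = c(NA_integer_, NA_integer_),
                truncated5 = NA, polya = 0L, svlen = NA_integer_))
  for (i in seq_len(nrow(ev))) {
    p0 <- ev$c_start[i]
    bases <- strsplit(ev$aln[i], "")[[1L]]
    pos <- p0 + seq_along(bases)  # 1-based index into consensus vectors
    keep <- pos <= L
    pos <- pos[keep]; bases <- bases[keep]
    depth[pos] <- depth[pos] + 1L
    strands[ev$c_strand[i], pos] <- strands[ev$c_strand[i], pos] + 1L
    real <- bases %in% DNA_BASES
    if (any(real)) {
      idx <- cbind(match(bases[real], DNA_BASES), pos[real])
      counts[idx] <- counts[idx] + 1L
    }
  }
  span <- c(min(ev$c_start), max(ev$c_end))
  ## poly(A) length: longest A-run immediately after the aligned query end,
  ## among reads whose alignment reaches the consensus 3' end
  polya <- 0L
  reach <- which(ev$c_end >= L - 5L & ev$qend < nchar(ev$seq))
  if (length(reach)) {
    tails <- substring(ev$seq[reach], ev$qend[reach] + 1L, nchar(ev$seq[reach]))
    runs <- vapply(tails, function(t) {
      m <- regexpr("^A+", t)
      if (m > 0L) attr(m, "match.length") else 0L
    }, 0L)
    polya <- as.integer(max(runs, 0L))
  }
  list(cons = entry$name, depth = depth, counts = counts, strands = strands,
       span = span, truncated5 = span[1L] > 50L, polya = polya,
       svlen = as.integer(span[2L] - span[1L] + polya))
}

#' Call interior mutations from a consensus pileup
#'
#' A position is reported when depth >= `mut_depth` (default 3) and the
#' fraction of non-consensus bases is >= `mut_frac` (default 0.7); the
#' majority non-consensus base is the alt. Mutations at CpG dinucleotide
#' positions are flagged.
#'
#' @param pileup from [build_pileup()].
#' @param entry consensus library entry.
#' @param params [mei_params()].
#' @return data.table `pos` (0-based), `ref`, `alt`, `cpg`.
#' @export
call_interior_mutations <- function(pileup, entry, params = mei_params()) {
  L <- entry$length
  consensus <- strsplit(entry$seq, "")[[1L]]
  basecov <- colSums(pileup$counts)
  cons_idx <- cbind(match(consensus, DNA_BASES), seq_len(L))
  cons_count <- pileup$counts[cons_idx]
  noncons <- basecov - cons_count
  hit <- which(pileup$depth >= params$mut_depth & basecov > 0L &
                 noncons / basecov >= params$mut_frac)
  if (length(hit) == 0L)
    return(data.table(pos = integer(0), ref = character(0),
                      alt = character(0), cpg = logical(0)))
  alt <- vapply(hit, function(p) {
    cnt <- pileup$counts[, p]
    cnt[consensus[p]] <- 0L
    DNA_BASES[which.max(cnt)]
  }, "")
  data.table(pos = hit - 1L, ref = consensus[hit], alt = alt,
             cpg = (hit - 1L) %in% entry$cpg)
}

## "c123t" style token; trailing * marks CpG-associated
mutation_string <- function(profile) {
  if (nrow(profile) == 0L) return("")
  paste0(tolower(profile$ref), profile$pos, tolower(profile$alt),
         ifelse(profile$cpg, "*", ""), collapse = ",")
}

parse_mutation_string <- function(s) {
  if (!nzchar(s)) return(data.table(pos = integer(0), ref = character(0),
                                    alt = character(0), cpg = logical(0)))
  tok <- strsplit(s, ",", fixed = TRUE)[[1L]]
  cpg <- endsWith(tok, "*")
  tok <- sub("\\*$", "", tok)
  data.table(pos = as.integer(gsub("[a-z]", "", tok)),
             ref = toupper(substring(tok, 1L, 1L)),
             alt = toupper(substring(tok, nchar(tok), nchar(tok))), cpg = cpg)
}

#' Assign a subfamily from an interior mutation profile
#'
#' Each subfamily is scored as (diagnostics present) - `diag_penalty` x
#' (diagnostics absent but assessable); diagnostics at positions with no
#' usable depth are excluded from both terms. Ties break toward the
#' subfamily with fewest diagnostics, then lexicographically; an empty
#' profile therefore returns the root (zero-diagnostic) subfamily.
#'
#' @param profile mutation table (`pos`, `alt` used).
#' @param entry consensus library entry with subfamily profiles.
#' @param assessable optional integer vector of assessable (0-based)
#'   positions; `NULL` means all positions are assessable.
#' @param params [mei_params()].
#' @return list(`subfamily`, `score`).
#' @export
assign_subfamily <- function(profile, entry, assessable = NULL,
                             params = mei_params()) {
  if (length(entry$profiles) == 0L)
    return(list(subfamily = entry$name, score = 0))
  have <- paste0(profile$pos, ">", profile$alt)
  res <- lapply(names(entry$profiles), function(nm) {
    pr <- entry$profiles[[nm]]
    if (nrow(pr) == 0L) return(list(nm = nm, score = 0, ndiag = 0L))
    ok <- if (is.null(assessable)) rep(TRUE, nrow(pr)) else pr$pos %in% assessable
    key <- paste0(pr$pos, ">", pr$alt)
    present <- sum(key[ok] %in% have)
    absent <- sum(ok) - present
    list(nm = nm, score = present - params$diag_penalty * absent, ndiag = nrow(pr))
  })
  score <- vapply(res, `[[`, 0, "score")
  ndiag <- vapply(res, function(x) x$ndiag, 0L)
  nm <- vapply(res, `[[`, "", "nm")
  o <- order(-score, ndiag, nm)
  list(subfamily = nm[o[1L]], score = score[o[1L]])
}

#' Discover novel subfamilies from annotated calls
#'
#' Groups calls of one class by their non-CpG interior mutation set after
#' removing mutations that are diagnostics of any known subfamily; groups
#' with at least `min_copies` members at distinct loci and a non-empty key
#' are reported as candidate novel subfamilies.
#'
#' @param calls annotated call table (`class`, `mutations`, `chrom`, `pos`).
#' @param library an [me_library()].
#' @param min_copies minimum independent copies (default 5).
#' @return data.table `class`, `mutations` (group key), `n`, `sites`.
#' @export
discover_novel_subfamilies <- function(calls, library, min_copies = 5L) {
  calls <- as.data.table(calls)
  out <- list()
  for (cls in unique(calls$class)) {
    entry <- library[[cls]]
    if (is.null(entry)) next
    known <- known_diagnostics(entry)
    d <- calls[class == cls]
    keys <- vapply(d$mutations, function(s) {
      m <- parse_mutation_string(s)
      m <- m[cpg == FALSE]
      m <- m[!paste0(pos, ">", alt) %in% known]
      if (nrow(m) == 0L) return("")
      m <- m[order(pos)]
      paste0(tolower(m$ref), m$pos, tolower(m$alt), collapse = ",")
    }, "", USE.NAMES = FALSE)
    d[, key := keys]
    grp <- d[nzchar(key), .(n = uniqueN(paste(chrom, pos)),
                            sites = paste(site_id, collapse = ",")), by = key]
    grp <- grp[n >= min_copies]
    if (nrow(grp))
      out[[cls]] <- data.table(class = cls, mutations = grp$key,
                               n = grp$n, sites = grp$sites)
  }
  if (length(out) == 0L)
    return(data.table(class = character(0), mutations = character(0),
                      n = integer(0), sites = character(0)))
  rbindlist(out)
}

#' Detect a twin-priming 5' inversion from consensus-space evidence
#'
#' Relative strand of each alignment is its consensus strand compared with
#' the insertion orientation; the inverted 5' segment of a twin-primed
#' element aligns on the opposite relative strand from the 3' segment. The
#' junction is the midpoint between the rightmost end of the
#' opposite-strand (5') group and the leftmost start of the same-strand
#' (3') group. The call is assessable when each group has at least
#' `inv_min_side` alignments, or when a single-strand element demonstrably
#' covers the consensus 5' end (no room for an unseen inverted segment).
#'
#' @param drps,srs site evidence rows.
#' @param entry consensus library entry.
#' @param orientation insertion orientation ("+"/"-").
#' @param params [mei_params()].
#' @return list(`inverted`, `junction` (0-based consensus, or NA),
#'   `assessable`).
#' @export
detect_inversion <- function(drps, srs, entry, orientation = "+",
                             params = mei_params()) {
  ev <- rbind(drps[!is.na(cons) & cons == entry$name,
                   .(c_start, c_end, c_strand)],
              srs[!is.na(cons) & cons == entry$name,
                  .(c_start, c_end, c_strand)])
  no <- list(inverted = FALSE, junction = NA_integer_, assessable = FALSE)
  if (nrow(ev) == 0L) return(no)
  rel <- ifelse(ev$c_strand == orientation, "+", "-")
  minus <- ev[rel == "-"]; plus <- ev[rel == "+"]
  if (nrow(minus) >= params$inv_min_side && nrow(plus) >= params$inv_min_side) {
    ## inverted segment must lie 5' of the non-inverted segment
    if (median(minus$c_start) < median(plus$c_start)) {
      ## the reverse-complemented 5' segment sits at a breakpoint-adjacent
      ## end of the insert, so its rightmost alignment end abuts the
      ## junction exactly; the same-strand 3' group only reaches the
      ## junction when coverage is contiguous, in which case the midpoint
      ## of the two bounds is used
      jm <- max(minus$c_end)
      jp <- min(plus$c_start)
      junction <- if (jp >= jm && jp - jm <= 200L)
        as.integer(floor((jm + jp) / 2)) else as.integer(jm)
      return(list(inverted = TRUE, junction = junction, assessable = TRUE))
    }
    return(list(inverted = FALSE, junction = NA_integer_, assessable = TRUE))
  }
  ## single-strand evidence: assessable only if the covered span reaches the
  ## consensus 5' end (a truncated element leaves the missing 5' part unseen)
  span_start <- min(ev$c_start)
  list(inverted = FALSE, junction = NA_integer_,
       assessable = span_start <= 50L && nrow(ev) >= params$inv_min_side)
}

## longest run-trimmed transduction tail from one sequence lying 3' of the
## consensus end: trim a first poly(A) run, then a trailing poly(A) run
split_tail <- function(tail, params) {
  m <- regexpr("^A+", tail)
  if (m > 0 && attr(m, "match.length") >= params$polya_min)
    tail <- substring(tail, attr(m, "match.length") + 1L)
  second <- FALSE
  m2 <- regexpr("A+$", tail)
  if (m2 > 0 && attr(m2, "match.length") >= params$polya_min) {
    second <- TRUE
    tail <- substring(tail, 1L, m2 - 1L)
  }
  list(tag = tail, second_polya = second)
}

#' Detect a 3' transduction and map it to a source element
#'
#' Candidate tails are the query parts lying 3' of the consensus end of the
#' element after trimming a first poly(A) run; tails that are at least
#' `tail_min_len` bp and under `tail_max_a` fraction A are aligned to the
#' reference. A unique near-exact hit gives the mapped locus; the source is
#' the annotated full-length element whose 3' end lies within
#' `tdn_source_pad` bp 5' of the locus on the matching strand, else
#' "unplaced". An ambiguous (multi-hit) tag yields no call.
#'
#' @param drps,srs site evidence rows.
#' @param entry consensus library entry.
#' @param reference named character vector of chromosome sequences.
#' @param fl_sources annotated full-length source intervals
#'   (`chrom,start,end,label,strand`), or NULL.
#' @param orientation insertion orientation.
#' @param params [mei_params()].
#' @return list(`seq`, `locus` (chrom,start,end,strand), `source`,
#'   `second_polya`) or NULL.
#' @export
detect_transduction <- function(drps, srs, entry, reference, fl_sources = NULL,
                                orientation = "+", params = mei_params()) {
  L <- entry$length
  tails <- character(0)
  ev <- rbind(drps[!is.na(cons) & cons == entry$name, .(c_end, qend, seq)],
              srs[!is.na(cons) & cons == entry$name,
                  .(c_end, qend, seq = clip_seq)])
  if (nrow(ev)) {
    reach <- ev[c_end >= L - 5L & qend < nchar(seq)]
    if (nrow(reach)) tails <- substring(reach$seq, reach$qend + 1L, nchar(reach$seq))
  }
  ## clips with no consensus alignment at the poly(A)-side junction carry the
  ## 3'-most insert sequence: leading clips for "+", trailing (reverse
  ## complemented to donor-forward) for "-"
  un <- srs[is.na(cons)]
  if (nrow(un)) {
    if (orientation == "+") tails <- c(tails, un[side == "L"]$clip_seq)
    else {
      r <- un[side == "R"]$clip_seq
      if (length(r)) tails <- c(tails, revcomp(r))
    }
  }
  if (length(tails) == 0L) return(NULL)
  parts <- lapply(tails, split_tail, params = params)
  tags <- vapply(parts, `[[`, "", "tag")
  keep <- nchar(tags) >= params$tail_min_len &
    vapply(tags, function(t) mean(strsplit(t, "")[[1L]] == "A"), 0) < params$tail_max_a
  if (!any(keep)) return(NULL)
  best_i <- which(keep)[which.max(nchar(tags[keep]))]
  tag <- tags[best_i]
  ## map the tag to the reference, both strands, allowing a few mismatches
  hits <- map_unique(tag, reference, max.mismatch = 2L)
  if (is.null(hits)) return(NULL)
  source <- "unplaced"
  if (!is.null(fl_sources) && nrow(fl_sources)) {
    fs <- as.data.table(fl_sources)
    if (!"strand" %in% names(fs)) fs[, strand := "+"]
    cand <- fs[chrom == hits$chrom & strand == hits$strand]
    if (nrow(cand)) {
      d <- ifelse(cand$strand == "+", hits$start - cand$end, cand$start - hits$end)
      ok <- which(d >= -10L & d <= params$tdn_source_pad)
      if (length(ok)) source <- cand$label[ok[which.min(d[ok])]]
    }
  }
  list(seq = tag, locus = hits, source = source,
       second_polya = parts[[best_i]]$second_polya)
}

## unique near-exact placement of a tag on the reference; NULL if 0 or >1 hits
map_unique <- function(tag, reference, max.mismatch = 2L) {
  hits <- list()
  pat <- Biostrings::DNAString(tag)
  rpat <- Biostrings::reverseComplement(pat)
  for (ch in names(reference)) {
    subj <- Biostrings::DNAString(reference[[ch]])
    for (st in c("+", "-")) {
      m <- Biostrings::matchPattern(if (st == "+") pat else rpat, subj,
                                    max.mismatch = max.mismatch)
      if (length(m))
        hits[[length(hits) + 1L]] <- data.table(
          chrom = ch, start = Biostrings::start(m) - 1L,
          end = Biostrings::end(m), strand = st)
    }
  }
  if (length(hits) == 0L) return(NULL)
  hits <- rbindlist(hits)
  if (nrow(hits) != 1L) return(NULL)   # ambiguous: no call
  as.list(hits[1L])
}

#' Annotate the gene impact of an insertion point
#'
#' Severity order: exon > UTR > promoter/terminator > intron > intergenic.
#' Promoter is 1 kb upstream of the transcription start, terminator 1 kb
#' downstream of the transcription end (strand-aware); introns are the
#' transcript extent not covered by a feature.
#'
#' @param chrom,pos insertion point (0-based).
#' @param genes gene-feature table from [read_gene_model()] (may be empty or
#'   NULL).
#' @param params [mei_params()].
#' @return one of "exon", "5UTR", "3UTR", "promoter", "terminator",
#'   "intron", "intergenic".
#' @export
annotate_gene_impact <- function(chrom, pos, genes, params = mei_params()) {
  if (is.null(genes) || nrow(genes) == 0L) return("intergenic")
  g <- as.data.table(genes)
  g <- g[g[["chrom"]] == chrom]
  if (nrow(g) == 0L) return("intergenic")
  hit <- g[start <= pos & pos < end]
  if (any(hit$feature == "exon")) return("exon")
  if (any(hit$feature == "5UTR")) return("5UTR")
  if (any(hit$feature == "3UTR")) return("3UTR")
  ## transcript extents per gene
  ext <- g[, .(start = min(start), end = max(end), strand = strand[1L]), by = gene]
  prom <- ext[ifelse(strand == "+", start - params$promoter <= pos & pos < start,
                     end <= pos & pos < end + params$promoter)]
  if (nrow(prom)) return("promoter")
  term <- ext[ifelse(strand == "+", end <= pos & pos < end + params$terminator,
                     start - params$terminator <= pos & pos < start)]
  if (nrow(term)) return("terminator")
  if (nrow(ext[start <= pos & pos < end])) return("intron")
  "intergenic"
}

#' Annotate discovered sites with element-internal and genic features
#'
#' Fills consensus span, SVLEN, subfamily, interior mutations, 5' inversion,
#' 3' transduction and gene impact on the call table from
#' [discover_sites()].
#'
#' @param disc output of [discover_sites()].
#' @param library an [me_library()].
#' @param reference named character vector of chromosome sequences.
#' @param fl_sources optional full-length source-element annotation.
#' @param genes optional gene model.
#' @param params [mei_params()].
#' @return the call table with annotation columns filled.
#' @export
annotate_calls <- function(disc, library, reference, fl_sources = NULL,
                           genes = NULL, params = mei_params()) {
  calls <- copy(disc$calls)
  if (nrow(calls) == 0L) return(calls)
  for (i in seq_len(nrow(calls))) {
    cls <- calls$class[i]
    entry <- library[[cls]]
    if (is.null(entry)) next
    sdrp <- disc$drp[site_id == calls$site_id[i]]
    ssr <- disc$sr[!is.na(site_id) & site_id == calls$site_id[i]]
    pu <- build_pileup(sdrp, ssr, entry)
    prof <- call_interior_mutations(pu, entry, params)
    assessable <- which(pu$depth >= params$mut_depth) - 1L
    sf <- assign_subfamily(prof, entry, assessable, params)
    inv <- detect_inversion(sdrp, ssr, entry, calls$orientation[i], params)
    tdn <- detect_transduction(sdrp, ssr, entry, reference, fl_sources,
                               calls$orientation[i], params)
    set(calls, i, c("cons_start", "cons_stop", "svlen", "subfamily",
                    "mutations", "inv5", "inv_junction", "gene_impact"),
        list(pu$span[1L], pu$span[2L], pu$svlen, sf$subfamily,
             mutation_string(prof),
             if (inv$assessable) inv$inverted else NA,
             inv$junction,
             annotate_gene_impact(calls$chrom[i], calls$pos[i], genes, params)))
    if (!is.null(tdn)) {
      set(calls, i, c("tdn_locus", "tdn_source"),
          list(sprintf("%s:%d-%d:%s", tdn$locus$chrom, tdn$locus$start,
                       tdn$locus$end, tdn$locus$strand), tdn$source))
    }
  }
  calls
}
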