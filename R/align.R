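## Local realignment of candidate mate / clip sequences against the
## mobile-element consensus library. Smith-Waterman scoring (match +2,
## mismatch -2, gap open -3, gap extend -1) via Biostrings; acceptance
## requires aligned length >= 30 on the consensus and identity >= 0.88,
## which error-free 30-bp fragments always meet and shuffled sequence
## essentially never does.

sub_matrix <- function(match, mismatch) {
  b <- c(DNA_BASES, "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- match
  m["N", ] <- 0; m[, "N"] <- 0
  m
}

#' Align sequences to a mobile-element consensus library
#'
#' Best local alignment over both strands of every library entry. Ties are
#' broken deterministically: higher score, then lower library index, then
#' `+` strand, then smaller consensus start.
#'
#' @param seqs character vector of query sequences.
#' @param library an [me_library()].
#' @param params [mei_params()].
#' @return data.table with one row per query: `cons` (consensus name or NA
#'   when no acceptable alignment), `c_start`, `c_end` (0-based half-open on
#'   the consensus), `c_strand`, `identity`, `score`, `qstart`, `qend`
#'   (0-based half-open on the query, query orientation), and `aln` (query
#'   bases laid out in consensus coordinates, `-` for deletions).
## per-entry k-mer index (both strands) used to prescreen queries before the
## O(nm) alignment; an error-free >= 30 bp element fragment always shares a
## k-mer with its consensus, random/shuffled sequence essentially never does
kmer_index <- function(library, k = 16L) {
  idx <- attr(library, ".kmer_index")
  if (!is.null(idx) && idx$k == k) return(idx)
  sets <- lapply(library, function(e) {
    n <- e$length - k + 1L
    if (n < 1L) return(character(0))
    fwd <- substring(e$seq, seq_len(n), seq_len(n) + k - 1L)
    rseq <- revcomp(e$seq)
    rev <- substring(rseq, seq_len(n), seq_len(n) + k - 1L)
    unique(c(fwd, rev))
  })
  list(k = k, sets = sets)
}

query_kmers <- function(seqs, k = 16L) {
  lapply(seqs, function(s) {
    n <- nchar(s) - k + 1L
    if (is.na(n) || n < 1L) return(character(0))
    unique(substring(s, seq_len(n), seq_len(n) + k - 1L))
  })
}

#' @export
align_to_consensus <- function(seqs, library, params = mei_params()) {
  if (length(library) == 0L) stopf("empty consensus library")
  n <- length(seqs)
  best <- data.table(cons = rep(NA_character_, n), c_start = NA_integer_,
                     c_end = NA_integer_, c_strand = NA_character_,
                     identity = NA_real_, score = NA_integer_,
                     qstart = NA_integer_, qend = NA_integer_,
                     aln = NA_character_, .rank = Inf)
  if (n == 0L) return(best[, !".rank"])
  ok <- !is.na(seqs) & nchar(seqs) >= params$min_seq & !grepl("[^ACGTN]", seqs)
  if (!any(ok)) return(best[, !".rank"])
  kidx <- kmer_index(library)
  qk <- query_kmers(seqs, kidx$k)
  idx_all <- which(ok)
  qlen_all <- nchar(seqs)
  pats_fwd_all <- Biostrings::DNAStringSet(ifelse(is.na(seqs), "", seqs))
  pats_rev_all <- Biostrings::reverseComplement(pats_fwd_all)
  sm <- sub_matrix(params$match, params$mismatch)
  for (li in seq_along(library)) {
    entry <- library[[li]]
    hit <- vapply(qk, function(ks) length(ks) > 0L && any(ks %in% kidx$sets[[li]]),
                  NA)
    idx <- idx_all[hit[idx_all]]
    if (length(idx) == 0L) next
    qlen <- qlen_all[idx]
    subj <- Biostrings::DNAString(entry$seq)
    for (strand in c("+", "-")) {
      pats <- if (strand == "+") pats_fwd_all[idx] else pats_rev_all[idx]
      al <- Biostrings::pairwiseAlignment(
        pats, subj, type = "local", substitutionMatrix = sm,
        gapOpening = params$gap_open, gapExtension = params$gap_extend)
      s_start <- Biostrings::start(Biostrings::subject(al))
      s_end <- Biostrings::end(Biostrings::subject(al))
      p_start <- Biostrings::start(Biostrings::pattern(al))
      p_end <- Biostrings::end(Biostrings::pattern(al))
      span <- s_end - s_start + 1L
      ident <- Biostrings::nmatch(al) / pmax(span, p_end - p_start + 1L)
      score <- as.integer(round(Biostrings::score(al)))
      acc <- span >= params$min_aln_len & ident >= params$min_identity
      if (!any(acc)) next
      # tie-break rank: lower is better
      rank <- -score * 1e12 + li * 1e9 + (strand == "-") * 1e8 + s_start
      upd <- which(acc & rank < best$.rank[idx])
      if (!length(upd)) next
      ## aligned() lays the pattern out over the whole subject; keep the span
      aln_str <- substring(as.character(Biostrings::aligned(al[upd])),
                           s_start[upd], s_end[upd])
      q0 <- p_start[upd] - 1L; q1 <- p_end[upd]
      if (strand == "-") { tmp <- qlen[upd] - q1; q1 <- qlen[upd] - q0; q0 <- tmp }
      set(best, idx[upd], c("cons", "c_start", "c_end", "c_strand", "identity",
                            "score", "qstart", "qend", "aln", ".rank"),
          list(entry$name, s_start[upd] - 1L, s_end[upd], strand,
               ident[upd], score[upd], q0, q1, aln_str, rank[upd]))
    }
  }
  best[, !".rank"]
}
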