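## Mobile-element consensus library: one consensus sequence per element
## class plus subfamily diagnostic-mutation profiles and CpG positions.

#' Construct a mobile-element consensus library
#'
#' A library is a named list of consensus entries. Each entry holds the class
#' consensus sequence, a set of subfamily profiles (each profile a table of
#' diagnostic mutations relative to the class consensus) and the positions of
#' CpG dinucleotides on the consensus. All coordinates are 0-based.
#'
#' @param entries named list; each element a list with fields `seq` (character
#'   scalar) and `profiles` (named list of data.tables with columns
#'   `pos`, `ref`, `alt`). The root subfamily is the profile with zero rows.
#' @return an object of class `me_library`.
#' @export
me_library <- function(entries) {
  stopifnot(is.list(entries), length(entries) > 0L, !is.null(names(entries)))
  out <- lapply(names(entries), function(nm) {
    e <- entries[[nm]]
    if (!nzchar(e$seq)) stopf("consensus '%s' has empty sequence", nm)
    profiles <- e$profiles %||% list()
    for (p in names(profiles)) {
      pr <- as.data.table(profiles[[p]])
      if (nrow(pr)) {
        if (any(pr$pos < 0L | pr$pos >= nchar(e$seq)))
          stopf("profile '%s' of '%s' has diagnostic outside consensus", p, nm)
        cons_base <- substring(e$seq, pr$pos + 1L, pr$pos + 1L)
        if (any(cons_base != pr$ref))
          stopf("profile '%s' of '%s': ref base mismatch with consensus", p, nm)
      }
      profiles[[p]] <- pr
    }
    list(name = nm, seq = e$seq, length = nchar(e$seq),
         profiles = profiles, cpg = cpg_positions(e$seq))
  })
  names(out) <- names(entries)
  structure(out, class = "me_library")
}

#' @export
print.me_library <- function(x, ...) {
  for (e in x)
    cat(sprintf("%s: %d bp, %d subfamily profiles, %d CpG positions\n",
                e$name, e$length, length(e$profiles), length(e$cpg)))
  invisible(x)
}

## deterministic synthetic consensus: random DNA of realistic class length
synth_consensus <- function(len, seed) random_dna(len, seed)

## pick diagnostic mutations at distinct non-CpG positions
synth_profile <- function(seq, n, seed) {
  with_seed(seed, {
    cpg <- cpg_positions(seq)
    ok <- setdiff(seq_len(nchar(seq)) - 1L, cpg)
    pos <- sort(sample(ok, n))
    ref <- substring(seq, pos + 1L, pos + 1L)
    alt <- vapply(ref, function(b) sample(setdiff(DNA_BASES, b), 1L), "")
    data.table(pos = pos, ref = ref, alt = unname(alt))
  })
}

#' Bundled synthetic consensus library
#'
#' Deterministically generated stand-in for a real Alu/LINE1/SVA consensus
#' library (synthetic sequences at realistic class lengths: Alu 281 bp,
#' LINE-1 6019 bp, SVA 1316 bp). Alu and LINE-1 carry toy subfamily profiles
#' (a zero-diagnostic root plus derived subfamilies with 3-8 diagnostic
#' mutations); SVA is annotated at class level only, mirroring tools that
#' build subfamily classifiers for Alu and L1 first.
#'
#' @return an `me_library` with entries `ALU`, `LINE1`, `SVA`.
#' @export
default_me_library <- function() {
  alu <- synth_consensus(281L, 900101L)
  l1  <- synth_consensus(6019L, 900102L)
  sva <- synth_consensus(1316L, 900103L)
  me_library(list(
    ALU = list(seq = alu, profiles = list(
      AluY   = data.table(pos = integer(0), ref = character(0), alt = character(0)),
      AluYa5s = synth_profile(alu, 5L, 910101L),
      AluYb8s = synth_profile(alu, 8L, 910102L))),
    LINE1 = list(seq = l1, profiles = list(
      L1     = data.table(pos = integer(0), ref = character(0), alt = character(0)),
      L1Ta1s = synth_profile(l1, 3L, 910103L),
      L1preTAs = synth_profile(l1, 4L, 910104L))),
    SVA = list(seq = sva, profiles = list(
      SVA = data.table(pos = integer(0), ref = character(0), alt = character(0))))
  ))
}

#' Read a consensus library from FASTA plus a profile table
#'
#' @param fasta path to a FASTA of class consensus sequences (names = classes).
#' @param profiles optional path to a TSV with columns
#'   `class`, `subfamily`, `pos`, `ref`, `alt` (0-based positions; a subfamily
#'   may appear with `pos` = -1 to declare a zero-diagnostic root).
#' @return an `me_library`.
#' @export
read_me_library <- function(fasta, profiles = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  entries <- lapply(seq_along(seqs), function(i)
    list(seq = as.character(seqs[[i]]), profiles = list()))
  names(entries) <- sub("\\s.*$", "", names(seqs))
  if (!is.null(profiles)) {
    pr <- fread(profiles, colClasses = list(character = c("class", "subfamily", "ref", "alt")))
    for (cl in unique(pr$class)) {
      if (!cl %in% names(entries)) stopf("profile class '%s' absent from FASTA", cl)
      sub <- pr[pr$class == cl]
      entries[[cl]]$profiles <- lapply(split(sub, by = "subfamily", sorted = TRUE),
        function(d) d[d$pos >= 0L, .(pos, ref, alt)])
    }
  }
  me_library(entries)
}

#' Write a consensus library to FASTA (+ profile TSV)
#'
#' @param lib an `me_library`.
#' @param fasta output FASTA path.
#' @param profiles optional output TSV path for subfamily profiles.
#' @export
write_me_library <- function(lib, fasta, profiles = NULL) {
  ss <- Biostrings::DNAStringSet(vapply(lib, `[[`, "", "seq"))
  names(ss) <- vapply(lib, `[[`, "", "name")
  Biostrings::writeXStringSet(ss, fasta)
  if (!is.null(profiles)) {
    rows <- rbindlist(lapply(lib, function(e)
      rbindlist(lapply(names(e$profiles), function(p) {
        pr <- e$profiles[[p]]
        if (nrow(pr) == 0L)
          data.table(class = e$name, subfamily = p, pos = -1L, ref = ".", alt = ".")
        else data.table(class = e$name, subfamily = p, pr)
      }))))
    fwrite(rows, profiles, sep = "\t")
  }
  invisible(fasta)
}

## all diagnostic (pos, alt) pairs known to any subfamily of a consensus entry
known_diagnostics <- function(entry) {
  d <- rbindlist(entry$profiles, use.names = TRUE)
  if (nrow(d) == 0L) return(character(0))
  unique(paste0(d$pos, ">", d$alt))
}
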