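#' Pipeline parameters
#'
#' All tunable thresholds with their defaults. Values the underlying method
#' states are fixed here as defaults (`min_separation` = 1 Mbp inclusive for
#' the discordant-pair definition, `min_drp` = 4 for cluster admission,
#' `eval_window` = 500 bp for truth matching); the remainder are this
#' package's documented choices.
#'
#' @param ... name = value overrides of any default.
#' @return named list of parameters.
#' @export
mei_params <- function(...) {
  p <- list(
    min_separation = 1000000L, # DRP: mates >= 1 Mbp apart or on different chroms
    min_anchor_mapq = 20L,     # anchor admission
    min_clip = 20L,            # minimum soft-clip length for a split read
    min_seq = 20L,             # minimum sequence length sent to the aligner
    min_aln_len = 30L,         # consensus alignment acceptance: aligned length
    min_identity = 0.88,       #   ... and identity
    match = 2L, mismatch = -2L, gap_open = 3L, gap_extend = 1L,
    cluster_window = 500L,     # single-linkage gap (~ fragment length)
    min_drp = 4L,              # cluster admission threshold (summed over samples)
    refme_pad = 50L,           # same-class reference-ME proximity filter
    depth_lo = 0.25, depth_hi = 2.5,  # local depth vs chromosome median
    frag_len = 500L,           # nominal fragment length (gap padding, SR attach)
    mut_depth = 3L,            # interior mutation: minimum consensus depth
    mut_frac = 0.7,            #   ... and non-consensus base fraction
    diag_penalty = 0.5,        # subfamily score: absent-but-assessable weight
    novel_min = 5L,            # novel subfamily: minimum independent copies
    inv_min_side = 3L,         # inversion: alignments required on each side
    polya_min = 8L,            # poly(A): minimum run of A
    tail_max_a = 0.8,          # transduction tail must be < 80% A
    tail_min_len = 30L,        # minimum transduction tag length
    tdn_source_pad = 500L,     # max distance source 3' end -> mapped tag locus
    tdn_uniq_ratio = 0.9,      # next-best hit must score <= ratio * best
    promoter = 1000L, terminator = 1000L,  # gene impact paddings
    err = 0.01,                # genotyping per-read error rate
    min_informative = 2L,      # below this many reads: ./. no-call
    nc_max = 0.25,             # site filter: max no-call fraction
    sr_bp_slack = 5L,          # SR counts as alt support within this of bp
    ref_span_pad = 20L,        # ref support must cleanly span bp +/- this
    tsd_consistency = 0.5)     # side agreement fraction for tranche 5
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown)) stopf("unknown parameter(s): %s", paste(unknown, collapse = ", "))
  p[names(over)] <- over
  p
}
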