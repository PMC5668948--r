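## End-to-end orchestration: single-sample and pooled (split) modes.

#' Pipeline run configuration
#'
#' @param samples named list of per-sample inputs: [aln_table()] objects or
#'   SAM/BAM paths.
#' @param reference named character vector of chromosome sequences, or a
#'   FASTA path.
#' @param library an [me_library()], or a consensus FASTA path.
#' @param profiles subfamily profile TSV (used when `library` is a path).
#' @param ref_mes,gaps,genes,fl_sources annotation tables or BED paths.
#' @param mode `"single"` (each sample independently) or `"split"` (pooled
#'   discovery, joint genotyping).
#' @param params [mei_params()].
#' @param strict restrict DRPs to mapped-mapped pairs.
#' @return validated config list.
#' @export
mei_config <- function(samples, reference, library = default_me_library(),
                       profiles = NULL, ref_mes = NULL, gaps = NULL,
                       genes = NULL, fl_sources = NULL,
                       mode = c("split", "single"), params = mei_params(),
                       strict = FALSE) {
  mode <- match.arg(mode)
  if (length(samples) == 0L || is.null(names(samples)) || any(!nzchar(names(samples))))
    stopf("samples must be a non-empty named list")
  if (anyDuplicated(names(samples))) stopf("duplicate sample names")
  if (is.character(reference) && length(reference) == 1L && file.exists(reference)) {
    ss <- Biostrings::readDNAStringSet(reference)
    reference <- setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  }
  if (!is.character(reference) || is.null(names(reference)))
    stopf("reference must be a named character vector or FASTA path")
  if (is.character(library)) {
    if (!file.exists(library)) stopf("ME library not found: %s", library)
    library <- read_me_library(library, profiles)
  }
  if (!inherits(library, "me_library")) stopf("library must be an me_library")
  bed <- function(x) if (is.character(x)) read_intervals(x) else x
  list(samples = samples, reference = reference, library = library,
       ref_mes = bed(ref_mes), gaps = bed(gaps),
       genes = if (is.character(genes)) read_gene_model(genes) else genes,
       fl_sources = bed(fl_sources), mode = mode, params = params,
       strict = strict)
}

load_sample <- function(x, name) {
  if (inherits(x, "aln_table")) {
    if (nrow(x) && x$sample[1L] != name) {   # config name wins
      x <- copy(x)
      x[, sample := name]
    }
    return(x)
  }
  if (is.character(x) && file.exists(x)) return(read_alignments(x, sample = name))
  stopf("sample '%s' is neither an alignment table nor a readable file", name)
}

## single chain shared by both modes: pooled discovery + per-sample genotyping
run_chain <- function(config, sample_names) {
  p <- config$params
  aln_by_sample <- lapply(sample_names, function(nm)
    load_sample(config$samples[[nm]], nm))
  names(aln_by_sample) <- sample_names
  evidence <- lapply(sample_names, function(nm)
    extract_evidence(aln_by_sample[[nm]], config$library, p, config$strict))
  pool <- merge_samples(evidence)
  disc <- discover_sites(pool, config$reference, config$ref_mes, config$gaps, p)
  calls <- annotate_calls(disc, config$library, config$reference,
                          config$fl_sources, config$genes, p)
  ev_by_sample <- lapply(sample_names, function(nm) {
    i <- match(nm, pool$samples)
    list(drp = disc$drp[sample == nm], sr = disc$sr[sample == nm],
         frag_mean = pool$summaries[[i]]$frag_mean,
         frag_sd = pool$summaries[[i]]$frag_sd)
  })
  names(ev_by_sample) <- sample_names
  gts <- genotype_samples(calls, ev_by_sample, aln_by_sample, p)
  calls <- apply_site_filters(calls, gts, p)
  vcf <- write_vcf(calls, gts[, .(site_id, sample, gt, gl, gq, ad_ref, ad_alt)],
                   sample_names, path = NULL, reference = config$reference)
  stats <- data.table(sample = sample_names,
                      n_drp = vapply(evidence, function(e) nrow(e$drp), 0L),
                      n_sr = vapply(evidence, function(e) nrow(e$sr), 0L))
  list(calls = calls, genotypes = gts, vcf = vcf, stats = stats,
       evidence = evidence)
}

#' Run the full discovery-to-VCF pipeline
#'
#' Split mode performs per-sample evidence extraction, pooled discovery
#' over all samples' DRPs and split reads, joint genotyping of every sample
#' at every site and one merged VCF; single mode runs the same chain on each
#' sample alone. Split mode on one sample is byte-identical to single mode.
#'
#' @param config [mei_config()].
#' @param out_vcf optional path (single mode with several samples gets one
#'   file per sample, suffixed by sample name).
#' @return split mode: one result list (`calls`, `genotypes`, `vcf`,
#'   `stats`); single mode: named list of per-sample results.
#' @export
run_pipeline <- function(config, out_vcf = NULL) {
  if (config$mode == "split") {
    res <- run_chain(config, names(config$samples))
    if (!is.null(out_vcf)) writeLines(res$vcf, out_vcf)
    return(res)
  }
  out <- lapply(names(config$samples), function(nm) {
    res <- run_chain(config, nm)
    if (!is.null(out_vcf)) {
      path <- if (length(config$samples) == 1L) out_vcf
              else sub("(\\.vcf)?$", sprintf(".%s.vcf", nm), out_vcf)
      writeLines(res$vcf, path)
    }
    res
  })
  names(out) <- names(config$samples)
  if (length(out) == 1L) out[[1L]] else out
}
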