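Package: meiscan
Title: Discovery, Annotation and Genotyping of Mobile Element Insertions
    from Paired-End Whole-Genome Sequencing
Version: 0.1.0
Authors@R:
    person("meiscan", "developers", email = "meiscan@example.org",
           role = c("aut", "cre"))
Description: Detects non-reference mobile element insertions (Alu, LINE-1,
    SVA) from coordinate-sorted paired-end alignments using discordant
    read pairs and split reads, refines breakpoints and target-site
    duplications, annotates element-internal features (subfamily
    diagnostic mutations, 5-prime inversions, 3-prime transductions,
    gene impact), genotypes insertions and reference mobile-element
    deletions across many samples with a diploid binomial likelihood
    model, and writes VCF 4.2. Ships a hermetic diploid genome and
    paired-read simulator with truth-aware alignment projection so the
    whole pipeline can be exercised and benchmarked without external
    data or aligners.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    data.table,
    stats,
    utils,
    tools,
    Biostrings,
    GenomicAlignments,
    IRanges,
    S4Vectors,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    SummarizedExperiment,
    Rsamtools
Config/testthat/edition: 3
RoxygenNote: 7.3.3
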