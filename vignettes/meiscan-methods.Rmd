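---
title: "meiscan methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{meiscan methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Alu, LINE-1 (L1) and SVA elements remain active in human genomes; new
insertions are structural variants that short-read pipelines miss unless
they exploit two signals: *discordant read pairs* (DRPs), where one mate
anchors on the reference and the other derives from the inserted element,
and *split reads* (SRs), soft-clipped at the insertion breakpoint with the
clip derived from the element. All three classes integrate by
target-primed reverse transcription, so insertions carry hallmark
features: target-site duplications (TSDs), 3′ poly(A) tails, 5′
truncations, twin-priming 5′ inversions, 3′ transductions, and
lineage-diagnostic interior mutations. meiscan detects insertions from
these signals, annotates the hallmark features, genotypes insertions and
reference-ME deletions across samples, and ships its own
simulation-and-evaluation harness.

# Evidence model and its assumptions

A pair is a DRP candidate when the mates map to different chromosomes or at
least 1 Mbp apart (inclusive bound). The candidate's non-anchor mate is
realigned to the consensus library with local alignment (match +2, mismatch
−2, gap open −3, gap extend −1) and accepted at ≥ 30 aligned consensus bp
and ≥ 0.88 identity. These thresholds are chosen so that an error-free
30-bp element fragment always passes while shuffled sequence essentially
never does (property-tested over 1,000 seeded shuffles). A 16-mer
prescreen skips the quadratic alignment for sequences sharing no exact
16-mer with a consensus — an error-free read with a handful of interior
mutations always retains a clean 16-mer, so under the simulator's zero-error
world the prescreen is lossless; on error-rich real data it would trade a
little sensitivity for speed.

Two deliberate extensions of the strict mapped–mapped DRP definition:

* **One-end-unmapped pairs are admitted** as DRP candidates (`strict =
  FALSE` default): a mate lying wholly inside a novel insertion may simply
  fail to map. The strict mode disables this.
* **Anchors must lie on the genome**: an alignment onto the consensus/decoy
  contigs themselves never anchors a site.

Split-read clips may be as short as the 20-bp clip minimum, so the
aligned-length floor is relaxed to the clip minimum for clips (otherwise a
clean 20–25 bp clip could never carry its consensus placement, which the
evidence contract requires).

# Discovery, breakpoints and the quality tranche

DRP anchors are clustered per chromosome by single linkage with a 500-bp
gap (about one fragment length; the method's source material states only
the ≥ 4-DRP cluster threshold, which is applied to the sum over samples —
this pooling *is* the multi-sample mode's sensitivity gain). `+`-strand
anchors point into the site from the left, `−` from the right.

Because two insertions slightly more than one window apart can chain into a
single anchor cluster, a candidate whose clip positions form groups
separated by > 150 bp (far beyond any plausible TSD) is split at the
midpoints between groups and each part re-admitted against the threshold.

Breakpoints: the modal clip position of left-side (trailing) clips is
`bpL`, of right-side (leading) clips `bpR`; modal ties break toward the
smaller coordinate. `bpL > bpR` ⇒ TSD = `ref[bpR, bpL)`; `bpL < bpR` ⇒
target-site deletion; equality ⇒ blunt. With no SRs the insertion point is
the midpoint between the innermost anchor ends. The insertion point is the
0-based position of the first base after the junction; VCF POS (the single
0→1-based conversion point) is the anchor base immediately 5′ of it.

Orientation is decided primarily from the poly(A) geometry of the junction
clips (leading clips end A-rich for `+` insertions; trailing clips start
T-rich for `−`), falling back to the majority consensus strand of the
3′-biased half of the mate alignments — the 3′ half because a twin-priming
inversion flips the 5′ half's strand and would otherwise flip the call.
Remaining ties default to `+` and flag the site `lc`.

The 0–5 ASSESS tranche is this package's concretisation of a 0–5
breakpoint-quality scale whose exact mapping is not published: 5 = SRs both
sides agreeing on a duplication/deletion joint (each side's modal position
supported by ≥ 50% of that side's clips); 4 = SRs both sides, blunt or
inconsistent; 3 = one-sided SRs plus two-sided DRPs; 2 = two-sided DRPs;
1 = one-sided DRPs (flagged `lc`); 0 otherwise.

Filters annotate rather than delete (`FILTER` ≠ PASS in the VCF), keeping
the cascade auditable: `refME` (same-class reference ME within 50 bp),
`mask` (gap interval padded by a fragment length), `depth` (window depth
outside 0.25–2.5× the chromosome median), then after genotyping `lc`,
`hNC` (no-call fraction > 0.25) and `noSR`. The named filters come from the
method's description; every numeric threshold here is this package's
documented choice.

# Feature annotation

The consensus-space pileup aggregates the already-accepted mate and clip
alignments. This has one structural blind spot that a maintainer should
know: fragments lying *wholly inside* a long insertion pair two
element-derived reads and carry no genome anchor, so the interior of a
full-length L1 (≈ 5 kb of its middle) receives little or no pileup depth
from a 500-bp-fragment library. Alu and SVA are fully covered; for L1 the
covered windows are the ~400 bp inside each junction. Consequences:
interior mutations and subfamily diagnostics in the uncovered middle are
unassessable (they are excluded from the subfamily score rather than
counted against it), and SVLEN for long elements is the covered span plus
the poly(A) estimate.

Interior mutations require depth ≥ 3 and non-consensus fraction ≥ 0.7;
CpG-dinucleotide positions are flagged and excluded from novel-subfamily
keys. Subfamily score = (diagnostics present) − 0.5 × (diagnostics absent
but assessable); ties prefer fewer diagnostics, then lexicographic order,
so an empty profile yields the root family. CpG-site mutations do
contribute to known-subfamily assignment (the source material excludes them
only for novel-subfamily discovery). Novel subfamilies require ≥ 5
independent loci sharing a non-CpG, non-diagnostic mutation set — the
boundary (4 vs 5) is tested explicitly.

5′ inversions: relative strand = alignment strand vs insertion
orientation. The reverse-complemented 5′ segment of a twin-primed element
sits at a junction-adjacent end of the insert, so its rightmost alignment
end abuts the junction exactly; the same-strand 3′ group only reaches the
junction when coverage is contiguous. The junction estimate therefore uses
the opposite-strand group's rightmost end, averaged with the same-strand
group's leftmost start only when the two bounds are within 200 bp. A call
needs ≥ 3 alignments per strand group; single-strand elements are
assessable only when their span reaches the consensus 5′ end (a 5′
truncation leaves the missing part unseen — mirroring the "could not
measure due to lack of evidence at one end" caveat of the field's
callers). The published observation that no junction falls in the first
~590 bp of L1 is an analysis result, not an algorithm rule, and is not
encoded.

3′ transductions: tails 3′ of the consensus end are stripped of a first
poly(A) run (≥ 8 A's); tails ≥ 30 bp and < 80% A are placed on the
reference by near-exact matching (≤ 2 mismatches); only a unique placement
is accepted (two hits ⇒ no call), and the source is the annotated
full-length element whose 3′ end lies within 500 bp 5′ of the locus on the
matching strand, else "unplaced". The poly(A) definitions (run ≥ 8, tail
< 80% A) separate tags from tails exactly under zero sequencing error;
error-rich data would need looser run definitions.

# Genotyping

For `g` ∈ {0,1,2} alt copies, `p(g) = (g/2)(1−e) + (1−g/2)e` with
`e = 0.01`; `L(g) = p(g)^a (1−p(g))^b`; flat prior; GL are log10-scaled and
normalised to max 0; GQ = 10·(log10 L(best) − log10 L(second)); fewer than
2 informative fragments gives `./.`. The published method says only that a
modified version of a standard SNP-likelihood framework is used; this
closed form is the package's concretisation — standard, testable against
direct evaluation, and monotone in the evidence (property-tested).

Evidence counting de-duplicates per fragment. Ref support must cleanly
span the breakpoint (±20 bp window, no clip ≥ 5 bp) *and* have an apparent
fragment length within 3 SD of the sample mean; the insert-length condition
excludes pairs that actually jump the inserted sequence, which would
otherwise inflate ref support at short-element hom-alt sites.

Deletion genotyping of reference-ME intervals mirrors this: alt = pairs
jumping the interval (reference span minus interval length within 3 SD of
the fragment mean — physically, mates from a deleted haplotype are
separated by fragment + interval on the reference) plus reads clipped at an
interval edge; ref = reads wholly inside the interval. Ref-inside counting
is restricted to within one fragment length of an edge, so ref counts scale
with fragment length like the alt counts do — otherwise a 6-kb L1 interval
accumulates interval-length-proportional ref reads and the binomial model
miscalls heterozygous deletions. Intervals shorter than two read lengths
are reported `./.` (not assessable).

# The simulator: what it emulates, what it does not

The generator's defaults are the stated benchmark world: an NA12878-like
class distribution (Alu:L1:SVA = 922:146:46, scaled to the synthetic
reference length; the rarest class keeps 10 copies at the 5-Mbp benchmark
size, giving 200/32/10), 95% heterozygous / 5% homozygous, 100-bp pairs at
500 ± 50 bp fragments, zero base error, and a 60/30/15/7.5× coverage
ladder with binomial fragment thinning for down-sampling. Where the
source material states no value the defaults are fixed once at realistic
choices and not revisited: TSD length uniform 4–20 bp with 5% target-site
deletions of 1–10 bp; poly(A) 10–40; L1 30% full-length, otherwise uniform
5′ truncation; L1 5′ inversion probability 0.182 (the published germline
rate, used as a generator default, not a claim); L1 3′ transduction
probability 0.1 with 60–150 bp tags copied from downstream of annotated
full-length source copies embedded in the reference.

Alignment is replaced by truth-aware projection: reads wholly in
unmodified sequence map at the lifted coordinate (`100M`, MAPQ 60); reads
crossing a boundary keep a ≥ 20 bp genome anchor and soft-clip the rest;
reads wholly inside an insertion map onto a decoy contig named after the
element class, so straddling pairs satisfy the different-chromosome DRP
definition by construction. This makes the suite hermetic and exactly
reproducible, at the price of not modelling real aligner behaviour:
no mapping ambiguity in repeats, no MAPQ degradation, no chimeric
mis-mappings, no base errors or quality strings. A green benchmark
therefore establishes the pipeline's logic (clustering, refinement,
annotation, genotyping, evaluation) under ideal mapping, not its
robustness to real-data noise. The synthetic consensus library is random
DNA at realistic class lengths (281/6019/1316 bp) with toy subfamily
profiles; it is labelled synthetic and is not a biological consensus.

Evaluation uses greedy one-to-one class-matched assignment within ±500 bp,
the published correctness rule.

# Numerical and degenerate-input choices

* All internal coordinates are 0-based half-open; the VCF writer is the
  only conversion point.
* Modal clip ties break toward the smaller coordinate; alignment ties break
  by score, then library order, then `+` strand, then smaller start —
  everything is deterministic, and two runs with the same seed produce
  byte-identical VCF bodies.
* Seeds: one global seed per simulated world; every internal stream derives
  from it by a labelled hash kept below 2^31.
* Empty inputs (no reads, no calls, empty BED/gene model) produce empty but
  valid outputs; a site reaching refinement always has ≥ 1 DRP by
  construction, and violating that is an internal error.

# Known limitations

* Interior-mutation and subfamily calls for long (L1-sized) elements are
  limited to junction-proximal windows (see the pileup blind spot above);
  subfamily recovery is quoted on fully-covered classes.
* One locus, one allele: multi-allelic insertions at a single site are out
  of scope, as are local assembly, CRAM input and long reads.
* The genotyper uses no population priors or allele-frequency refinement.
* SVA subfamilies are annotated at class level only, mirroring the
  Alu/L1-first scope of the field's interior-mutation classifiers.
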