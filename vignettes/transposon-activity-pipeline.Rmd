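---
title: "Detecting stage-specific transposon activity from assemblies and read summaries"
author: "karyoscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting stage-specific transposon activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyoscan)
```

## The problem

Mushroom-forming fungi alternate between a long-lived dikaryotic stage (two
haploid nuclei per cell) and haploid monokaryotic stages derived from
protoplasts or sexual spores. A recurring observation is that large
structural variants — mostly transposable-element (TE) insertions and
excisions — appear almost exclusively in the haploid isolates, while the
dikaryon is remarkably stable. Detecting this requires comparing genome
assemblies of closely related isolates for TE presence/absence
polymorphisms, classifying each variant's cellular penetrance from read
support, scanning for mitotic recombination between the two nuclear
genotypes, and quantifying TE family load and CpG methylation. karyoscan
implements that analysis chain as composable functions, together with a
synthetic-data generator that plants known events so the entire pipeline is
testable without any sequencing data.

## Empty-site calling

The core procedure detects loci where a TE present in one assembly (the
"filled" site) is absent in another (the "empty" site):

1. `extract_flanks()` takes 5,000 bp on each side of every annotated TE copy
   larger than 120 bp. Flanks exclude the TE itself; copies whose flanks are
   truncated by a contig end are flagged, and loci whose usable flank drops
   below the alignment threshold are skipped rather than silently tested at
   a weaker threshold, so the printed thresholds stay exact.
2. `call_putative_empty_site()` searches both flanks against the other
   assembly. A putative empty site requires the best hits of both flanks on
   the same contig, in the same orientation, each with an alignment of at
   least 4,500 bp, and with their inner ends within 20 bp of each other.
   Distances down to −20 bp (a slight overlap) are accepted: at a filled
   donor locus the target-site duplication (TSD) places the same few bases
   at the inner end of both flanks, so at the true empty locus the two hits
   legitimately overlap by the TSD length.
3. `confirm_empty_site()` concatenates the flanks into an artificial
   "empty" query. The call is confirmed only if that merged query has
   exactly one hit with ≥ 99% identity over ≥ 9,000 bp. The single-hit rule
   protects against paralogous loci; the length rule guarantees both flanks
   participate.
4. `cluster_homologous_loci()` groups calls from different assembly pairs
   that concern the same locus, requiring homologous flanks and a
   per-genome span of at most 70 kb. With 9 kb of merged flank, this caps
   detectable insertions at `implied_max_insertion()` = 61,000 bp.
5. `detect_tsd()` enumerates every placement of the inserted segment that is
   consistent with the filled/empty sequence difference and reports the
   longest exact duplication (≤ 20 bp) at the junction, flagging ambiguous
   junctions (e.g. homopolymers). Exact matching is a deliberate
   codification of what is otherwise a visual-inspection step.

### The similarity search

All of the above sits on `local_search()`, a self-contained seed-and-extend
local aligner: exact 15-mer anchors are chained by subject position and
diagonal, and each chain is aligned by banded affine-gap Smith–Waterman
(match +2, mismatch −3, gap open 5, gap extend 2; a gap of length L costs
5 + 2L). Identity is matches / alignment columns, so gap columns count
against identity, and N never counts as a match. On small instances
(query ≤ 2 kb against a subject ≤ 5 kb) the search switches to exhaustive
dynamic programming with mask-and-repeat, which the test suite holds equal
to an independent DP implementation. Chains whose query span is below half
the minimum reported alignment length are skipped before DP; an alignment
passing the identity filter necessarily contains long exact stretches, so
this prunes short-repeat cross-matches (TIR-only or LTR-only matches)
without affecting reportable hits. Ties are resolved by score and then by
leftmost subject coordinate, making the output deterministic.

`self_inverted_repeat()` measures terminal inverted repeats by comparing an
element's 5′ end with the reverse complement of its 3′ end, end-anchored and
ungapped; among candidate lengths the matches-minus-mismatches score picks
the repeat length, with ties going to the shorter candidate.
`best_source_copy()` attributes a new insertion to the candidate genomic
copy with the highest global identity on either strand, reporting exact
ties as ambiguous rather than picking arbitrarily.

## Variant filters

`size_filter()` keeps variants of ≥ 50 bp (translocations have no length and
always pass). `classify_fixed_mosaic()` calls a variant *fixed* when fewer
than three reads carry the reference allele and *mosaic* otherwise, and
always reports the mosaic fraction alt/(alt+ref); the two states partition
every supported call. `consensus_filter()` requires agreement of at least
three caller modules (set semantics on the labels), and
`uniqueness_filter()` removes calls whose interval overlaps a call in any
other sample — point-like insertion breakpoints are padded by 100 bp on each
side because breakpoint coordinates jitter between callers.
`classify_deletion_mechanism()` explains deletions from the annotation
context: a TE excision (boundaries within ±10 bp of a copy), a solo-LTR
formation (internal sequence plus one LTR removed), or an inter-copy
recombination deletion (breakpoints inside two homologous copies, relative
orientation recorded).

## Recombination scan and diversity

The scan works on a haploid site-by-sample genotype matrix with two
nucleotype groups. A site is *discordant* in a focal sample when its call
differs from its own group's consensus and equals the other group's
consensus; the focal sample is excluded from its own group's consensus so a
sample cannot vote for itself. Candidate tracts are maximal runs of at
least two consecutive discordant sites, where "consecutive" means adjacency
in the sorted site list, and missing calls break runs — a conservative
stand-in for the mapping-quality review that such candidates receive in
practice (a mappability mask can be applied upstream by setting calls to
missing). `nucleotide_diversity()` is the average number of pairwise
differences per callable site; the callable length is an explicit argument
because a variant matrix does not know how much of the genome was callable.

## TE family load

Per-sample depth over each family consensus is first rescaled to a 35×
single-copy target (`normalization_factor()`, capped at 1 — samples below
target are never upsampled). `family_presence_median()` codes a family
absent (median 0) unless at least 90% of consensus positions reach 15×,
which guards against partial structures such as solo LTRs masquerading as
low-copy presence; the median is taken over all consensus positions.
`cv_across_samples()` is the n−1 standard deviation over the mean, and
`quartile_rank()` flags families strictly above the type-7 third quartile.
Type-7 (linear interpolation) is the default quantile convention of this
statistical environment, which is what the downstream numbers were
calculated with; the sample SD is chosen because the population here is
seven genomes.

## Methylation

Per-read CpG calls pass three mapping filters — mapq 60, primary alignment,
and an uninterrupted aligned reference span of at least 6 kb
(`filter_reads()`). The span filter is what separates the two nucleotypes'
reads in dikaryon data; "uninterrupted mapping distance" is codified as the
contiguous aligned reference span of the primary alignment, clipping
excluded, which is the most literal testable reading.
`site_frequencies()` aggregates calls into per-site methylation
frequencies. `compare_repeat_vs_nonrepeat()` labels sites by repeat-interval
overlap (the non-repeat class is the complement of the repeat intervals) and
downsamples before a two-sided rank-sum test. Downsampling "500 times" is
read as a 500-fold reduction of the site count — one balanced subsample per
class, then one test — because that reading keeps the test exactly
calibrated — a single test on disjoint subsampled data has its nominal
type-I error, which the acceptance checks verify. The alternative reading
(500 subsample replicates summarised by the median p-value) cannot be
calibrated: the median of correlated p-values is pulled toward 0.5, so its
rejection rate under the null falls below the nominal level. Both modes are implemented;
the replicate mode is documented as a stability summary, not a calibrated
p-value. `te_copy_methylation()` reports per-copy mean frequencies, which
is how hypomethylated source copies stand out against their methylated
paralogs.

## The synthetic-data generator

`simulate_ancestral()` builds a genome of 4 × 50 kb contigs (i.i.d.
background at configurable GC) and plants a TE library emulating the
structures the pipeline keys on: two DNA-transposon families sharing a
28-bp terminal inverted repeat (an autonomous 1,200 bp element and a 450 bp
nonautonomous partner, 8 bp TSDs — hAT-like values), a LINE-like element
planted with variable 5′ truncation (12 bp TSD), and a 2,400 bp LTR element
with paired 250 bp LTRs (5 bp TSD). Copies diverge from their consensus by
0.5% so that source-copy attribution is meaningful. Planted loci keep
5,200 bp between each other and 5,000 bp from contig ends, so every flank is
unique background sequence; with i.i.d. background the chance of an
accidental homologous flank is negligible at these sizes. A "hard mode" is
simply a smaller `min_separation`, which is exposed in the configuration.

`derive_sample()` applies per-sample event plans. The defaults put 5
insertions and 5 excisions in each of two derived samples — 20 clean events
per dataset, the unit the recovery tests use — plus one solo-LTR deletion,
one inter-copy recombination deletion and one inversion to exercise the
deletion classifier. Excision removes exactly the TE and leaves both TSD
copies as a footprint (the classic DNA-transposon excision footprint), so a
derived genome is shorter by exactly the TE length; insertions duplicate
the target site around the copied element. Every event's coordinates are
verified against the emitted sequence before the truth table is returned.

Read support is Binomial(40, mosaic fraction) per event; mosaic fractions
are uniform on [0.15, 1] with a 20% chance of being exactly 1, reflecting a
single-cell bottleneck followed by drift during mycelial propagation. Depth
is negative binomial with mean copy-number × coverage (dispersion 20;
large dispersion recovers Poisson), and per-sample raw coverages are drawn
above the 35× target so normalization is always a down-scaling.
Methylation uses per-site latent frequencies Beta-distributed around class
means 0.76 (repeats) and 0.20 (elsewhere) with precision 10, and per-read
Bernoulli calls; read attributes are drawn so a configurable fraction fails
each mapping filter. Genotype matrices place enough divergent sites between
the two nucleotype groups to hit a target diversity (default π = 0.0056)
exactly by construction, with an optional planted swapped block for the
recombination scan.

What the generator does *not* emulate: sequencing error, chimeric reads,
low-complexity and segmental-duplication background, nested and tandem TE
insertions near event loci, or assembly artifacts. Passing the recovery
tests therefore demonstrates the correctness of the calling logic under
clean homology, not robustness to the full messiness of real assemblies —
on real data the curation steps (nested-locus flags, skip logs, reject
reasons) are where that messiness surfaces.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere inside the package;
  conversion happens only at I/O boundaries (BED is native, RepeatMasker
  `.out` is 1-based inclusive, the tabular hit format is written 1-based).
* Alignment tie-breaks: best score, then leftmost subject coordinate; DP
  traceback prefers diagonal moves. Fixed inputs give identical output.
* The contig end-merge requires the overlap to reach within 50 bp of A's
  end and B's start, at ≥ 99% identity over ≥ 1 kb (the merge script this
  emulates leaves these unstated; the values are deliberately
  conservative). Failing that, the join is `A + 100×N + B`. N bases never
  count toward identity, so N runs cannot justify a merge, and a full-span
  self-identical overlap is rejected as degenerate.
* Zero-support variants, empty genotype groups, all-zero medians, fewer
  than four families for quartiles, empty site classes and zero callable
  length all raise explicit errors rather than propagating NaN.
* Problem sizes in the tests: recovery runs three 200-kb datasets with 20
  planted clean events each; oracle equivalence uses 50 instances of
  ≤ 2 kb; calibration uses 200 replicates per setting. These sizes were
  chosen so the full suite exercises every claim at desk scale.

## Known limitations

* The seeded search can miss alignments whose longest exact match is below
  the 15-mer seed (≈ 77% identity and below); all thresholds in this
  pipeline sit far above that regime.
* `cluster_homologous_loci()` links loci through left-flank homology only;
  a locus whose left flank was deleted in one genome would need the
  right-flank route, which is not implemented.
* The recombination scan reports candidates; it cannot reproduce the
  read-level visual review that dismisses mapping artifacts, only the
  mask hook for it.
* TSD detection is exact-match; a TSD mutated after insertion is reported
  shorter or not at all.
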