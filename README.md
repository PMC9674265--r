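# karyoscan

Detecting stage-specific transposable-element (TE) activity in fungal
genomes from assemblies and read-level summaries.

Mushroom-forming fungi cycle between a long-lived dikaryon (two haploid
nuclei per cell) and haploid monokaryons derived from protoplasts or
basidiospores. Comparing genome assemblies of such closely related isolates
shows where a TE copy present in one genome (a *filled* site) is absent in
another (an *empty* site) — the signature of a recent insertion or
excision. karyoscan implements that comparison and the analyses around it:

* **Empty-site calling** — extract 5 kb flanks of every annotated TE copy
  (> 120 bp), call a putative empty site where both flanks hit the other
  assembly on the same contig and strand, ≥ 4,500 bp each, with inner ends
  within 20 bp; confirm it only when the merged flank query has exactly one
  hit at ≥ 99% identity over ≥ 9,000 bp; cluster homologous loci across
  pairs (span ≤ 70 kb, implying a 61 kb insertion-size cap) and detect
  target-site duplications (TSDs).
* **Variant filters** — the ≥ 50 bp size rule; *fixed* (fewer than 3
  reference reads) vs *mosaic* classification with the mosaic fraction
  alt/(alt+ref); ≥ 3-caller consensus; cross-sample uniqueness; and
  deletion-mechanism classification (TE excision, solo-LTR,
  inter-copy recombination).
* **Mitotic recombination scan** — runs of ≥ 2 consecutive sites in a
  haploid genotype matrix where one sample swaps to the other nucleotype's
  consensus, plus nucleotide diversity (π).
* **TE family load** — depth over family consensi normalized to 35×,
  presence requiring 15× across 90% of the element, per-family coefficient
  of variation (SD/mean) across genomes and above-Q3 ranking.
* **CpG methylation** — per-site methylation frequencies under strict read
  filters (mapq 60, primary, ≥ 6 kb span), repeat vs non-repeat comparison
  with seeded downsampling and a rank-sum test, and per-copy means.
* **A synthetic-data generator** that plants insertions (with TSDs),
  excisions, solo-LTR and recombination deletions and inversions into a
  simulated ancestral genome, with truth tables, read support, depth and
  methylation models — so the whole pipeline runs and is tested without any
  external data.

A self-contained seed-and-extend local aligner (exact 15-mer anchors,
banded affine Smith–Waterman in compiled code) backs the sequence
comparisons; on small instances it is held equal to exhaustive dynamic
programming by the test suite.

## Worked example

Simulate a dataset with planted events and recover them:

```r
library(karyoscan)

sim <- simulate_dataset(sim_config(), seed = 1)
table(sim$truth$type)
#>      excision     insertion     inversion nahr_deletion      solo_ltr
#>            10            10             1             1             1

res <- evaluate_empty_site_recovery(sim)
c(events = res$n_events, recovered = res$n_recovered, false = res$n_false)
#>    events recovered     false
#>        20        20         0
```

The 20 clean events are the 10 insertions and 10 excisions planted across
two derived samples; all 20 come back as *confirmed* empty sites (each from
the correct comparison direction) and no confirmed call points at a locus
where nothing was planted.

Classify the planted variants from their simulated read support:

```r
st <- classify_fixed_mosaic(sim$support)
table(st$state)
#> fixed mosaic
#>     4     19
```

Events whose mosaic fraction reached 1 after the single-cell bottleneck
yield no reference reads and are called fixed; the rest are mosaic, with
`st$mosaic_fraction` estimating the planted fraction.

Methylation, on the same simulated genome:

```r
anc <- sim$ancestral
rec <- simulate_methylation(anc$genome, anc$annotations, seed = 2)
sf  <- site_frequencies(filter_reads(rec))
cmp <- compare_repeat_vs_nonrepeat(sf, anc$annotations, n_downsample = 5,
                                   seed = 3)
round(c(repeat_ = cmp$mean_repeat, nonrepeat = cmp$mean_nonrepeat), 2)
#>  repeat_ nonrepeat
#>     0.76      0.20
cmp$p_value
#> [1] 1.41e-82
```

Repeat sites come out near the generator's 0.76 class mean, non-repeat
sites near 0.20, and the rank-sum comparison (here at a 5-fold site
reduction — the ~12,000 CpG sites of a 200-kb simulated genome are three
orders of magnitude fewer than a real genome's) is strongly significant.

A thin command-line wrapper is installed as `exec/karyoscan`
(subcommands `density`, `empty-sites`, `te-load`, `methyl`, `recomb-scan`,
`simulate`); it only parses arguments and calls the functions above.

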