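Package: karyoscan
Title: Stage-Specific Transposon Activity Analysis for Fungal Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and characterising transposable-element (TE)
    activity across the stages of a fungal life cycle from genome assemblies and
    read-level summaries. Implements flank-anchored presence/absence (empty-site)
    calling between assemblies with target-site-duplication detection,
    fixed/mosaic classification of variants from read support, multi-caller
    consensus and cross-sample uniqueness filtering, deletion-mechanism
    classification (excision, solo-LTR, inter-copy recombination), a
    mitotic-recombination scan over haploid genotype matrices with nucleotide
    diversity, coverage-based TE family load estimation with population
    coefficient-of-variation ranking, per-CpG methylation frequency aggregation
    with repeat versus non-repeat comparison, and a deterministic synthetic-data
    generator that plants known TE events so the whole pipeline is testable
    without external data.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
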