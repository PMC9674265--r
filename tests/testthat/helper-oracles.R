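# Independent oracles used to check the package's own implementations.

# Exhaustive local-alignment oracle: Biostrings' dynamic-programming engine
# with the same scoring scheme as align_scoring(). Returns the single best
# local alignment; identity = matches / alignment columns.
oracle_local_align <- function(q, s, scoring = align_scoring()) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(scoring$match,
                                                  scoring$mismatch,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(q), Biostrings::DNAString(s), type = "local",
    substitutionMatrix = mat, gapOpening = scoring$gap_open,
    gapExtension = scoring$gap_ext)
  pr <- aln@pattern@range
  sr <- aln@subject@range
  list(score = Biostrings::score(aln),
       q_start = BiocGenerics::start(pr) - 1L, q_end = BiocGenerics::end(pr),
       s_start = BiocGenerics::start(sr) - 1L, s_end = BiocGenerics::end(sr),
       identity = 100 * Biostrings::nmatch(aln) / Biostrings::nchar(aln),
       aln_len = Biostrings::nchar(aln))
}

# per-base brute-force windowed density
brute_density <- function(ann, g, window, step) {
  lens <- karyoscan::contig_lengths(g)
  out <- list()
  for (ctg in names(lens)) {
    len <- lens[[ctg]]
    covered <- logical(len)
    a <- ann[ann$contig == ctg, , drop = FALSE]
    for (i in seq_len(nrow(a)))
      covered[(a$start[i] + 1):a$end[i]] <- TRUE
    starts <- seq.int(0L, max(0L, len - 1L), by = step)
    starts <- starts[starts < len]
    ends <- pmin(starts + window, len)
    fr <- vapply(seq_along(starts), function(k)
      mean(covered[(starts[k] + 1):ends[k]]), numeric(1))
    out[[ctg]] <- data.frame(contig = ctg, start = starts, end = ends,
                             fraction = fr, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# brute-force pairwise nucleotide diversity over a 0/1/NA matrix
brute_pi <- function(geno, callable_length) {
  n <- ncol(geno)
  tot <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(geno[, i]) & !is.na(geno[, j])
    tot <- tot + sum(geno[ok, i] != geno[ok, j])
    np <- np + 1
  }
  (tot / np) / callable_length
}

# substitute k random positions of a sequence (guaranteed changes)
mutate_positions <- function(seq, k) {
  v <- strsplit(seq, "")[[1]]
  pos <- sample(length(v), k)
  for (i in pos) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  paste(v, collapse = "")
}
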