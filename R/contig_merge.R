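#' Merge two contigs by end overlap
#'
#' Looks for an alignment between the end of contig A and the start of
#' contig B. If a terminal overlap passes the length and identity thresholds,
#' the two sequences are joined gaplessly with the overlap collapsed once;
#' otherwise the join is `A + 100*N + B` and the report flags a gap. N bases
#' never count toward identity, so runs of N cannot justify a merge, and a
#' candidate overlap spanning essentially all of either contig (a
#' self-identical join) is rejected as degenerate.
#'
#' @param a,b contig sequences (non-empty DNA strings).
#' @param min_overlap minimum overlap length in bp.
#' @param min_identity minimum percent identity of the overlap alignment.
#' @param end_window how much of A's tail / B's head to search (bp).
#' @param end_slop how close the overlap must come to A's end and B's start.
#' @param scoring an [align_scoring()] scheme.
#' @return `list(sequence=, report=)`; the report records `gapped`,
#'   `overlap_length`, `identity` and a `reason` string.
#' @export
merge_contigs_by_end_overlap <- function(a, b, min_overlap = 1000,
                                         min_identity = 99,
                                         end_window = 20000, end_slop = 50,
                                         scoring = align_scoring()) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) == 0 || nchar(b) == 0) stop("contigs must be non-empty")
  gap_join <- function(reason) {
    list(sequence = paste0(a, strrep("N", 100), b),
         report = list(gapped = TRUE, overlap_length = 0L,
                       identity = NA_real_, reason = reason))
  }
  wa <- min(nchar(a), end_window)
  wb <- min(nchar(b), end_window)
  sufa <- substr(a, nchar(a) - wa + 1, nchar(a))
  preb <- substr(b, 1, wb)
  hit <- NULL
  seeds <- .kmer_seeds_cpp(sufa, preb, 15L)
  if (length(seeds$qpos)) {
    dg <- seeds$spos - seeds$qpos
    res <- .sw_banded_cpp(sufa, preb, min(dg) - 100L, max(dg) + 100L,
                          scoring$match, scoring$mismatch,
                          scoring$gap_open, scoring$gap_ext)
    if (res$score > 0) hit <- res
  }
  if (is.null(hit)) return(gap_join("no_overlap_alignment"))
  identity <- 100 * hit$matches / hit$aln_len
  terminal <- hit$q1 >= wa - end_slop && hit$s0 <= end_slop
  if (!terminal) return(gap_join("overlap_not_terminal"))
  if (hit$aln_len < min_overlap) return(gap_join("overlap_too_short"))
  if (identity < min_identity) return(gap_join("overlap_identity_below_threshold"))
  # reject a self-identical full-span overlap (e.g. a contig merged with itself)
  if (hit$q1 - hit$q0 >= 0.95 * nchar(a) || hit$s1 - hit$s0 >= 0.95 * nchar(b))
    return(gap_join("self_identical_full_span_overlap"))
  cut_a <- (nchar(a) - wa) + hit$q0       # keep A up to the overlap start
  merged <- paste0(substr(a, 1, cut_a), substr(b, hit$s0 + 1, nchar(b)))
  list(sequence = merged,
       report = list(gapped = FALSE, overlap_length = hit$aln_len,
                     identity = identity, reason = "merged"))
}
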