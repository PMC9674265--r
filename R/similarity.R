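#' Alignment scoring scheme
#'
#' Identity is defined as matches / alignment columns, so gap columns count
#' against identity. A gap of length L costs `gap_open + L * gap_ext`. N bases
#' never count as matches.
#'
#' @param match,mismatch per-base substitution scores.
#' @param gap_open,gap_ext affine gap penalties (positive numbers).
#' @return a list used by [local_search()] and friends.
#' @export
align_scoring <- function(match = 2, mismatch = -3, gap_open = 5, gap_ext = 2) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_ext > 0)
  list(match = match, mismatch = mismatch,
       gap_open = gap_open, gap_ext = gap_ext)
}

# minimum score any alignment passing (min_identity, min_length) can have;
# used to stop the mask-and-repeat iteration early
min_passing_score <- function(min_identity, min_length, scoring) {
  p <- min_identity / 100
  max(1, floor(min_length * (scoring$match * p + scoring$mismatch * (1 - p))))
}

# one banded alignment, returned as a hit row in subject-forward coordinates
aln_to_hit <- function(res, strand, qlen, contig_name, query_id) {
  if (res$score <= 0) return(NULL)
  q0 <- res$q0; q1 <- res$q1
  if (strand == "-") { tmp <- q0; q0 <- qlen - q1; q1 <- qlen - tmp }
  data.frame(query_id = query_id, subject_contig = contig_name,
             q_start = q0, q_end = q1, s_start = res$s0, s_end = res$s1,
             strand = strand,
             pct_identity = 100 * res$matches / res$aln_len,
             aln_length = res$aln_len, n_matches = res$matches,
             score = res$score, stringsAsFactors = FALSE)
}

# exhaustive DP on one (query-strand, contig): full band, multiple hits by
# masking each found alignment and repeating
search_exhaustive <- function(qseq, sseq, strand, contig_name, query_id,
                              min_identity, min_length, scoring) {
  qlen <- nchar(qseq)
  stop_score <- min_passing_score(min_identity, min_length, scoring)
  hits <- list()
  s_masked <- sseq
  for (iter in seq_len(50)) {
    res <- .sw_banded_cpp(qseq, s_masked, -qlen, nchar(sseq),
                          scoring$match, scoring$mismatch,
                          scoring$gap_open, scoring$gap_ext)
    if (res$score < stop_score) break
    hits[[length(hits) + 1L]] <- aln_to_hit(res, strand, qlen, contig_name,
                                            query_id)
    # forbid re-finding the same subject interval
    substr(s_masked, res$s0 + 1L, res$s1) <-
      strrep("#", res$s1 - res$s0)
  }
  hits
}

# seed-and-extend on one (query-strand, contig): k-mer anchors chained by
# subject position and diagonal, then banded DP per chain
search_seeded <- function(qseq, sseq, strand, contig_name, query_id,
                          min_identity, min_length, seed_k, scoring,
                          band_pad = 100, max_diag_jump = 100,
                          max_spos_gap = 2000) {
  seeds <- .kmer_seeds_cpp(qseq, sseq, seed_k)
  if (length(seeds$qpos) == 0) return(list())
  qp <- seeds$qpos; sp <- seeds$spos
  dg <- sp - qp
  # cluster seeds by diagonal band first (so stray off-diagonal seeds from
  # short repeats cannot fragment a chain), then split each band at large
  # subject-position gaps (so separate copies on the same diagonal stay
  # separate)
  ord <- order(dg, sp)
  band <- cumsum(c(1L, diff(dg[ord]) > max_diag_jump))
  cluster <- integer(length(qp))
  cid <- 0L
  for (b in split(ord, band)) {
    bo <- b[order(sp[b])]
    sub <- cumsum(c(1L, diff(sp[bo]) > max_spos_gap))
    for (piece in split(bo, sub)) {
      cid <- cid + 1L
      cluster[piece] <- cid
    }
  }
  qlen <- nchar(qseq)
  stop_score <- min_passing_score(min_identity, min_length, scoring)
  hits <- list()
  for (cl in split(seq_along(qp), cluster)) {
    # a chain whose query span is far below min_length cannot seed a passing
    # alignment; skipping those avoids DP on short-repeat cross-matches
    qspan <- max(qp[cl]) + seed_k - min(qp[cl])
    if (qspan < min_length / 2) next
    dmin <- min(dg[cl]) - band_pad
    dmax <- max(dg[cl]) + band_pad
    res <- .sw_banded_cpp(qseq, sseq, dmin, dmax,
                          scoring$match, scoring$mismatch,
                          scoring$gap_open, scoring$gap_ext)
    if (res$score >= stop_score)
      hits[[length(hits) + 1L]] <- aln_to_hit(res, strand, qlen, contig_name,
                                              query_id)
  }
  hits
}

empty_hits <- function(query_id = character(0)) {
  data.frame(query_id = character(0), subject_contig = character(0),
             q_start = integer(0), q_end = integer(0),
             s_start = integer(0), s_end = integer(0),
             strand = character(0), pct_identity = numeric(0),
             aln_length = integer(0), n_matches = integer(0),
             score = numeric(0), stringsAsFactors = FALSE)
}

#' Local similarity search
#'
#' Seed-and-extend local alignment of one query against every contig of a
#' subject genome, on both strands. Small instances (query <= 2 kb against a
#' contig <= 5 kb) are solved by exhaustive dynamic programming with
#' mask-and-repeat so that every maximal local alignment passing the filters
#' is reported; larger instances use exact k-mer anchors with banded DP
#' around each anchor chain. Results are deterministic for fixed inputs:
#' hits are sorted by descending score, ties by leftmost subject coordinate,
#' and overlapping hits on the same contig and strand are resolved the same
#' way.
#'
#' @param query DNA string (length >= `seed_k`).
#' @param subject a [genome()] or named character vector of contigs.
#' @param min_identity minimum percent identity (matches / alignment columns).
#' @param min_length minimum alignment length in columns.
#' @param seed_k k-mer size for seeding.
#' @param scoring an [align_scoring()] scheme.
#' @param query_id label carried into the hit table.
#' @return a `data.frame` of class `similarity_hits` with 0-based half-open
#'   `q_start`/`q_end` (on the forward query), `s_start`/`s_end`, `strand`,
#'   `pct_identity`, `aln_length`, `n_matches` and `score`.
#' @export
local_search <- function(query, subject, min_identity = 90, min_length = 100,
                         seed_k = 15, scoring = align_scoring(),
                         query_id = "query") {
  if (inherits(subject, "genome")) subject <- subject$contigs
  if (is.null(names(subject))) names(subject) <- paste0("contig", seq_along(subject))
  query <- toupper(query)
  if (nchar(query) < seed_k)
    stop("query shorter than seed_k (", seed_k, ")")
  qrc <- revcomp(query)
  all_hits <- list()
  for (ctg in names(subject)) {
    sseq <- toupper(subject[[ctg]])
    small <- nchar(query) <= 2000 && nchar(sseq) <= 5000
    for (strand in c("+", "-")) {
      qs <- if (strand == "+") query else qrc
      h <- if (small)
        search_exhaustive(qs, sseq, strand, ctg, query_id,
                          min_identity, min_length, scoring)
      else
        search_seeded(qs, sseq, strand, ctg, query_id,
                      min_identity, min_length, seed_k, scoring)
      all_hits <- c(all_hits, h)
    }
  }
  if (length(all_hits) == 0) return(structure(empty_hits(),
                                              class = c("similarity_hits", "data.frame")))
  hits <- do.call(rbind, all_hits)
  hits <- hits[hits$aln_length >= min_length &
                 hits$pct_identity >= min_identity, , drop = FALSE]
  if (nrow(hits) > 1) {
    hits <- hits[order(-hits$score, hits$s_start), , drop = FALSE]
    keep <- rep(TRUE, nrow(hits))
    for (i in seq_len(nrow(hits))[-1]) {
      prior <- which(keep[seq_len(i - 1)])
      same <- hits$subject_contig[prior] == hits$subject_contig[i] &
        hits$strand[prior] == hits$strand[i]
      ovl <- hits$s_start[prior] < hits$s_end[i] &
        hits$s_end[prior] > hits$s_start[i]
      if (any(same & ovl)) keep[i] <- FALSE
    }
    hits <- hits[keep, , drop = FALSE]
  }
  hits <- hits[order(-hits$score, hits$s_start), , drop = FALSE]
  rownames(hits) <- NULL
  class(hits) <- c("similarity_hits", "data.frame")
  hits
}

#' Write similarity hits in 12-column tabular format
#'
#' Mirrors the classic tabular search-output layout (query, subject, percent
#' identity, alignment length, mismatches, gap columns, query start/end,
#' subject start/end, e-value placeholder, score). Coordinates are written
#' 1-based inclusive as in that format; the in-memory table stays 0-based
#' half-open.
#'
#' @param hits a [local_search()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  gaps <- hits$aln_length - (hits$q_end - hits$q_start)
  mism <- hits$aln_length - hits$n_matches - pmax(gaps, 0)
  out <- data.frame(hits$query_id, hits$subject_contig,
                    sprintf("%.2f", hits$pct_identity), hits$aln_length,
                    mism, pmax(gaps, 0),
                    hits$q_start + 1L, hits$q_end,
                    ifelse(hits$strand == "+", hits$s_start + 1L, hits$s_end),
                    ifelse(hits$strand == "+", hits$s_end, hits$s_start + 1L),
                    ".", hits$score)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Terminal inverted repeat detection
#'
#' Aligns the 5' end of an element to the reverse complement of its 3' end
#' and reports the longest terminal (ungapped, end-anchored) repeat passing
#' the identity threshold. Among candidate lengths the one maximising
#' matches minus mismatches wins; ties go to the shorter length.
#'
#' @param seq element sequence (length >= 2 * `min_tir_len`).
#' @param min_tir_len minimum TIR length in bp.
#' @param min_tir_identity minimum percent identity of the repeat.
#' @return `list(tir_length=, tir_identity=)`, or `NULL` when no terminal
#'   inverted repeat passes.
#' @export
self_inverted_repeat <- function(seq, min_tir_len = 10, min_tir_identity = 90) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 2 * min_tir_len) stop("sequence shorter than 2 * min_tir_len")
  w <- n %/% 2
  a <- strsplit(substr(seq, 1, w), "")[[1]]
  b <- strsplit(revcomp(substr(seq, n - w + 1, n)), "")[[1]]
  match <- a == b & a %in% c("A", "C", "G", "T")
  cum <- cumsum(match)
  t <- seq_len(w)
  score <- cum - (t - cum)
  ident <- 100 * cum / t
  cand <- which(t >= min_tir_len & ident >= min_tir_identity & score > 0)
  if (length(cand) == 0) return(NULL)
  best <- cand[which.max(score[cand])]  # which.max takes the first: shortest tie
  list(tir_length = best, tir_identity = ident[best])
}

#' Attribute a new insertion to its most similar source copy
#'
#' Computes global percent identity (matches / alignment columns) between the
#' inserted sequence and each candidate genomic copy, on both strands, and
#' returns the best-matching copy. Exact ties are reported as ambiguous with
#' all tied copy ids.
#'
#' @param insertion_seq DNA string of the new insertion.
#' @param candidates named character vector of candidate copy sequences
#'   (names are copy ids), or a data.frame with `copy_id` and `seq` columns.
#' @return `list(copy_id=, identity=, ambiguous=, identities=)`.
#' @export
best_source_copy <- function(insertion_seq, candidates) {
  if (is.data.frame(candidates))
    candidates <- setNames(candidates$seq, candidates$copy_id)
  if (length(candidates) == 0) stop("no candidate copies supplied")
  if (is.null(names(candidates))) stop("candidates must be named by copy_id")
  mat <- Biostrings::nucleotideSubstitutionMatrix(1, -1, baseOnly = FALSE)
  pid_one <- function(s) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(toupper(insertion_seq)),
      Biostrings::DNAString(toupper(s)),
      type = "global", substitutionMatrix = mat,
      gapOpening = 2, gapExtension = 1)
    Biostrings::pid(aln, type = "PID1")
  }
  ids <- vapply(candidates, function(s) max(pid_one(s), pid_one(revcomp(s))),
                numeric(1))
  top <- max(ids)
  tied <- names(ids)[abs(ids - top) < 1e-9]
  list(copy_id = tied, identity = top, ambiguous = length(tied) > 1,
       identities = ids)
}

#' Annotate TE copies in a genome from a family consensus library
#'
#' A light repeat annotator: each family consensus is searched against the
#' genome with [local_search()] and every passing hit becomes one annotated
#' copy (overlapping hits of the same family are resolved by score inside the
#' search). Used to annotate simulated or newly assembled genomes.
#'
#' @param g a [genome()].
#' @param library named character vector of family consensus sequences.
#' @param min_identity,min_length hit filters passed to [local_search()].
#' @param seed_k seeding k-mer size.
#' @return a [annotations()] table.
#' @export
annotate_tes <- function(g, library, min_identity = 90, min_length = 150,
                         seed_k = 15) {
  rows <- list()
  for (fam in names(library)) {
    hits <- local_search(library[[fam]], g, min_identity = min_identity,
                         min_length = min_length, seed_k = seed_k,
                         query_id = fam)
    if (nrow(hits))
      rows[[fam]] <- data.frame(contig = hits$subject_contig,
                                start = hits$s_start, end = hits$s_end,
                                strand = hits$strand, family_id = fam,
                                stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    stop("no TE copies found in genome '", g$id, "'")
  df <- do.call(rbind, rows)
  # drop lower-scoring duplicates across families occupying the same interval
  df <- df[order(df$contig, df$start), , drop = FALSE]
  annotations(contig = df$contig, start = df$start, end = df$end,
              strand = df$strand, family_id = df$family_id)
}
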