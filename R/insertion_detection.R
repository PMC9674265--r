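#' Extract TE flanking sequences
#'
#' For every annotated TE copy larger than `min_te_len`, extracts up to
#' `flank_len` bp on each side (the TE itself is excluded). Flanks are
#' truncated at contig ends and the truncation is flagged. Copies whose flank
#' overlaps another annotation are flagged as nested; copies within 50 bp of
#' a same-family copy are flagged as tandem. Both are still processed.
#'
#' @param g a [genome()].
#' @param ann a [annotations()] table for `g`.
#' @param flank_len flank length in bp (default 5,000).
#' @param min_te_len copies must be strictly larger than this (default 120 bp).
#' @return a `data.frame` of class `flank_pairs`: one row per retained copy
#'   with `left_flank`/`right_flank` sequences, lengths, truncation, `nested`
#'   and `tandem` flags; the genome id is kept in the `genome_id` attribute.
#' @export
extract_flanks <- function(g, ann, flank_len = 5000, min_te_len = 120) {
  validate_annotations(ann, g)
  keep <- (ann$end - ann$start) > min_te_len
  a <- ann[keep, , drop = FALSE]
  lens <- contig_lengths(g)
  rows <- lapply(seq_len(nrow(a)), function(i) {
    ctg <- a$contig[i]; s <- a$start[i]; e <- a$end[i]
    len <- lens[[ctg]]
    ls <- max(0L, s - flank_len)
    re <- min(len, e + flank_len)
    others <- ann[ann$contig == ctg & ann$copy_id != a$copy_id[i], , drop = FALSE]
    nested <- any(others$start < re & others$end > ls)
    samefam <- others[others$family_id == a$family_id[i], , drop = FALSE]
    # tandem: another copy of the same family within 50 bp (edge to edge)
    tandem <- nrow(samefam) > 0 &&
      any(pmax(samefam$start - e, s - samefam$end) <= 50)
    data.frame(te_copy_id = a$copy_id[i], family_id = a$family_id[i],
               contig = ctg, te_start = s, te_end = e, strand = a$strand[i],
               left_flank = subseq0(g$contigs[[ctg]], ls, s),
               right_flank = subseq0(g$contigs[[ctg]], e, re),
               left_len = s - ls, right_len = re - e,
               left_truncated = (s - ls) < flank_len,
               right_truncated = (re - e) < flank_len,
               nested = nested, tandem = isTRUE(tandem),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(te_copy_id = character(0))
  attr(out, "genome_id") <- g$id
  attr(out, "flank_len") <- flank_len
  class(out) <- c("flank_pairs", "data.frame")
  out
}

#' Call a putative empty site for one TE copy
#'
#' Searches both flanks of a (donor) TE copy against a subject genome. The
#' locus yields a putative empty-site call iff the best left-flank hit and
#' the best right-flank hit land on the same subject contig, in the same
#' orientation, each with alignment length at least `min_flank_aln`, and with
#' their inner ends within `max_gap` bp of each other. Slightly overlapping
#' flank hits (down to `min_gap`, default -20 bp) are allowed: a target-site
#' duplication places the same few bases at the end of the left flank and the
#' start of the right flank of a filled donor locus. Best hit per flank is
#' the highest-scoring one, ties broken by leftmost subject coordinate.
#'
#' @param fp one row of [extract_flanks()] output.
#' @param subject the target [genome()].
#' @param max_gap maximum distance between inner flank-hit ends (bp).
#' @param min_gap most negative allowed distance (overlap) in bp.
#' @param min_flank_aln minimum per-flank alignment length (bp).
#' @param min_flank_identity percent identity floor for flank hits.
#' @param donor_genome donor genome label recorded in the call.
#' @param scoring an [align_scoring()] scheme.
#' @return a one-row `data.frame` call with `status = "putative"`, or an
#'   empty object of class `no_call` carrying a `reason` attribute when the
#'   locus yields no call.
#' @export
call_putative_empty_site <- function(fp, subject, max_gap = 20, min_gap = -20,
                                     min_flank_aln = 4500,
                                     min_flank_identity = 90,
                                     donor_genome = attr(fp, "genome_id"),
                                     scoring = align_scoring()) {
  none <- function(reason) structure(list(), class = "no_call",
                                     reason = reason)
  if (fp$left_len < min_flank_aln || fp$right_len < min_flank_aln)
    return(none("flank_truncated_below_min_aln"))
  hl <- local_search(fp$left_flank, subject, min_identity = min_flank_identity,
                     min_length = min_flank_aln, scoring = scoring,
                     query_id = paste0(fp$te_copy_id, ":L"))
  if (nrow(hl) == 0) return(none("no_left_flank_hit"))
  hr <- local_search(fp$right_flank, subject, min_identity = min_flank_identity,
                     min_length = min_flank_aln, scoring = scoring,
                     query_id = paste0(fp$te_copy_id, ":R"))
  if (nrow(hr) == 0) return(none("no_right_flank_hit"))
  bl <- hl[1, ]; br <- hr[1, ]
  if (bl$subject_contig != br$subject_contig) return(none("flank_hits_on_different_contigs"))
  if (bl$strand != br$strand) return(none("flank_hits_in_opposite_orientation"))
  if (bl$strand == "+") {
    gap <- br$s_start - bl$s_end
    junction <- (bl$s_end + br$s_start) %/% 2
  } else {
    gap <- bl$s_start - br$s_end
    junction <- (br$s_end + bl$s_start) %/% 2
  }
  if (gap > max_gap) return(none("flank_hits_too_far_apart"))
  if (gap < min_gap) return(none("flank_hits_overlap_beyond_limit"))
  data.frame(te_copy_id = fp$te_copy_id, family_id = fp$family_id,
             donor_genome = donor_genome,
             target_genome = if (inherits(subject, "genome")) subject$id else "subject",
             target_contig = bl$subject_contig, strand = bl$strand,
             junction = junction, flank_gap = gap,
             left_identity = bl$pct_identity, left_aln = bl$aln_length,
             right_identity = br$pct_identity, right_aln = br$aln_length,
             status = "putative", merged_identity = NA_real_,
             merged_len = NA_integer_, reject_reason = NA_character_,
             tsd = NA_character_, stringsAsFactors = FALSE)
}

#' Confirm a putative empty site with a merged-flank search
#'
#' Builds the artificial merged query `left_flank + right_flank` and searches
#' it against the subject genome at the confirmation thresholds. The call is
#' confirmed iff the search returns exactly one hit with percent identity of
#' at least `min_identity` and alignment length of at least `min_len`;
#' otherwise it stays putative and the rejection reason (no merged hit, or
#' multiple homologous loci) is recorded.
#'
#' @param call a putative call from [call_putative_empty_site()].
#' @param fp the matching [extract_flanks()] row.
#' @param subject the target [genome()].
#' @param min_identity confirmation identity threshold (percent).
#' @param min_len confirmation alignment length threshold (bp).
#' @param scoring an [align_scoring()] scheme.
#' @return the call with `status` set to `"confirmed"` or left `"putative"`.
#' @export
confirm_empty_site <- function(call, fp, subject, min_identity = 99,
                               min_len = 9000, scoring = align_scoring()) {
  stopifnot(identical(call$status, "putative"))
  merged <- paste0(fp$left_flank, fp$right_flank)
  hits <- local_search(merged, subject, min_identity = min_identity,
                       min_length = min_len, scoring = scoring,
                       query_id = paste0(call$te_copy_id, ":merged"))
  if (nrow(hits) == 1) {
    call$status <- "confirmed"
    call$merged_identity <- hits$pct_identity[1]
    call$merged_len <- hits$aln_length[1]
  } else {
    call$reject_reason <- if (nrow(hits) == 0) "no_merged_hit"
      else "multiple_merged_hits"
  }
  call
}

#' Detect empty sites of one genome's TEs in another genome
#'
#' The full per-pair procedure: extract flanks of every TE copy in the donor,
#' call putative empty sites in the target, and confirm each with the
#' merged-flank search. Skipped loci and their reasons are kept in the `log`
#' attribute.
#'
#' @param donor donor [genome()] (whose TEs are queried).
#' @param donor_ann [annotations()] for the donor.
#' @param target target [genome()] searched for empty sites.
#' @param flank_len,min_te_len flank extraction parameters.
#' @param max_gap,min_flank_aln putative-call thresholds.
#' @param confirm_identity,confirm_len confirmation thresholds.
#' @param scoring an [align_scoring()] scheme.
#' @return a `data.frame` of calls (possibly 0 rows) with a `log` attribute
#'   and a `flanks` attribute holding the donor flank table.
#' @export
find_empty_sites <- function(donor, donor_ann, target, flank_len = 5000,
                             min_te_len = 120, max_gap = 20,
                             min_flank_aln = 4500, confirm_identity = 99,
                             confirm_len = 9000, scoring = align_scoring()) {
  fps <- extract_flanks(donor, donor_ann, flank_len = flank_len,
                        min_te_len = min_te_len)
  calls <- list(); log <- character(0)
  for (i in seq_len(nrow(fps))) {
    fp <- fps[i, ]
    call <- call_putative_empty_site(fp, target, max_gap = max_gap,
                                     min_flank_aln = min_flank_aln,
                                     donor_genome = donor$id,
                                     scoring = scoring)
    if (is.null(call) || inherits(call, "no_call")) {
      log <- c(log, paste0(fp$te_copy_id, ": ", attr(call, "reason")))
      next
    }
    call <- confirm_empty_site(call, fp, target,
                               min_identity = confirm_identity,
                               min_len = confirm_len, scoring = scoring)
    calls[[length(calls) + 1L]] <- call
  }
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(te_copy_id = character(0), family_id = character(0),
               donor_genome = character(0), target_genome = character(0),
               target_contig = character(0), strand = character(0),
               junction = integer(0), flank_gap = integer(0),
               left_identity = numeric(0), left_aln = integer(0),
               right_identity = numeric(0), right_aln = integer(0),
               status = character(0), merged_identity = numeric(0),
               merged_len = integer(0), reject_reason = character(0),
               tsd = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "log") <- log
  attr(out, "flanks") <- fps
  out
}

#' Cluster homologous empty-site loci across pairwise comparisons
#'
#' Calls from different genome pairs are grouped when they concern the same
#' donor copy or when their donor left flanks are homologous (reciprocal
#' similarity search). Within a cluster the flanking sequences of a locus
#' cannot be farther apart than `max_locus_span` in any one genome; groupings
#' that would exceed it are split at the largest coordinate gaps.
#'
#' @param calls row-bound output of several [find_empty_sites()] runs.
#' @param flanks row-bound donor flank tables (the `flanks` attributes),
#'   carrying a `genome_id` column or attribute per donor.
#' @param max_locus_span maximum per-genome span in bp (default 70 kb).
#' @param min_link_identity,min_link_len homology-link thresholds for flanks.
#' @return a list of clusters; each cluster is a list with `members` (row
#'   indices into `calls`), `calls` and `span` (per target genome).
#' @export
cluster_homologous_loci <- function(calls, flanks, max_locus_span = 70000,
                                    min_link_identity = 95,
                                    min_link_len = 2000) {
  n <- nrow(calls)
  if (n == 0) stop("no calls to cluster")
  key <- paste(calls$donor_genome, calls$te_copy_id)
  fkey <- paste(if (!is.null(flanks$genome_id)) flanks$genome_id else
    attr(flanks, "genome_id"), flanks$te_copy_id)
  left_of <- setNames(flanks$left_flank, fkey)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  link <- function(i, j) {
    ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <<- ri
  }
  homologous <- function(i, j) {
    qi <- left_of[[key[i]]]; qj <- left_of[[key[j]]]
    if (is.null(qi) || is.null(qj)) return(FALSE)
    h <- local_search(qi, setNames(qj, "flank"),
                      min_identity = min_link_identity,
                      min_length = min_link_len)
    nrow(h) > 0
  }
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    if (key[i] == key[j] || homologous(i, j)) link(i, j)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  clusters <- split(seq_len(n), roots)
  # enforce per-genome span by splitting at the largest junction gaps
  refine <- function(members) {
    spans_ok <- function(ms) {
      for (gme in unique(calls$target_genome[ms])) {
        sel <- ms[calls$target_genome[ms] == gme]
        if (length(unique(calls$target_contig[sel])) > 1) return(FALSE)
        if (diff(range(calls$junction[sel])) > max_locus_span) return(FALSE)
      }
      TRUE
    }
    if (spans_ok(members)) return(list(members))
    ord <- members[order(calls$target_genome[members],
                         calls$target_contig[members],
                         calls$junction[members])]
    # split each offending genome-group at its largest coordinate gap
    out <- list()
    for (piece in split(ord, paste(calls$target_genome[ord],
                                   calls$target_contig[ord]))) {
      while (length(piece) &&
             diff(range(calls$junction[piece])) > max_locus_span) {
        j <- calls$junction[piece]
        cut <- which.max(diff(sort(j)))
        lo <- piece[j <= sort(j)[cut]]
        out[[length(out) + 1L]] <- lo
        piece <- setdiff(piece, lo)
      }
      if (length(piece)) out[[length(out) + 1L]] <- piece
    }
    out
  }
  clusters <- unlist(lapply(clusters, refine), recursive = FALSE)
  lapply(unname(clusters), function(ms) {
    spans <- tapply(calls$junction[ms], calls$target_genome[ms],
                    function(x) diff(range(x)))
    list(members = ms, calls = calls[ms, , drop = FALSE], span = spans)
  })
}

#' Implied maximum insertion size
#'
#' With homologous flanking loci constrained to lie within `max_locus_span`
#' of each other and the confirmed merged flanks occupying `flank_total` bp,
#' an insertion cannot exceed their difference (70,000 - 9,000 = 61,000 bp at
#' the defaults).
#'
#' @param max_locus_span maximum locus span (bp).
#' @param flank_total merged flank length accounted to the locus (bp).
#' @return the implied cap in bp.
#' @export
implied_max_insertion <- function(max_locus_span = 70000, flank_total = 9000) {
  max_locus_span - flank_total
}

#' Detect a target-site duplication at an insertion locus
#'
#' Compares the filled (insertion-bearing) and empty locus sequences. The
#' insertion placement is ambiguous within the longest-common-prefix /
#' longest-common-suffix window; for every consistent placement the longest
#' exact duplication (at most `max_tsd` bp) where the inserted segment ends
#' with a copy of the bases immediately preceding it is enumerated, and the
#' longest one is returned. If distinct placements yield distinct maximal
#' duplications (e.g. a homopolymer junction) the result is flagged
#' ambiguous.
#'
#' @param filled_seq locus sequence carrying the insertion.
#' @param empty_seq homologous locus sequence without it.
#' @param max_tsd maximum duplication length considered (bp).
#' @return `list(tsd=, length=, ambiguous=)` or `NULL` when no duplication is
#'   found (or the sequences do not differ by an insertion).
#' @export
detect_tsd <- function(filled_seq, empty_seq, max_tsd = 20) {
  f <- toupper(filled_seq); e <- toupper(empty_seq)
  L <- nchar(f) - nchar(e)
  if (L <= 0) return(NULL)
  fv <- strsplit(f, "")[[1]]; ev <- strsplit(e, "")[[1]]
  ne <- length(ev)
  p <- 0L
  while (p < ne && fv[p + 1] == ev[p + 1]) p <- p + 1L
  s <- 0L
  while (s < ne - 0L && s < ne && fv[length(fv) - s] == ev[ne - s]) s <- s + 1L
  jmin <- max(0L, ne - s); jmax <- min(p, ne)
  if (jmin > jmax) return(NULL)
  best_k <- 0L; best_tsd <- character(0); n_placements <- 0L
  for (j in jmin:jmax) {
    ins <- substr(f, j + 1L, j + L)
    kmax <- min(max_tsd, j, L)
    for (k in rev(seq_len(kmax))) {
      if (substr(ins, L - k + 1L, L) == substr(f, j - k + 1L, j)) {
        if (k > best_k) {
          best_k <- k; best_tsd <- substr(ins, L - k + 1L, L)
          n_placements <- 1L
        } else if (k == best_k) {
          best_tsd <- union(best_tsd, substr(ins, L - k + 1L, L))
          n_placements <- n_placements + 1L
        }
        break
      }
    }
  }
  if (best_k == 0L) return(NULL)
  list(tsd = best_tsd[1], length = best_k,
       ambiguous = n_placements > 1L || length(best_tsd) > 1L)
}
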