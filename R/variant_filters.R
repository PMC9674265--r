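#' Construct a variant call table
#'
#' One candidate structural variant per row. `caller_ids` holds the
#' contributing caller-module labels as a comma-separated string; duplicates
#' collapse under set semantics wherever callers are counted.
#'
#' @param sample_id,contig,pos,type,length vectors of equal length; `pos` is
#'   0-based; `type` in INS/DEL/INV/TRA.
#' @param ref_support,alt_support read counts for the reference and variant
#'   allele.
#' @param caller_ids comma-separated caller labels.
#' @param seq optional variant sequence.
#' @return a `data.frame` of class `variant_calls`.
#' @export
variant_calls <- function(sample_id, contig, pos, type, length,
                          ref_support = NA_integer_,
                          alt_support = NA_integer_,
                          caller_ids = "caller1", seq = NA_character_) {
  type <- as.character(type)
  if (!all(type %in% c("INS", "DEL", "INV", "TRA")))
    stop("type must be one of INS, DEL, INV, TRA")
  if (any(length < 0, na.rm = TRUE)) stop("length must be >= 0")
  if (any(c(ref_support, alt_support) < 0, na.rm = TRUE))
    stop("support counts must be >= 0")
  if (any(!nzchar(caller_ids))) stop("caller_ids must be non-empty")
  df <- data.frame(sample_id = as.character(sample_id),
                   contig = as.character(contig), pos = as.integer(pos),
                   type = type, length = as.integer(length),
                   ref_support = as.integer(ref_support),
                   alt_support = as.integer(alt_support),
                   caller_ids = as.character(caller_ids),
                   seq = as.character(seq), stringsAsFactors = FALSE)
  class(df) <- c("variant_calls", "data.frame")
  df
}

n_callers <- function(caller_ids) {
  vapply(strsplit(caller_ids, ","), function(x) length(unique(trimws(x))),
         integer(1))
}

#' Minimum variant size filter
#'
#' Retains calls with `length >= min_len`. Translocations (TRA) have no
#' defined length and are always retained.
#'
#' @param calls a [variant_calls()] table.
#' @param min_len minimum variant size in bp (default 50).
#' @return the filtered table.
#' @export
size_filter <- function(calls, min_len = 50) {
  keep <- calls$type == "TRA" | calls$length >= min_len
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify variants as fixed or mosaic from read support
#'
#' A variant is fixed when fewer than `fixed_max_ref` reads carry the
#' reference allele, mosaic otherwise. The mosaic fraction
#' `alt / (alt + ref)` is always computed. Every supported call falls in
#' exactly one of the two states.
#'
#' @param calls a [variant_calls()] table (or any data.frame with
#'   `ref_support` and `alt_support`).
#' @param fixed_max_ref reference reads must be strictly below this for a
#'   fixed call (default 3).
#' @return a `data.frame` with columns `state` and `mosaic_fraction`.
#' @export
classify_fixed_mosaic <- function(calls, fixed_max_ref = 3) {
  ref <- calls$ref_support; alt <- calls$alt_support
  total <- ref + alt
  if (any(is.na(total)) || any(total <= 0))
    stop("every call needs ref_support + alt_support > 0")
  data.frame(state = ifelse(ref < fixed_max_ref, "fixed", "mosaic"),
             mosaic_fraction = alt / total, stringsAsFactors = FALSE)
}

#' Multi-caller consensus filter
#'
#' Retains calls identified by at least `min_callers` distinct caller
#' modules.
#'
#' @param calls a [variant_calls()] table.
#' @param min_callers minimum number of agreeing modules (default 3).
#' @return the filtered table.
#' @export
consensus_filter <- function(calls, min_callers = 3) {
  out <- calls[n_callers(calls$caller_ids) >= min_callers, , drop = FALSE]
  rownames(out) <- NULL
  out
}

call_intervals <- function(calls, breakpoint_slop) {
  w <- ifelse(calls$type == "INS" | calls$type == "TRA",
              1L, pmax(calls$length, 1L))
  start <- calls$pos - ifelse(calls$type %in% c("INS", "TRA"),
                              breakpoint_slop, 0L)
  end <- calls$pos + w + ifelse(calls$type %in% c("INS", "TRA"),
                                breakpoint_slop, 0L)
  list(start = start, end = end)
}

#' Cross-sample uniqueness filter
#'
#' A call survives iff its genomic interval intersects no call interval from
#' any other sample. Overlap is judged against `universe` — by default the
#' input itself, but when the filter is combined with other filters the full
#' unfiltered call set should be passed there, since a call removed by
#' another filter still disqualifies the locus. Insertions and
#' translocations are treated as 1-bp breakpoints padded by
#' `breakpoint_slop` on each side, since breakpoint coordinates jitter
#' between callers.
#'
#' @param calls a [variant_calls()] table spanning several samples.
#' @param breakpoint_slop padding around point breakpoints in bp.
#' @param universe call set overlaps are judged against (default `calls`).
#' @return the filtered table.
#' @export
uniqueness_filter <- function(calls, breakpoint_slop = 100,
                              universe = calls) {
  if (nrow(calls) == 0) return(calls)
  iv <- call_intervals(calls, breakpoint_slop)
  uv <- call_intervals(universe, breakpoint_slop)
  keep <- rep(TRUE, nrow(calls))
  for (ctg in unique(calls$contig)) {
    idx <- which(calls$contig == ctg)
    jdx <- which(universe$contig == ctg)
    if (length(jdx) == 0) next
    ir <- IRanges::IRanges(iv$start[idx] + 1L, iv$end[idx])
    ur <- IRanges::IRanges(uv$start[jdx] + 1L, uv$end[jdx])
    ov <- IRanges::findOverlaps(ir, ur)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    other <- calls$sample_id[idx[qh]] != universe$sample_id[jdx[sh]]
    keep[idx[unique(qh[other])]] <- FALSE
  }
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify the mechanism behind a deletion
#'
#' Uses the TE annotation to decide whether a deletion is a TE excision (the
#' deleted interval matches an annotated copy's boundaries within
#' `tolerance`), a solo-LTR formation (one LTR plus the internal sequence of
#' an LTR element removed, leaving a single LTR; requires `class` and
#' `ltr_len` annotation columns), an inter-copy recombination deletion
#' (bounded by two homologous copies of the same family, spanning roughly
#' one copy plus the intervening sequence; the relative orientation is
#' recorded), or none of these.
#'
#' @param deletion one-row `data.frame`/list with `contig`, `pos`, `length`.
#' @param ann a [annotations()] table, optionally with `class`/`ltr_len`.
#' @param tolerance boundary slop in bp (default 10).
#' @return `list(mechanism=, copy_id=, orientation=)`; `mechanism` is one of
#'   `te_excision`, `solo_ltr`, `inter_copy_nahr`, `other`.
#' @export
classify_deletion_mechanism <- function(deletion, ann, tolerance = 10) {
  dstart <- deletion$pos; dend <- deletion$pos + deletion$length
  a <- ann[ann$contig == deletion$contig, , drop = FALSE]
  near <- function(x, y) abs(x - y) <= tolerance
  # 1. excision: deletion matches one copy's boundaries
  hit <- which(near(a$start, dstart) & near(a$end, dend))
  if (length(hit))
    return(list(mechanism = "te_excision", copy_id = a$copy_id[hit[1]],
                orientation = NA_character_))
  # 2. solo LTR: one LTR + internal removed from an LTR element
  if (!is.null(a$class) && !is.null(a$ltr_len)) {
    ltr <- which(a$class == "LTR" & !is.na(a$ltr_len))
    for (i in ltr) {
      l <- a$ltr_len[i]
      if ((near(dstart, a$start[i]) && near(dend, a$end[i] - l)) ||
          (near(dstart, a$start[i] + l) && near(dend, a$end[i])))
        return(list(mechanism = "solo_ltr", copy_id = a$copy_id[i],
                    orientation = NA_character_))
    }
  }
  # 3. inter-copy recombination: breakpoints inside two homologous copies
  i1 <- which(a$start - tolerance <= dstart & dstart <= a$end + tolerance)
  i2 <- which(a$start - tolerance <= dend & dend <= a$end + tolerance)
  for (i in i1) for (j in i2) {
    if (i != j && a$family_id[i] == a$family_id[j])
      return(list(mechanism = "inter_copy_nahr",
                  copy_id = c(a$copy_id[i], a$copy_id[j]),
                  orientation = if (a$strand[i] == a$strand[j]) "direct"
                  else "head_to_head"))
  }
  list(mechanism = "other", copy_id = NA_character_,
       orientation = NA_character_)
}

#' Write variant calls as TSV
#' @param calls a [variant_calls()] table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_variant_calls <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read variant calls from TSV written by [write_variant_calls()]
#' @param path input file.
#' @return a [variant_calls()] table.
#' @export
read_variant_calls <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  variant_calls(df$sample_id, df$contig, df$pos, df$type, df$length,
                df$ref_support, df$alt_support, df$caller_ids, df$seq)
}

#' Emit variant calls as a minimal VCF
#'
#' Symbolic ALT alleles (`<INS>`, `<DEL>`, `<INV>`, `<TRA>`) with INFO keys
#' SVLEN, SUPPORT_REF, SUPPORT_ALT, CALLERS and STATE.
#'
#' @param calls a [variant_calls()] table.
#' @param path output file.
#' @param fixed_max_ref threshold passed to [classify_fixed_mosaic()].
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, fixed_max_ref = 3) {
  state <- rep(NA_character_, nrow(calls))
  ok <- !is.na(calls$ref_support) & !is.na(calls$alt_support) &
    (calls$ref_support + calls$alt_support) > 0
  if (any(ok)) state[ok] <- classify_fixed_mosaic(calls[ok, , drop = FALSE],
                                                  fixed_max_ref)$state
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Variant length\">",
           "##INFO=<ID=SUPPORT_REF,Number=1,Type=Integer,Description=\"Reference-allele reads\">",
           "##INFO=<ID=SUPPORT_ALT,Number=1,Type=Integer,Description=\"Variant-allele reads\">",
           "##INFO=<ID=CALLERS,Number=.,Type=String,Description=\"Contributing caller modules\">",
           "##INFO=<ID=STATE,Number=1,Type=String,Description=\"fixed or mosaic\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- paste0("SVLEN=", calls$length,
                 ";SUPPORT_REF=", calls$ref_support,
                 ";SUPPORT_ALT=", calls$alt_support,
                 ";CALLERS=", gsub(",", "|", calls$caller_ids),
                 ifelse(is.na(state), "", paste0(";STATE=", state)))
  body <- paste(calls$contig, calls$pos + 1L,
                paste0(calls$sample_id, ".", seq_len(nrow(calls))), "N",
                paste0("<", calls$type, ">"), ".", "PASS", info, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
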