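#' Windowed repeat-density track
#'
#' Slides windows along every contig and reports, per window, the fraction of
#' positions covered by the union of the annotation intervals falling in it.
#' Overlapping annotations are unioned, never summed. The final window on a
#' contig is truncated at the contig end and its fraction uses the truncated
#' span, so fractions stay in [0, 1].
#'
#' @param ann a [annotations()] table.
#' @param g a [genome()].
#' @param window window size in bp (default 50 kb).
#' @param step step between window starts in bp (default 10 kb).
#' @return a `data.frame` of class `density_track` with columns contig, start,
#'   end, fraction, plus `window`/`step` attributes.
#' @export
windowed_density <- function(ann, g, window = 50000, step = 10000) {
  if (window <= 0 || step <= 0) stop("window and step must be positive")
  validate_annotations(ann, g)
  lens <- contig_lengths(g)
  out <- lapply(names(lens), function(ctg) {
    len <- lens[[ctg]]
    starts <- seq.int(0L, max(0L, len - 1L), by = step)
    starts <- starts[starts < len]
    ends <- pmin(starts + window, len)
    a <- ann[ann$contig == ctg, , drop = FALSE]
    cov <- numeric(length(starts))
    if (nrow(a) > 0) {
      ir <- IRanges::reduce(IRanges::IRanges(a$start + 1L, a$end))
      win <- IRanges::IRanges(starts + 1L, ends)
      ov <- IRanges::findOverlaps(win, ir)
      if (length(ov)) {
        w <- IRanges::width(IRanges::pintersect(
          win[S4Vectors::queryHits(ov)], ir[S4Vectors::subjectHits(ov)]))
        cov <- as.numeric(tapply(w, factor(S4Vectors::queryHits(ov),
                                           levels = seq_along(win)), sum))
        cov[is.na(cov)] <- 0
      }
    }
    data.frame(contig = ctg, start = starts, end = ends,
               fraction = cov / (ends - starts), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "window") <- window
  attr(res, "step") <- step
  class(res) <- c("density_track", "data.frame")
  res
}

#' Write a density track as 4-column TSV
#' @param track a [windowed_density()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_density_track <- function(track, path) {
  write.table(track[, c("contig", "start", "end", "fraction")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
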