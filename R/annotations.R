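#' Construct a TE annotation table
#'
#' One row per TE copy with 0-based half-open coordinates. Optional columns
#' (`class`, `ltr_len`, `tsd`) carry structural information used by
#' deletion-mechanism classification and the simulator truth tables.
#'
#' @param contig,start,end,strand,family_id,copy_id vectors of equal length;
#'   `strand` in `+`/`-`; `copy_id` defaults to `family_id.<i>`.
#' @param ... further per-copy columns recycled to length.
#' @return a `data.frame` of class `te_annotations`, sorted by (contig, start).
#' @export
annotations <- function(contig, start, end, strand = "+", family_id,
                        copy_id = NULL, ...) {
  n <- length(contig)
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 0) || any(start >= end))
    stop("annotation intervals must satisfy 0 <= start < end")
  if (any(!nzchar(family_id))) stop("family_id must be non-empty")
  strand <- rep_len(as.character(strand), n)
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  family_id <- rep_len(as.character(family_id), n)
  if (is.null(copy_id)) {
    copy_id <- paste0(family_id, ".", stats::ave(seq_len(n), family_id,
                                                 FUN = seq_along))
  }
  if (anyDuplicated(copy_id)) stop("copy_id must be unique")
  df <- data.frame(contig = as.character(contig), start = start, end = end,
                   strand = strand, family_id = family_id,
                   copy_id = as.character(copy_id),
                   stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- rep_len(extra[[nm]], n)
  df <- df[order(df$contig, df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("te_annotations", "data.frame")
  df
}

#' Validate annotations against a genome
#'
#' @param ann a [annotations()] table.
#' @param g a [genome()].
#' @return `ann`, invisibly; errors if any interval falls outside its contig.
#' @export
validate_annotations <- function(ann, g) {
  lens <- contig_lengths(g)
  missing <- setdiff(ann$contig, names(lens))
  if (length(missing))
    stop("annotation contig(s) not in genome: ", paste(missing, collapse = ", "))
  bad <- ann$end > lens[ann$contig]
  if (any(bad))
    stop("annotation ", ann$copy_id[which(bad)[1]],
         " extends past the end of contig ", ann$contig[which(bad)[1]])
  invisible(ann)
}

#' Read TE annotations from BED or RepeatMasker output
#'
#' Coordinates are normalised to 0-based half-open on read, whatever the
#' dialect: BED6 is taken as-is, RepeatMasker `.out` begin/end columns are
#' treated as 1-based inclusive. Records come back sorted by (contig, start).
#'
#' @param path input file.
#' @param dialect `"bed"` (BED6: contig, start, end, name = family, score,
#'   strand) or `"repeatmasker_out"` (whitespace-delimited `.out` with the
#'   usual header lines, strand `C` meaning minus).
#' @param genome optional [genome()] to validate intervals against.
#' @return a [annotations()] table.
#' @export
read_annotations <- function(path, dialect = c("bed", "repeatmasker_out"),
                             genome = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "bed") {
    df <- read.table(path, header = FALSE, sep = "", comment.char = "#",
                     stringsAsFactors = FALSE)
    if (ncol(df) < 4) stop("BED input needs at least 4 columns (BED6 expected)")
    strand <- if (ncol(df) >= 6) df[[6]] else "+"
    strand[!strand %in% c("+", "-")] <- "+"
    ann <- annotations(contig = df[[1]], start = df[[2]], end = df[[3]],
                       strand = strand, family_id = df[[4]])
  } else {
    lines <- readLines(path, warn = FALSE)
    # data lines start with a numeric alignment score
    keep <- grepl("^\\s*\\d", lines)
    if (!any(keep)) stop("no data lines in RepeatMasker file: ", path)
    fields <- strsplit(trimws(lines[keep]), "\\s+")
    nf <- vapply(fields, length, integer(1))
    if (any(nf < 11)) stop("malformed RepeatMasker line: fewer than 11 fields")
    getf <- function(i) vapply(fields, `[[`, character(1), i)
    strand <- getf(9)
    strand <- ifelse(strand == "C", "-", "+")
    copy_id <- if (all(nf >= 15)) getf(15) else NULL
    if (!is.null(copy_id) && anyDuplicated(copy_id)) copy_id <- NULL
    ann <- annotations(contig = getf(5),
                       start = as.integer(getf(6)) - 1L,
                       end = as.integer(getf(7)),
                       strand = strand, family_id = getf(10),
                       copy_id = copy_id)
  }
  if (!is.null(genome)) validate_annotations(ann, genome)
  ann
}

#' Write annotations as BED6
#'
#' The BED dialect is already 0-based half-open, so `read_annotations()` on
#' the written file round-trips coordinates exactly.
#'
#' @param ann a [annotations()] table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(ann, path) {
  out <- data.frame(ann$contig, ann$start, ann$end, ann$family_id, 0L,
                    ann$strand)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
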