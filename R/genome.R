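#' Construct a genome object
#'
#' A genome is an ordered set of named contig sequences plus a sample or
#' assembly label. Sequences are upper-cased and restricted to the alphabet
#' A, C, G, T, N; internal coordinates throughout the package are 0-based
#' half-open.
#'
#' @param contigs named character vector of DNA sequences.
#' @param id sample/assembly label.
#' @return an object of class `genome`.
#' @export
genome <- function(contigs, id = "genome") {
  if (length(contigs) == 0) stop("genome must contain at least one contig")
  if (is.null(names(contigs)) || any(!nzchar(names(contigs))))
    stop("all contigs must be named")
  if (anyDuplicated(names(contigs)))
    stop("contig names must be unique")
  nms <- names(contigs)
  contigs <- setNames(toupper(as.character(contigs)), nms)
  if (any(nchar(contigs) == 0)) stop("contigs must be non-empty")
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad))
    stop("contig '", nms[which(bad)[1]],
         "' contains characters outside A,C,G,T,N")
  structure(list(id = id, contigs = contigs), class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat("<genome> ", x$id, ": ", length(x$contigs), " contig(s), ",
      format(sum(nchar(x$contigs)), big.mark = ","), " bp total\n", sep = "")
  invisible(x)
}

#' Contig lengths of a genome
#' @param g a `genome`.
#' @return named integer vector.
#' @export
contig_lengths <- function(g) {
  stopifnot(inherits(g, "genome"))
  setNames(nchar(g$contigs), names(g$contigs))
}

#' Read a FASTA file into a genome
#'
#' @param path FASTA file (wrapped or unwrapped, multi-record).
#' @param id label for the resulting genome; defaults to the file name.
#' @return a [genome()].
#' @export
read_fasta <- function(path, id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0) stop("empty FASTA file: ", path)
  if (!startsWith(trimws(lines[nonempty[1]]), ">"))
    stop("malformed FASTA: line ", nonempty[1], " of ", path,
         " is not a header")
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (length(seqs) == 0) stop("no sequences in FASTA file: ", path)
  contigs <- as.character(seqs)
  # keep only the first whitespace-delimited token of each header
  names(contigs) <- sub("\\s.*$", "", names(seqs))
  genome(contigs, id = if (is.null(id)) basename(path) else id)
}

#' Write a genome to FASTA
#'
#' `read_fasta(write_fasta(g, path))` preserves contig names and sequences
#' exactly.
#'
#' @param g a [genome()].
#' @param path output file.
#' @param width line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(g, path, width = 70) {
  stopifnot(inherits(g, "genome"))
  ss <- Biostrings::DNAStringSet(g$contigs)
  names(ss) <- names(g$contigs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Reverse complement of DNA strings
#' @param x character vector of DNA sequences (A,C,G,T,N).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# 0-based half-open substring of a contig sequence
subseq0 <- function(seq, start, end) {
  substr(seq, start + 1L, end)
}
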