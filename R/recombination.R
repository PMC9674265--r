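#' Construct a haploid genotype matrix
#'
#' Biallelic sites by samples, haploid calls coded 0/1 with NA for missing.
#' Samples carry a nucleotype group label (e.g. "A"/"B"). Sites are sorted by
#' (contig, pos).
#'
#' @param sites `data.frame` with `contig` and `pos` (one row per site).
#' @param geno integer matrix, sites x samples, values 0/1/NA; column names
#'   are sample ids.
#' @param groups named character vector mapping every sample id to its group.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, geno, groups) {
  geno <- as.matrix(geno)
  if (nrow(sites) != nrow(geno)) stop("sites and geno row counts differ")
  if (is.null(colnames(geno))) stop("geno needs sample ids as column names")
  if (!all(colnames(geno) %in% names(groups)))
    stop("every sample needs a group label")
  if (!all(geno %in% c(0L, 1L, NA)))
    stop("genotypes must be 0, 1 or NA (biallelic haploid calls)")
  ord <- order(sites$contig, sites$pos)
  structure(list(sites = sites[ord, , drop = FALSE],
                 geno = geno[ord, , drop = FALSE],
                 groups = groups[colnames(geno)]),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$geno), " sites x ", ncol(x$geno),
      " samples (groups: ", paste(sort(unique(x$groups)), collapse = "/"),
      ")\n", sep = "")
  invisible(x)
}

#' Per-site consensus allele of a nucleotype group
#'
#' Majority allele among the non-missing calls of the group's samples at each
#' site; ties and all-missing sites give NA.
#'
#' @param gm a [genotype_matrix()].
#' @param group group label.
#' @param exclude optional sample id left out of the consensus (used when
#'   comparing a focal sample to its own group).
#' @return integer vector (0/1/NA) over sites.
#' @export
group_consensus <- function(gm, group, exclude = NULL) {
  members <- names(gm$groups)[gm$groups == group]
  members <- setdiff(members, exclude)
  if (length(members) == 0) stop("no samples in group '", group, "'")
  sub <- gm$geno[, members, drop = FALSE]
  ones <- rowSums(sub == 1L, na.rm = TRUE)
  zeros <- rowSums(sub == 0L, na.rm = TRUE)
  out <- ifelse(ones > zeros, 1L, ifelse(zeros > ones, 0L, NA_integer_))
  out[ones + zeros == 0] <- NA_integer_
  as.integer(out)
}

#' Scan one sample for candidate mitotic recombination tracts
#'
#' A site is discordant when the focal sample's genotype differs from its own
#' group's consensus and equals the other group's consensus (all three calls
#' non-missing; the focal sample is excluded from its own group's consensus).
#' Maximal runs of at least `min_run` consecutive discordant sites within a
#' contig are reported; missing genotypes break runs. "Consecutive" means
#' adjacency in the sorted site list, not base-pair distance.
#'
#' @param gm a [genotype_matrix()] with exactly two groups.
#' @param focal_sample sample id to scan.
#' @param min_run minimum run length in sites (default 2).
#' @return a `data.frame` of tracts: `sample_id`, `contig`, `first_site`,
#'   `last_site` (positions), `n_sites`.
#' @export
find_discordant_runs <- function(gm, focal_sample, min_run = 2) {
  if (!focal_sample %in% names(gm$groups))
    stop("unknown sample: ", focal_sample)
  own <- gm$groups[[focal_sample]]
  other <- setdiff(unique(gm$groups), own)
  if (length(other) != 1) stop("exactly two groups are required")
  cons_own <- group_consensus(gm, own, exclude = focal_sample)
  cons_other <- group_consensus(gm, other)
  focal <- gm$geno[, focal_sample]
  disc <- !is.na(focal) & !is.na(cons_own) & !is.na(cons_other) &
    focal != cons_own & focal == cons_other
  tracts <- list()
  for (ctg in unique(gm$sites$contig)) {
    idx <- which(gm$sites$contig == ctg)
    r <- rle(disc[idx])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values & r$lengths >= min_run)
    for (k in runs) {
      sel <- idx[starts[k]:ends[k]]
      tracts[[length(tracts) + 1L]] <-
        data.frame(sample_id = focal_sample, contig = ctg,
                   first_site = gm$sites$pos[sel[1]],
                   last_site = gm$sites$pos[sel[length(sel)]],
                   n_sites = length(sel), stringsAsFactors = FALSE)
    }
  }
  if (length(tracts) == 0)
    return(data.frame(sample_id = character(0), contig = character(0),
                      first_site = integer(0), last_site = integer(0),
                      n_sites = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, tracts)
}

#' Nucleotide diversity (pi)
#'
#' Average number of pairwise differences per callable site across all sample
#' pairs. For a character vector of equal-length haplotype sequences the
#' callable length defaults to the sequence length; for a genotype matrix (or
#' 0/1/NA site-by-sample matrix) the total callable length must be supplied,
#' since the matrix only holds the variant sites.
#'
#' @param x character vector of >= 2 haplotype sequences, a
#'   [genotype_matrix()], or a site-by-sample 0/1/NA matrix.
#' @param callable_length callable genome length in bp.
#' @return pi per site (numeric scalar).
#' @export
nucleotide_diversity <- function(x, callable_length = NULL) {
  if (inherits(x, "genotype_matrix")) x <- x$geno
  if (is.character(x)) {
    if (length(x) < 2) stop("need at least two haplotypes")
    if (length(unique(nchar(x))) != 1) stop("haplotypes must have equal length")
    if (is.null(callable_length)) callable_length <- nchar(x[1])
    mats <- lapply(x, function(s) strsplit(toupper(s), "")[[1]])
    pairs <- utils::combn(length(x), 2)
    diffs <- apply(pairs, 2, function(p) sum(mats[[p[1]]] != mats[[p[2]]]))
  } else {
    x <- as.matrix(x)
    if (ncol(x) < 2) stop("need at least two samples")
    if (is.null(callable_length))
      stop("callable_length is required for a genotype matrix")
    pairs <- utils::combn(ncol(x), 2)
    diffs <- apply(pairs, 2, function(p) {
      ok <- !is.na(x[, p[1]]) & !is.na(x[, p[2]])
      sum(x[ok, p[1]] != x[ok, p[2]])
    })
  }
  if (callable_length <= 0) stop("callable_length must be positive")
  mean(diffs) / callable_length
}

#' Write recombination tracts as TSV
#' @param tracts output of [find_discordant_runs()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tracts <- function(tracts, path) {
  write.table(tracts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
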