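#' Filter per-read methylation call records
#'
#' Keeps records whose read passes all three mapping filters: mapping quality
#' of at least `min_mapq`, primary alignment, and an uninterrupted aligned
#' reference span of at least `min_span` (6 kb by default). The filter is
#' idempotent and its output is a subset of its input.
#'
#' @param records `data.frame` with columns `read_id`, `contig`, `pos`,
#'   `methylated` (0/1), `mapq`, `primary` (0/1 or logical), `span`.
#' @param min_mapq minimum mapping quality (default 60).
#' @param require_primary drop secondary/supplementary alignments.
#' @param min_span minimum aligned reference span in bp (default 6,000).
#' @return the filtered records.
#' @export
filter_reads <- function(records, min_mapq = 60, require_primary = TRUE,
                         min_span = 6000) {
  keep <- records$mapq >= min_mapq & records$span >= min_span
  if (require_primary) keep <- keep & as.logical(records$primary)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-CpG methylation frequencies
#'
#' Tallies filtered per-read calls into one record per CpG site with at least
#' one call: methylated and total call counts and their ratio. Invariant to
#' record order.
#'
#' @param records (filtered) per-read call records.
#' @return `data.frame` with `contig`, `pos`, `methylated_calls`,
#'   `total_calls`, `frequency`, sorted by (contig, pos).
#' @export
site_frequencies <- function(records) {
  if (nrow(records) == 0)
    return(data.frame(contig = character(0), pos = integer(0),
                      methylated_calls = integer(0), total_calls = integer(0),
                      frequency = numeric(0), stringsAsFactors = FALSE))
  key <- paste(records$contig, records$pos, sep = "\r")
  meth <- tapply(as.integer(records$methylated), key, sum)
  tot <- tapply(rep(1L, nrow(records)), key, sum)
  parts <- strsplit(names(meth), "\r", fixed = TRUE)
  out <- data.frame(contig = vapply(parts, `[[`, character(1), 1),
                    pos = as.integer(vapply(parts, `[[`, character(1), 2)),
                    methylated_calls = as.integer(meth),
                    total_calls = as.integer(tot),
                    frequency = as.numeric(meth / tot),
                    stringsAsFactors = FALSE)
  out <- out[order(out$contig, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Label CpG sites by repeat overlap
#'
#' @param sites a [site_frequencies()] table.
#' @param repeats a [annotations()] table (or BED-derived intervals).
#' @return `sites` with a logical `in_repeat` column.
#' @export
label_repeat_sites <- function(sites, repeats) {
  sites$in_repeat <- rep(FALSE, nrow(sites))
  for (ctg in unique(sites$contig)) {
    r <- repeats[repeats$contig == ctg, , drop = FALSE]
    if (nrow(r) == 0) next
    idx <- which(sites$contig == ctg)
    ir <- IRanges::IRanges(r$start + 1L, r$end)
    pt <- IRanges::IRanges(sites$pos[idx] + 1L, sites$pos[idx] + 1L)
    sites$in_repeat[idx] <- IRanges::overlapsAny(pt, ir)
  }
  sites
}

#' Compare methylation between repeat and non-repeat CpG sites
#'
#' Labels sites by repeat overlap, then downsamples the site count before a
#' two-sided rank-sum (Wilcoxon) test. The default (`mode = "reduce"`)
#' performs one balanced test on `n_sites / n_downsample` sites per class: a
#' single n-fold reduction keeps the test's type-I error at its nominal
#' level. `mode = "replicate"` instead draws `n_downsample` balanced
#' subsamples and reports the median statistic and p-value across them; that
#' summary is deliberately stability-oriented and conservative (the median
#' of correlated p-values is pulled toward 0.5), so it should not be read as
#' a calibrated p-value. Class means are always computed on all sites.
#'
#' @param sites a [site_frequencies()] table.
#' @param repeats a [annotations()] table marking repeat intervals.
#' @param n_downsample reduction factor (default 500) under `"reduce"`, or
#'   the number of subsample replicates under `"replicate"`.
#' @param downsample_size per-class subsample size for `"replicate"` mode;
#'   defaults to the smaller class size (capped at 5,000).
#' @param seed integer seed controlling the subsampling.
#' @param mode `"reduce"` (default) or `"replicate"`.
#' @return `list(mean_repeat=, mean_nonrepeat=, statistic=, p_value=,
#'   n_repeat=, n_nonrepeat=, n_downsample=, mode=)`.
#' @export
compare_repeat_vs_nonrepeat <- function(sites, repeats, n_downsample = 500,
                                        downsample_size = NULL, seed = 1,
                                        mode = c("reduce", "replicate")) {
  mode <- match.arg(mode)
  sites <- label_repeat_sites(sites, repeats)
  rep_f <- sites$frequency[sites$in_repeat]
  non_f <- sites$frequency[!sites$in_repeat]
  if (length(rep_f) == 0 || length(non_f) == 0)
    stop("both repeat and non-repeat site classes must be non-empty")
  set.seed(seed)
  if (mode == "reduce") {
    m <- max(2L, floor(min(length(rep_f), length(non_f)) / n_downsample))
    wt <- wilcox.test(sample(rep_f, m), sample(non_f, m), exact = FALSE)
    stat <- unname(wt$statistic); pval <- wt$p.value
    reps <- 1L
  } else {
    if (is.null(downsample_size))
      downsample_size <- min(length(rep_f), length(non_f), 5000L)
    res <- vapply(seq_len(n_downsample), function(i) {
      wt <- wilcox.test(sample(rep_f, downsample_size),
                        sample(non_f, downsample_size), exact = FALSE)
      c(unname(wt$statistic), wt$p.value)
    }, numeric(2))
    stat <- median(res[1, ]); pval <- median(res[2, ])
    reps <- n_downsample
  }
  list(mean_repeat = mean(rep_f), mean_nonrepeat = mean(non_f),
       statistic = stat, p_value = pval,
       n_repeat = length(rep_f), n_nonrepeat = length(non_f),
       n_downsample = reps, mode = mode)
}

#' Mean methylation frequency per TE copy
#'
#' @param sites a [site_frequencies()] table.
#' @param copies a [annotations()] table of TE copy intervals.
#' @return `data.frame` per copy with `mean_frequency` and `n_sites`; copies
#'   without CpG sites get NA and reason "no_cpg_sites".
#' @export
te_copy_methylation <- function(sites, copies) {
  rows <- lapply(seq_len(nrow(copies)), function(i) {
    sel <- sites$contig == copies$contig[i] &
      sites$pos >= copies$start[i] & sites$pos < copies$end[i]
    n <- sum(sel)
    data.frame(copy_id = copies$copy_id[i], family_id = copies$family_id[i],
               mean_frequency = if (n > 0) mean(sites$frequency[sel]) else NA_real_,
               n_sites = n,
               reason = if (n > 0) NA_character_ else "no_cpg_sites",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read per-read methylation calls from TSV
#'
#' Expected columns: read_id, contig, pos, methylated (0/1), mapq,
#' primary (0/1), span — the summary format emitted by methylation callers.
#'
#' @param path input TSV (with header).
#' @return a `data.frame` of records for [filter_reads()].
#' @export
read_methylation_calls <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
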