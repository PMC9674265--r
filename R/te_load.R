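#' Depth normalization factor
#'
#' Factor that rescales a sample's depth to the target single-copy coverage
#' (default 35x, emulating read subsampling). Capped at 1: samples below the
#' target are never upsampled, with a warning.
#'
#' @param observed_single_copy_median observed median depth over single-copy
#'   regions.
#' @param target target coverage (default 35).
#' @return the multiplicative factor.
#' @export
normalization_factor <- function(observed_single_copy_median, target = 35) {
  if (is.na(observed_single_copy_median) || observed_single_copy_median <= 0)
    stop("observed single-copy median must be positive")
  f <- target / observed_single_copy_median
  if (f > 1) {
    warning("observed coverage ", observed_single_copy_median,
            " below target ", target, "; factor capped at 1 (no upsampling)")
    f <- 1
  }
  f
}

#' Family presence call and median depth
#'
#' Breadth is the fraction of consensus positions covered at or above
#' `min_depth`. Families with breadth below `min_breadth` are coded absent
#' (median 0), guarding against partial mapping such as solo LTRs; otherwise
#' the median over all consensus positions is returned.
#'
#' @param depth_vector per-position depth over the family consensus.
#' @param min_depth depth floor for horizontal coverage (default 15).
#' @param min_breadth required covered fraction (default 0.90).
#' @return the median depth, or 0 when the family is called absent.
#' @export
family_presence_median <- function(depth_vector, min_depth = 15,
                                   min_breadth = 0.90) {
  if (length(depth_vector) == 0) stop("empty depth vector")
  breadth <- mean(depth_vector >= min_depth)
  if (breadth < min_breadth) return(0)
  median(depth_vector)
}

#' Coefficient of variation of per-sample medians
#'
#' CV = sample standard deviation (n-1) / mean. Undefined (NA with a reason
#' attribute) when the mean is zero.
#'
#' @param medians per-sample median depths for one family (length >= 2).
#' @return the CV, or NA.
#' @export
cv_across_samples <- function(medians) {
  if (length(medians) < 2) stop("need medians from at least two samples")
  m <- mean(medians)
  if (m == 0) return(structure(NA_real_, reason = "all medians zero"))
  sd(medians) / m
}

#' Flag families with CV above the third quartile
#'
#' Q3 uses linear interpolation (quantile type 7); the flag is strict
#' (`cv > Q3`), so with all-equal CVs nothing is flagged.
#'
#' @param cvs named numeric vector of per-family CVs (length >= 4).
#' @return named logical vector.
#' @export
quartile_rank <- function(cvs) {
  ok <- !is.na(cvs)
  if (sum(ok) < 4) stop("need CVs for at least four families")
  q3 <- quantile(cvs[ok], 0.75, type = 7, names = FALSE)
  out <- cvs > q3
  out[!ok] <- NA
  out
}

#' Build a TE family load table across samples
#'
#' For every sample, depth vectors are rescaled by the sample's
#' [normalization_factor()] and each family gets a presence call and median
#' depth via [family_presence_median()]; per family, the coefficient of
#' variation of medians across samples and the above-Q3 flag are added.
#'
#' @param profiles list of depth profiles; each is a list with `sample_id`,
#'   `family_depths` (named list of depth vectors) and
#'   `observed_single_copy_median`.
#' @param target target coverage for normalization (default 35).
#' @param min_depth,min_breadth presence-call parameters.
#' @return `list(samples=, families=)`: a long `data.frame` of per-(sample,
#'   family) medians and presence flags, and a per-family `data.frame` with
#'   `cv` and `above_q3`.
#' @export
te_load_table <- function(profiles, target = 35, min_depth = 15,
                          min_breadth = 0.90) {
  rows <- list()
  for (p in profiles) {
    f <- normalization_factor(p$observed_single_copy_median, target)
    for (fam in names(p$family_depths)) {
      med <- family_presence_median(p$family_depths[[fam]] * f,
                                    min_depth = min_depth,
                                    min_breadth = min_breadth)
      rows[[length(rows) + 1L]] <-
        data.frame(sample_id = p$sample_id, family_id = fam,
                   present = med > 0, median_depth = med,
                   stringsAsFactors = FALSE)
    }
  }
  samples <- do.call(rbind, rows)
  cvs <- vapply(split(samples$median_depth, samples$family_id),
                function(x) as.numeric(cv_across_samples(x)), numeric(1))
  families <- data.frame(family_id = names(cvs), cv = unname(cvs),
                         stringsAsFactors = FALSE)
  families$above_q3 <- if (sum(!is.na(cvs)) >= 4) unname(quartile_rank(cvs))
    else rep(NA, length(cvs))
  list(samples = samples, families = families)
}

#' Read per-family depth profiles from TSV
#'
#' Long format: columns `family`, `position`, `depth` (header optional but
#' expected). Positions must tile each family consensus contiguously.
#'
#' @param path input TSV.
#' @param sample_id sample label.
#' @param observed_single_copy_median the sample's single-copy median depth.
#' @return a profile list usable with [te_load_table()].
#' @export
read_depth_profile <- function(path, sample_id,
                               observed_single_copy_median) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  fams <- split(df, df$family)
  depths <- lapply(fams, function(d) d$depth[order(d$position)])
  list(sample_id = sample_id, family_depths = depths,
       observed_single_copy_median = observed_single_copy_median)
}
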