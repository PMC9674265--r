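mkcalls <- function(...) variant_calls(...)

test_that("size filter keeps 50 bp and larger, and always keeps TRA", {
  calls <- mkcalls("s1", "c1", c(10, 20, 30, 40), c("DEL", "INS", "DEL", "TRA"),
                   c(49, 50, 51, 0))
  out <- size_filter(calls)
  expect_equal(out$length, c(50L, 51L, 0L))
  expect_equal(nrow(size_filter(calls[0, ])), 0L)
  all_big <- mkcalls("s1", "c1", 1:3, "DEL", c(60, 70, 80))
  expect_equal(size_filter(all_big), all_big)
})

test_that("fixed/mosaic classification partitions at fewer-than-three reference reads", {
  calls <- mkcalls("s1", "c1", 1:4, "INS", 100,
                   ref_support = c(2, 3, 0, 10), alt_support = c(30, 30, 10, 30))
  st <- classify_fixed_mosaic(calls)
  expect_equal(st$state, c("fixed", "mosaic", "fixed", "mosaic"))
  expect_equal(st$mosaic_fraction, c(30 / 32, 30 / 33, 1, 0.75))
  # every supported call gets exactly one state
  expect_true(all(st$state %in% c("fixed", "mosaic")))
  zero <- mkcalls("s1", "c1", 1, "INS", 100, ref_support = 0, alt_support = 0)
  expect_error(classify_fixed_mosaic(zero), "> 0")
})

test_that("caller consensus requires three distinct modules", {
  calls <- mkcalls("s1", "c1", 1:4, "INS", 100,
                   caller_ids = c("a,b", "a,b,c", "a,a,b,a", "a,b,c,d"))
  out <- consensus_filter(calls)
  expect_equal(out$caller_ids, c("a,b,c", "a,b,c,d"))   # duplicates collapse
  singletons <- mkcalls("s1", "c1", 1:3, "INS", 100, caller_ids = "only")
  expect_equal(nrow(consensus_filter(singletons)), 0L)
})

test_that("cross-sample uniqueness drops every overlapping call", {
  calls <- mkcalls(c("s1", "s2", "s3"), "c1", c(500, 500, 5000), "INS", 100)
  out <- uniqueness_filter(calls)
  expect_equal(out$sample_id, "s3")

  disjoint <- mkcalls(c("s1", "s2", "s3"), "c1", c(1000, 5000, 9000),
                      "DEL", 200)
  expect_equal(nrow(uniqueness_filter(disjoint)), 3L)

  # brute-force all-pairs interval check on a random call set
  set.seed(61)
  n <- 40
  rc <- mkcalls(sample(paste0("s", 1:4), n, TRUE), "c1",
                sample(seq(0, 50000, by = 10), n),
                sample(c("INS", "DEL"), n, TRUE), sample(60:500, n))
  out2 <- uniqueness_filter(rc, breakpoint_slop = 100)
  iv <- karyoscan:::call_intervals(rc, 100)
  keep <- vapply(seq_len(n), function(i) {
    !any(vapply(seq_len(n), function(j) {
      j != i && rc$sample_id[j] != rc$sample_id[i] &&
        iv$start[j] < iv$end[i] && iv$end[j] > iv$start[i]
    }, logical(1)))
  }, logical(1))
  expect_equal(nrow(out2), sum(keep))
})

test_that("the three filters are idempotent and order-commutative", {
  set.seed(62)
  n <- 30
  calls <- mkcalls(sample(paste0("s", 1:3), n, TRUE), "c1",
                   sample(seq(0, 30000, by = 7), n),
                   sample(c("INS", "DEL", "INV"), n, TRUE),
                   sample(20:300, n),
                   caller_ids = vapply(seq_len(n), function(i)
                     paste(sample(letters[1:5], sample(1:5, 1)),
                           collapse = ","), character(1)))
  f1 <- function(x) size_filter(x)
  f2 <- function(x) consensus_filter(x)
  # overlap judged against the full call set, so the filters commute
  f3 <- function(x) uniqueness_filter(x, universe = calls)
  a <- f3(f2(f1(calls)))
  expect_equal(f1(a), a)
  expect_equal(f2(a), a)
  expect_equal(f3(a), a)
  b <- f1(f3(f2(calls)))
  c_ <- f2(f1(f3(calls)))
  expect_equal(a[order(a$pos), ], b[order(b$pos), ], ignore_attr = TRUE)
  expect_equal(a[order(a$pos), ], c_[order(c_$pos), ], ignore_attr = TRUE)
})

test_that("deletion mechanisms are classified from the annotation context", {
  ann <- annotations(contig = rep("c1", 4),
                     start = c(1000, 5000, 20000, 24900),
                     end = c(1600, 7400, 22400, 27300),
                     family_id = c("hAT", "LTR1", "LTR1", "LTR1"),
                     copy_id = c("hAT.1", "LTR1.1", "LTR1.2", "LTR1.3"),
                     class = c("DNA_TIR", "LTR", "LTR", "LTR"),
                     ltr_len = c(NA, 250, 250, 250))
  # deletion matching the hAT copy within +-10 bp
  exc <- classify_deletion_mechanism(list(contig = "c1", pos = 1005,
                                          length = 590), ann)
  expect_equal(exc$mechanism, "te_excision")
  expect_equal(exc$copy_id, "hAT.1")
  # internal + one LTR removed -> solo LTR
  solo <- classify_deletion_mechanism(list(contig = "c1", pos = 5000,
                                           length = 2400 - 250), ann)
  expect_equal(solo$mechanism, "solo_ltr")
  # breakpoints inside two homologous copies -> inter-copy recombination
  nahr <- classify_deletion_mechanism(list(contig = "c1", pos = 20005,
                                           length = 24905 - 20005), ann)
  expect_equal(nahr$mechanism, "inter_copy_nahr")
  expect_equal(nahr$orientation, "direct")
  # a 70 bp deletion in unique sequence
  oth <- classify_deletion_mechanism(list(contig = "c1", pos = 40000,
                                          length = 70), ann)
  expect_equal(oth$mechanism, "other")
})

test_that("variant tables round-trip through TSV and emit minimal VCF", {
  calls <- mkcalls(c("s1", "s1"), "c1", c(100, 300), c("INS", "DEL"),
                   c(120, 80), ref_support = c(1, 10), alt_support = c(30, 5),
                   caller_ids = c("a,b,c", "a"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variant_calls(calls, path)
  back <- read_variant_calls(path)
  expect_equal(back$pos, calls$pos)
  expect_equal(back$caller_ids, calls$caller_ids)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(calls, vcf)
  lines <- readLines(vcf)
  expect_match(lines[length(lines)], "SVLEN=80.*STATE=mosaic")
  expect_match(lines[length(lines) - 1], "<INS>.*STATE=fixed")
})
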