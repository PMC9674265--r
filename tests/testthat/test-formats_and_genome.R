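test_that("FASTA round-trips preserve names and sequences exactly", {
  set.seed(11)
  g <- genome(c(chrA = random_dna(500), chrB = random_dna(1200),
                chrC = random_dna(77)), id = "g1")
  path <- withr::local_tempfile(fileext = ".fa")
  write_fasta(g, path)
  g2 <- read_fasta(path, id = "g1")
  expect_identical(g2$contigs, g$contigs)

  # two-record file parsed directly
  path2 <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a desc ignored", "ACGT", "ACG", ">b", "GGGTTT"), path2)
  g3 <- read_fasta(path2)
  expect_equal(unname(nchar(g3$contigs)), c(7L, 6L))
  expect_equal(names(g3$contigs), c("a", "b"))
})

test_that("malformed or empty FASTA input raises parse errors", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), path)
  expect_error(read_fasta(path), "empty")
  writeLines(c("ACGT", ">a"), path)
  expect_error(read_fasta(path), "line 1")
  expect_error(read_fasta(file.path(tempdir(), "nope.fa")), "not found")
})

test_that("genome objects enforce alphabet, names and non-emptiness", {
  expect_error(genome(c(a = "ACGU")), "outside")
  expect_error(genome(c("ACGT")), "named")
  expect_error(genome(c(a = "ACGT", a = "ACGT")), "unique")
  expect_error(genome(c(a = "")), "non-empty")
  g <- genome(c(a = "acgtn"))
  expect_identical(unname(g$contigs), "ACGTN")
})

test_that("annotation dialects normalise to 0-based half-open coordinates", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t600\tfamX\t.\t+", bed)
  a <- read_annotations(bed, "bed")
  expect_equal(a$start, 100L)
  expect_equal(a$end, 600L)
  expect_equal(a$family_id, "famX")

  rm <- withr::local_tempfile(fileext = ".out")
  writeLines(c(
    "   SW   perc perc perc  query     position in query    matching repeat",
    "score   div. del. ins.  sequence  begin end   (left)   repeat class/family begin end (left) ID",
    "",
    "  239   12.5  0.0  0.0  chr1       101   600  (4000) +  famX  DNA/hAT  1  500  (0)  1"),
    rm)
  b <- read_annotations(rm, "repeatmasker_out")
  expect_equal(b$start, 100L)   # 1-based inclusive 101..600
  expect_equal(b$end, 600L)

  # out-of-order input comes back sorted; bed -> internal -> bed is lossless
  bed2 <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr2\t50\t200\tf\t.\t-", "chr1\t700\t900\tf\t.\t+",
               "chr1\t10\t40\tg\t.\t+"), bed2)
  ann <- read_annotations(bed2, "bed")
  expect_true(!is.unsorted(order(ann$contig, ann$start)))
  out <- withr::local_tempfile(fileext = ".bed")
  write_bed(ann, out)
  ann2 <- read_annotations(out, "bed")
  expect_equal(ann2$start, ann$start)
  expect_equal(ann2$end, ann$end)
  expect_equal(ann2$strand, ann$strand)
})

test_that("annotations are validated against contig bounds", {
  g <- genome(c(c1 = strrep("A", 100)))
  expect_error(validate_annotations(
    annotations("c1", 50, 150, family_id = "f"), g), "past the end")
  expect_error(annotations("c1", 5, 5, family_id = "f"), "start < end")
})

test_that("windowed density equals per-base counting and respects bounds", {
  set.seed(21)
  g <- genome(c(c1 = random_dna(90000), c2 = random_dna(30000)))
  # no annotations -> all zero (empty annotation set via a dummy off-contig)
  ann0 <- annotations("c1", 0, 10, family_id = "f")
  d0 <- windowed_density(ann0[0, ], g, window = 50000, step = 10000)
  expect_true(all(d0$fraction == 0))
  # a single annotation covering a full window -> fraction 1 there
  ann1 <- annotations("c1", 10000, 60000, family_id = "f")
  d1 <- windowed_density(ann1, g, window = 10000, step = 10000)
  expect_equal(d1$fraction[d1$contig == "c1" & d1$start == 20000], 1)
  # overlapping annotations are unioned, not summed
  ann2 <- annotations(c("c1", "c1"), c(1000, 3000), c(5000, 7000),
                      family_id = "f")
  d2 <- windowed_density(ann2, g, window = 10000, step = 10000)
  expect_equal(d2$fraction[d2$contig == "c1" & d2$start == 0], 6000 / 10000)
  # random instance matches the brute-force oracle
  set.seed(22)
  n <- 40
  st <- sample(0:85000, n)
  ann3 <- annotations(sample(c("c1", "c2"), n, replace = TRUE,
                             prob = c(.7, .3)),
                      pmin(st, 25000), pmin(st, 25000) + sample(200:4000, n),
                      family_id = "f")
  d3 <- windowed_density(ann3, g, window = 7000, step = 3000)
  b3 <- brute_density(ann3, g, window = 7000, step = 3000)
  expect_equal(d3$fraction, b3$fraction, tolerance = 1e-12)
  expect_error(windowed_density(ann1, g, window = 0), "positive")
  expect_error(windowed_density(ann1, g, step = -1), "positive")
})

test_that("contig end-overlap merge collapses true overlaps and gaps the rest", {
  set.seed(31)
  a <- random_dna(6000)
  b <- paste0(substr(a, 4001, 6000), random_dna(5000))   # 2 kb true overlap
  m <- merge_contigs_by_end_overlap(a, b)
  expect_false(m$report$gapped)
  expect_equal(nchar(m$sequence), 6000 + 7000 - 2000)
  expect_false(grepl("N", m$sequence))

  # unrelated contigs: join with a gap of exactly 100 N
  u <- merge_contigs_by_end_overlap(random_dna(4000), random_dna(3000))
  expect_true(u$report$gapped)
  expect_equal(nchar(u$sequence), 4000 + 3000 + 100)
  runs <- regmatches(u$sequence, gregexpr("N+", u$sequence))[[1]]
  expect_equal(runs, strrep("N", 100))

  # a contig merged with itself: full-span self-identity is rejected
  s <- random_dna(3000)
  self <- merge_contigs_by_end_overlap(s, s)
  expect_true(self$report$gapped)
  expect_match(self$report$reason, "self_identical")

  # N runs cannot justify a merge: N never counts toward identity
  an <- paste0(random_dna(3000), strrep("N", 1500))
  bn <- paste0(strrep("N", 1500), random_dna(3000))
  nn <- merge_contigs_by_end_overlap(an, bn)
  expect_true(nn$report$gapped)
})
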