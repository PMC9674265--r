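# A small constructed donor/target pair: one TE in unique background, the
# target carrying a clean deletion of it (optionally with a spacer at the
# junction to control the flank-hit gap).
make_pair <- function(te_len = 600, flank = 6000, spacer = "",
                      seed = 1, extra_copy = FALSE) {
  set.seed(seed)
  left <- random_dna(flank); right <- random_dna(flank)
  te <- random_dna(te_len)
  donor_seq <- paste0(left, te, right)
  target_seq <- paste0(left, spacer, right)
  if (extra_copy)
    target_seq <- paste0(target_seq, random_dna(2000), left, spacer, right)
  donor <- genome(c(chr1 = donor_seq), id = "donor")
  target <- genome(c(chr1 = target_seq), id = "target")
  ann <- annotations("chr1", flank, flank + te_len, family_id = "fam",
                     copy_id = "fam.1")
  list(donor = donor, target = target, ann = ann, junction = flank)
}

test_that("flank extraction honours the size threshold and contig ends", {
  set.seed(51)
  g <- genome(c(c1 = random_dna(100000)))
  ann <- annotations(rep("c1", 3), c(2000, 30000, 60000),
                     c(2000 + 119, 30000 + 120, 60000 + 121),
                     family_id = "f")
  fp <- extract_flanks(g, ann)
  # strictly larger than 120 bp: the 119 and 120 bp copies are excluded
  expect_equal(nrow(fp), 1L)
  expect_equal(fp$te_start, 60000L)
  expect_equal(fp$left_len, 5000L)
  expect_equal(fp$right_len, 5000L)
  expect_false(fp$left_truncated)

  # a copy near the contig start gets a truncated left flank
  ann2 <- annotations("c1", 2000, 2500, family_id = "f")
  fp2 <- extract_flanks(g, ann2)
  expect_equal(fp2$left_len, 2000L)
  expect_true(fp2$left_truncated)
  expect_equal(fp2$right_len, 5000L)
  # flanks exclude the TE itself
  expect_equal(substr(g$contigs[["c1"]], 1, 2000), fp2$left_flank)
})

test_that("putative empty sites require close, co-oriented flank hits", {
  pr <- make_pair(seed = 52)
  fp <- extract_flanks(pr$donor, pr$ann)
  call <- call_putative_empty_site(fp[1, ], pr$target)
  expect_false(inherits(call, "no_call"))
  expect_equal(call$status, "putative")
  expect_equal(call$flank_gap, 0L)
  expect_equal(call$junction, pr$junction)

  # hits 25 bp apart exceed the 20 bp proximity cap
  pr25 <- make_pair(seed = 52, spacer = random_dna(25))
  no <- call_putative_empty_site(extract_flanks(pr25$donor, pr25$ann)[1, ],
                                 pr25$target)
  expect_true(inherits(no, "no_call"))
  expect_match(attr(no, "reason"), "too_far")

  # a filled site (subject identical to donor) yields no call either
  filled <- call_putative_empty_site(fp[1, ], pr$donor)
  expect_true(inherits(filled, "no_call"))

  # truncated flanks skip the locus with a logged reason
  short <- fp[1, ]; short$left_len <- 4000L
  sk <- call_putative_empty_site(short, pr$target)
  expect_match(attr(sk, "reason"), "truncated")
})

test_that("confirmation demands a single high-identity full-length merged hit", {
  pr <- make_pair(seed = 53)
  fp <- extract_flanks(pr$donor, pr$ann)
  call <- call_putative_empty_site(fp[1, ], pr$target)
  conf <- confirm_empty_site(call, fp[1, ], pr$target)
  expect_equal(conf$status, "confirmed")
  expect_gte(conf$merged_identity, 99)
  expect_gte(conf$merged_len, 9000)

  # two homologous loci in the target: the single-hit rule rejects
  pr2 <- make_pair(seed = 53, extra_copy = TRUE)
  fp2 <- extract_flanks(pr2$donor, pr2$ann)
  call2 <- call_putative_empty_site(fp2[1, ], pr2$target)
  conf2 <- confirm_empty_site(call2, fp2[1, ], pr2$target)
  expect_equal(conf2$status, "putative")
  expect_equal(conf2$reject_reason, "multiple_merged_hits")

  # identity below 99% is rejected
  set.seed(99)
  tseq <- pr$target$contigs[["chr1"]]
  mut <- genome(c(chr1 = mutate_positions(tseq, floor(nchar(tseq) * 0.015))),
                id = "mutated")
  call3 <- call_putative_empty_site(fp[1, ], mut)
  if (!inherits(call3, "no_call")) {
    conf3 <- confirm_empty_site(call3, fp[1, ], mut)
    expect_equal(conf3$status, "putative")
  } else succeed()
})

test_that("find_empty_sites is direction-consistent on a clean deletion", {
  pr <- make_pair(seed = 54)
  fwd <- find_empty_sites(pr$donor, pr$ann, pr$target)
  expect_equal(nrow(fwd), 1L)
  expect_equal(fwd$status, "confirmed")
  expect_equal(fwd$donor_genome, "donor")
  # the target genome has no annotated TE at the locus, so the reverse
  # query set is empty: a TE present in A and absent in B is reported when
  # querying A against B, never the other way round
  expect_error(annotate_tes(pr$target, c(fam = random_dna(600))),
               "no TE copies")
})

test_that("homologous locus clustering groups shared loci and splits wide spans", {
  pr <- make_pair(seed = 55)
  fp <- extract_flanks(pr$donor, pr$ann)
  # the same excision seen against two target genomes
  t2 <- genome(pr$target$contigs, id = "target2")
  c1 <- find_empty_sites(pr$donor, pr$ann, pr$target)
  c2 <- find_empty_sites(pr$donor, pr$ann, t2)
  calls <- rbind(c1, c2)
  fl <- attr(c1, "flanks"); fl$genome_id <- "donor"
  cl <- cluster_homologous_loci(calls, fl)
  expect_equal(length(cl), 1L)
  expect_equal(length(cl[[1]]$members), 2L)

  # a singleton call clusters alone
  cl1 <- cluster_homologous_loci(c1, fl)
  expect_equal(length(cl1[[1]]$members), 1L)

  # loci farther apart than 70 kb in one genome are split
  fake <- rbind(c1, c1)
  fake$junction <- c(1000L, 76000L)
  fake$te_copy_id <- c("fam.1", "fam.2")   # not linked by copy id
  fl2 <- rbind(fl, transform(fl, te_copy_id = "fam.2"))
  cl2 <- cluster_homologous_loci(fake, fl2)
  expect_equal(length(cl2), 2L)
})

test_that("implied maximum insertion size follows from span minus flanks", {
  expect_equal(implied_max_insertion(), 61000)
  expect_equal(implied_max_insertion(70000, 9000), 61000)
})

test_that("target-site duplications are recovered from filled/empty pairs", {
  set.seed(56)
  ctxL <- random_dna(400); ctxR <- random_dna(400)
  tsd <- "GATCGATC"                       # 8-mer
  te <- paste0("CC", random_dna(296), "GG")
  filled <- paste0(ctxL, tsd, te, tsd, ctxR)
  empty <- paste0(ctxL, tsd, ctxR)
  r <- detect_tsd(filled, empty)
  expect_equal(r$tsd, tsd)
  expect_equal(r$length, 8L)

  # insertion without a duplication
  f2 <- paste0(ctxL, te, ctxR)
  e2 <- paste0(ctxL, ctxR)
  expect_null(detect_tsd(f2, e2))

  # homopolymer junction: a duplication is returned but flagged ambiguous
  f3 <- paste0(ctxL, "TTT", "AAAA", te, "AAAA", "GGG", ctxR)
  e3 <- paste0(ctxL, "TTT", "AAAA", "GGG", ctxR)
  r3 <- detect_tsd(f3, e3)
  expect_equal(r3$tsd, "AAAA")
  expect_equal(r3$length, 4L)
})
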