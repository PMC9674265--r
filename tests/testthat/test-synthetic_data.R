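test_that("ancestral simulation plants extractable, self-consistent copies", {
  anc <- simulate_ancestral(small_cfg(n_copies = 5, contig_length = 60000),
                            seed = 2)
  expect_equal(nrow(anc$annotations), 5L)
  for (i in seq_len(5)) {
    a <- anc$annotations[i, ]
    sliced <- substr(anc$genome$contigs[[a$contig]], a$start + 1, a$end)
    expect_identical(sliced, unname(anc$copy_seqs[[a$copy_id]]))
    # the planted TSD flanks the copy on both sides
    expect_identical(substr(anc$genome$contigs[[a$contig]],
                            a$start - nchar(a$tsd) + 1, a$start), a$tsd)
    expect_identical(substr(anc$genome$contigs[[a$contig]],
                            a$end + 1, a$end + nchar(a$tsd)), a$tsd)
  }
  # determinism: the same seed reproduces byte-identical output
  anc2 <- simulate_ancestral(small_cfg(n_copies = 5, contig_length = 60000),
                             seed = 2)
  expect_identical(anc2$genome$contigs, anc$genome$contigs)
  expect_identical(anc2$annotations, anc$annotations)
})

test_that("DNA transposon consensi carry the configured terminal inverted repeat", {
  anc <- simulate_ancestral(sim_config(), seed = 4)
  for (fam in c("hAT_auto", "hAT_NA1")) {
    r <- self_inverted_repeat(anc$library[[fam]])
    expect_equal(r$tir_length, 28L)
    expect_equal(r$tir_identity, 100)
  }
  # families of the same superfamily group share the TIR
  expect_identical(substr(anc$library[["hAT_auto"]], 1, 28),
                   substr(anc$library[["hAT_NA1"]], 1, 28))
  # LTR consensus starts and ends with the same LTR
  ltr <- anc$library[["LTR1"]]
  expect_identical(substr(ltr, 1, 250), substr(ltr, nchar(ltr) - 249,
                                               nchar(ltr)))
})

test_that("derived genomes implement the planted event semantics", {
  cfg <- sim_config()
  anc <- simulate_ancestral(cfg, seed = 5)
  d1 <- derive_sample(anc, "P1", seed = 6)
  tr <- d1$truth
  expect_setequal(unique(tr$type),
                  c("insertion", "excision", "solo_ltr", "inversion"))
  # excision: the derived genome shrinks by exactly the TE length and the
  # TSD footprint (both copies) remains at the junction
  exc <- tr[tr$type == "excision", ][1, ]
  a <- anc$annotations[anc$annotations$copy_id == exc$copy_id, ]
  jct <- substr(d1$genome$contigs[[exc$contig]],
                exc$derived_start - nchar(a$tsd) + 1,
                exc$derived_start + nchar(a$tsd))
  expect_identical(jct, paste0(a$tsd, a$tsd))
  # insertion: the inserted copy is flanked by a duplicated target site
  ins <- tr[tr$type == "insertion", ][1, ]
  t <- nchar(ins$tsd)
  gseq <- d1$genome$contigs[[ins$contig]]
  expect_identical(substr(gseq, ins$derived_start - t + 1, ins$derived_start),
                   ins$tsd)
  expect_identical(substr(gseq, ins$derived_end + 1, ins$derived_end + t),
                   ins$tsd)
  # solo LTR: exactly one LTR remains at the locus
  solo <- tr[tr$type == "solo_ltr", ][1, ]
  asolo <- anc$annotations[anc$annotations$copy_id == solo$copy_id, ]
  remaining <- substr(d1$genome$contigs[[solo$contig]],
                      solo$derived_start + 1,
                      solo$derived_start + asolo$ltr_len)
  ltr_cons <- substr(anc$library[["LTR1"]], 1, asolo$ltr_len)
  hits <- local_search(ltr_cons, genome(c(x = paste0(
    remaining, substr(d1$genome$contigs[[solo$contig]],
                      solo$derived_start + asolo$ltr_len + 1,
                      solo$derived_start + asolo$ltr_len + 3000))), id = "loc"),
    min_identity = 90, min_length = 200)
  expect_equal(nrow(hits), 1L)   # one LTR, not two
  # an empty plan reproduces the ancestral genome exactly
  cfg0 <- cfg
  cfg0$plans$P0 <- list(n_insertions = 0, n_excisions = 0, n_solo_ltr = 0,
                        n_nahr = 0, n_inversions = 0)
  anc0 <- simulate_ancestral(cfg0, seed = 5)
  d0 <- derive_sample(anc0, "P0", seed = 7)
  expect_identical(d0$genome$contigs, anc0$genome$contigs)
  expect_equal(nrow(d0$truth), 0L)
})

test_that("recombination deletions leave a single chimeric copy", {
  cfg <- sim_config()
  anc <- simulate_ancestral(cfg, seed = 8)
  d2 <- derive_sample(anc, "P2", seed = 9)
  nahr <- d2$truth[d2$truth$type == "nahr_deletion", ]
  expect_equal(nrow(nahr), 1L)
  p1 <- anc$annotations[anc$annotations$copy_id == anc$nahr_pair[1], ]
  p2 <- anc$annotations[anc$annotations$copy_id == anc$nahr_pair[2], ]
  expect_equal(nahr$length, p2$start - p1$start)
  # and the deletion classifies as inter-copy recombination from annotations
  mech <- classify_deletion_mechanism(
    list(contig = nahr$contig, pos = p1$start, length = nahr$length),
    anc$annotations)
  expect_equal(mech$mechanism, "inter_copy_nahr")
})

test_that("read support is binomial in the mosaic fraction and deterministic", {
  truth <- data.frame(sample_id = "s", type = "insertion", family_id = "f",
                      copy_id = "f.1", contig = "c1", anc_start = 0L,
                      anc_end = 0L, derived_start = 1000L,
                      derived_end = 1100L, length = 100L, tsd = "ACGTACGT",
                      mosaic_fraction = 1, stringsAsFactors = FALSE)
  sup <- simulate_read_support(truth, total_reads = 40, seed = 1)
  expect_equal(sup$ref_support, 0L)      # fraction 1: no reference reads
  expect_equal(sup$alt_support, 40L)

  t2 <- truth[rep(1, 1000), ]; t2$mosaic_fraction <- 0.5
  sup2 <- simulate_read_support(t2, total_reads = 40, seed = 2)
  se <- sqrt(0.5 * 0.5 / 40) * 40 / sqrt(1000)
  expect_lt(abs(mean(sup2$alt_support) - 20), 3 * se)
  expect_identical(simulate_read_support(t2, total_reads = 40, seed = 2),
                   sup2)
  expect_error(simulate_read_support(truth, total_reads = 0), ">= 1")
})

test_that("methylation simulation hits its class means and filter fractions", {
  anc <- simulate_ancestral(small_cfg(n_copies = 4, contig_length = 60000),
                            seed = 13)
  rec <- simulate_methylation(anc$genome, anc$annotations, seed = 14)
  lat <- attr(rec, "latent")
  sf <- label_repeat_sites(site_frequencies(filter_reads(rec)),
                           anc$annotations)
  expect_equal(mean(sf$frequency[!sf$in_repeat]), 0.20, tolerance = 0.02)
  expect_equal(mean(sf$frequency[sf$in_repeat]), 0.76, tolerance = 0.05)
  # all-pass attributes make filter_reads the identity
  rec0 <- simulate_methylation(anc$genome, anc$annotations, seed = 15,
                               frac_low_mapq = 0, frac_secondary = 0,
                               frac_short_span = 0)
  expect_equal(nrow(filter_reads(rec0)), nrow(rec0))
  # determinism
  rec2 <- simulate_methylation(anc$genome, anc$annotations, seed = 14)
  expect_identical(rec2, rec)
})

test_that("the full bundle is a pure function of (config, seed)", {
  cfg <- sim_config()
  s1 <- simulate_dataset(cfg, seed = 17)
  s2 <- simulate_dataset(cfg, seed = 17)
  expect_identical(s1$ancestral$genome$contigs, s2$ancestral$genome$contigs)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$support, s2$support)
  for (smp in names(s1$samples))
    expect_identical(s1$samples[[smp]]$genome$contigs,
                     s2$samples[[smp]]$genome$contigs)
})
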