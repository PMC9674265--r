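#' Random DNA sequence
#' @param n length in bp.
#' @param gc GC fraction.
#' @return a DNA string.
#' @export
random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  v <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(v)) < rate)
  for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  paste(v, collapse = "")
}

#' Simulation configuration
#'
#' Encodes the study conditions the simulator emulates: an ancestral genome
#' with a TE library (DNA transposons with shared terminal inverted repeats,
#' a 5'-truncating LINE-like element, an LTR element with paired LTRs),
#' derived samples carrying planted insertions with target-site duplications,
#' excisions, solo-LTR and inter-copy recombination deletions and inversions,
#' binomial read support for mosaic variants, negative-binomial depth
#' proportional to copy number, and beta-binomial methylation calls with a
#' higher mean in repeats.
#'
#' @param n_contigs,contig_length,gc ancestral genome shape.
#' @param te_library list of family specs (`class`, `length`, and per class
#'   `tir_len`/`tir_group`, `ltr_len`, `tsd_len`, `autonomous`, `n_ancestral`).
#' @param plans named list (one per derived sample) of event counts:
#'   `n_insertions`, `n_excisions`, `n_solo_ltr`, `n_nahr`, `n_inversions`.
#' @param copy_divergence per-base substitution rate of ancestral copies away
#'   from their family consensus (makes source-copy attribution meaningful).
#' @param mosaic_fixed_prob probability an event is fixed (fraction 1);
#'   otherwise the mosaic fraction is uniform on `mosaic_range`.
#' @param mosaic_range range of mosaic fractions.
#' @param total_reads reads per locus for the read-support model.
#' @param base_cov,dispersion depth model (mean single-copy coverage and NB
#'   size parameter).
#' @param repeat_mean,nonrepeat_mean,meth_precision,reads_per_site
#'   methylation model.
#' @param flank_margin keep planted loci this far from contig ends (bp).
#' @param min_separation minimum edge-to-edge distance between planted loci
#'   (bp); kept above the 5 kb flank length so flanks stay repeat-free.
#' @param nahr_gap intervening sequence between the two copies of the
#'   recombination pair (bp).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_contigs = 4, contig_length = 50000, gc = 0.5,
                       te_library = NULL, plans = NULL,
                       copy_divergence = 0.005,
                       mosaic_fixed_prob = 0.2, mosaic_range = c(0.15, 1),
                       total_reads = 40, base_cov = 35, dispersion = 20,
                       repeat_mean = 0.76, nonrepeat_mean = 0.20,
                       meth_precision = 10, reads_per_site = 20,
                       flank_margin = 5000, min_separation = 5200,
                       nahr_gap = 2500) {
  if (is.null(te_library)) {
    te_library <- list(
      hAT_auto = list(class = "DNA_TIR", length = 1200, tir_len = 28,
                      tir_group = "hAT", tsd_len = 8, autonomous = TRUE,
                      n_ancestral = 4),
      hAT_NA1 = list(class = "DNA_TIR", length = 450, tir_len = 28,
                     tir_group = "hAT", tsd_len = 8, autonomous = FALSE,
                     n_ancestral = 4),
      LINE1 = list(class = "LINE", length = 1800, tsd_len = 12,
                   autonomous = TRUE, n_ancestral = 3),
      LTR1 = list(class = "LTR", length = 2400, ltr_len = 250, tsd_len = 5,
                  autonomous = TRUE, n_ancestral = 4))
  }
  if (is.null(plans)) {
    plans <- list(
      P1 = list(n_insertions = 5, n_excisions = 5, n_solo_ltr = 1,
                n_nahr = 0, n_inversions = 1),
      P2 = list(n_insertions = 5, n_excisions = 5, n_solo_ltr = 0,
                n_nahr = 1, n_inversions = 0))
  }
  structure(list(n_contigs = n_contigs, contig_length = contig_length,
                 gc = gc, te_library = te_library, plans = plans,
                 copy_divergence = copy_divergence,
                 mosaic_fixed_prob = mosaic_fixed_prob,
                 mosaic_range = mosaic_range, total_reads = total_reads,
                 base_cov = base_cov, dispersion = dispersion,
                 repeat_mean = repeat_mean, nonrepeat_mean = nonrepeat_mean,
                 meth_precision = meth_precision,
                 reads_per_site = reads_per_site,
                 flank_margin = flank_margin,
                 min_separation = min_separation, nahr_gap = nahr_gap),
            class = "sim_config")
}

# family consensus sequences; DNA_TIR families of a tir_group share TIRs,
# LTR consensi carry two identical LTRs
build_library <- function(cfg) {
  tirs <- list()
  lib <- list()
  for (fam in names(cfg$te_library)) {
    sp <- cfg$te_library[[fam]]
    if (sp$class == "DNA_TIR") {
      grp <- if (!is.null(sp$tir_group)) sp$tir_group else fam
      if (is.null(tirs[[grp]])) tirs[[grp]] <- random_dna(sp$tir_len, cfg$gc)
      # core ends are fixed non-complementary so the terminal inverted
      # repeat stops exactly at tir_len
      core <- paste0("AAAA", random_dna(sp$length - 2 * sp$tir_len - 8, cfg$gc),
                     "AAAA")
      lib[[fam]] <- paste0(tirs[[grp]], core, revcomp(tirs[[grp]]))
    } else if (sp$class == "LTR") {
      ltr <- random_dna(sp$ltr_len, cfg$gc)
      lib[[fam]] <- paste0(ltr, random_dna(sp$length - 2 * sp$ltr_len, cfg$gc),
                           ltr)
    } else {
      lib[[fam]] <- random_dna(sp$length, cfg$gc)
    }
  }
  list(consensus = unlist(lib), tirs = tirs)
}

#' Simulate an ancestral genome with planted TE copies
#'
#' Plants the configured number of copies of each family (plus one adjacent
#' same-family pair for recombination events, when any plan requests one) at
#' random positions that keep `min_separation` bp between loci and
#' `flank_margin` bp from contig ends, so that extracted flanks are unique
#' background sequence. Every copy is planted with a target-site duplication
#' and diverges from its consensus by `copy_divergence`. Target positions for
#' the derived samples' future insertions are reserved with the same
#' clearance. Fully deterministic given the seed.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return list with `genome`, `annotations` (with `class`, `ltr_len`, `tsd`
#'   columns), `library` (consensus vector), `tirs`, `copy_seqs`,
#'   `insertion_sites` (reserved per-sample positions), `nahr_pair` (copy
#'   ids or NULL) and the config.
#' @export
simulate_ancestral <- function(cfg = sim_config(), seed = 1) {
  set.seed(seed)
  lib <- build_library(cfg)
  want_nahr <- any(vapply(cfg$plans, function(p) p$n_nahr > 0, logical(1)))
  # slot list: ancestral copies, one optional recombination pair, reserved
  # insertion sites
  slots <- list()
  for (fam in names(cfg$te_library)) {
    sp <- cfg$te_library[[fam]]
    n <- sp$n_ancestral
    if (want_nahr && sp$class == "LTR" && n >= 2) n <- n - 2
    for (i in seq_len(n))
      slots[[length(slots) + 1L]] <- list(kind = "te", family = fam)
  }
  if (want_nahr) {
    pairfam <- names(cfg$te_library)[vapply(cfg$te_library, function(s)
      s$class == "LTR", logical(1))][1]
    if (is.na(pairfam)) stop("a recombination pair needs an LTR family")
    slots[[length(slots) + 1L]] <- list(kind = "pair", family = pairfam)
  }
  for (smp in names(cfg$plans)) {
    for (i in seq_len(cfg$plans[[smp]]$n_insertions))
      slots[[length(slots) + 1L]] <- list(kind = "site", sample = smp, index = i)
  }
  slot_len <- vapply(slots, function(sl) {
    if (sl$kind == "site") return(0L)
    sp <- cfg$te_library[[sl$family]]
    if (sl$kind == "pair")
      return(as.integer(2 * (sp$length + 2 * sp$tsd_len) + cfg$nahr_gap))
    as.integer(sp$length + 2L * sp$tsd_len)
  }, integer(1))
  # assign slots to contigs greedily by remaining capacity, in a seeded
  # random order, so loci plus their separation always fit
  ord <- sample(seq_along(slots))
  usable <- cfg$contig_length - 2 * cfg$flank_margin
  contig_of <- integer(length(slots))
  load <- numeric(cfg$n_contigs)      # sequence bp committed per contig
  nslot <- integer(cfg$n_contigs)
  for (i in ord) {
    need <- load + slot_len[i] + nslot * cfg$min_separation
    c <- which.max(usable - need)
    if (need[c] > usable)
      stop("genome too small for requested copies: needs ", need[c],
           " bp of ", usable, " usable on the fullest contig")
    contig_of[i] <- c
    load[c] <- load[c] + slot_len[i]
    nslot[c] <- nslot[c] + 1L
  }
  contigs <- character(cfg$n_contigs)
  names(contigs) <- paste0("chr", seq_len(cfg$n_contigs))
  ann_rows <- list(); copy_seqs <- character(0); sites <- list()
  nahr_pair <- NULL
  copy_counter <- integer(0)
  next_copy_id <- function(fam) {
    copy_counter[fam] <<- if (is.na(copy_counter[fam])) 1L else
      copy_counter[fam] + 1L
    paste0(fam, ".", copy_counter[fam])
  }
  for (c in seq_len(cfg$n_contigs)) {
    ctg <- names(contigs)[c]
    idx <- which(contig_of == c)
    idx <- idx[order(match(idx, ord))]          # seeded order within contig
    k <- length(idx)
    slack <- usable - sum(slot_len[idx]) - max(0L, k - 1L) * cfg$min_separation
    w <- runif(k + 1)
    extra <- floor(slack * w / sum(w))
    extra[k + 1] <- slack - sum(extra[seq_len(k)])
    parts <- character(0)
    cur <- 0L
    emit <- function(s) { parts[length(parts) + 1L] <<- s; cur <<- cur + nchar(s) }
    emit(random_dna(cfg$flank_margin + extra[1], cfg$gc))
    for (t in seq_len(k)) {
      sl <- slots[[idx[t]]]
      if (t > 1) emit(random_dna(cfg$min_separation + extra[t], cfg$gc))
      if (sl$kind == "site") {
        sites[[length(sites) + 1L]] <- data.frame(
          sample = sl$sample, index = sl$index, contig = ctg, pos = cur,
          stringsAsFactors = FALSE)
      } else if (sl$kind == "te") {
        sp <- cfg$te_library[[sl$family]]
        seq <- mutate_seq(lib$consensus[[sl$family]], cfg$copy_divergence)
        if (sp$class == "LINE") {   # variable 5' truncation
          keep <- ceiling(nchar(seq) * runif(1, 0.5, 1))
          seq <- substr(seq, nchar(seq) - keep + 1, nchar(seq))
        }
        tsd <- random_dna(sp$tsd_len, cfg$gc)
        id <- next_copy_id(sl$family)
        emit(tsd)
        ann_rows[[length(ann_rows) + 1L]] <- data.frame(
          contig = ctg, start = cur, end = cur + nchar(seq), strand = "+",
          family_id = sl$family, copy_id = id, class = sp$class,
          ltr_len = if (sp$class == "LTR") sp$ltr_len else NA_integer_,
          tsd = tsd, stringsAsFactors = FALSE)
        copy_seqs[id] <- seq
        emit(seq); emit(tsd)
      } else {                      # recombination pair
        sp <- cfg$te_library[[sl$family]]
        ids <- character(2)
        for (p in 1:2) {
          if (p == 2) emit(random_dna(cfg$nahr_gap, cfg$gc))
          seq <- mutate_seq(lib$consensus[[sl$family]], cfg$copy_divergence)
          tsd <- random_dna(sp$tsd_len, cfg$gc)
          id <- next_copy_id(sl$family)
          ids[p] <- id
          emit(tsd)
          ann_rows[[length(ann_rows) + 1L]] <- data.frame(
            contig = ctg, start = cur, end = cur + nchar(seq), strand = "+",
            family_id = sl$family, copy_id = id, class = sp$class,
            ltr_len = sp$ltr_len, tsd = tsd, stringsAsFactors = FALSE)
          copy_seqs[id] <- seq
          emit(seq); emit(tsd)
        }
        nahr_pair <- ids
      }
    }
    emit(random_dna(cfg$flank_margin + extra[k + 1], cfg$gc))
    contigs[ctg] <- paste(parts, collapse = "")
  }
  adf <- do.call(rbind, ann_rows)
  ann <- annotations(contig = adf$contig, start = adf$start, end = adf$end,
                     strand = adf$strand, family_id = adf$family_id,
                     copy_id = adf$copy_id, class = adf$class,
                     ltr_len = adf$ltr_len, tsd = adf$tsd)
  g <- genome(contigs, id = "ancestral")
  validate_annotations(ann, g)
  list(genome = g, annotations = ann, library = lib$consensus,
       tirs = lib$tirs, copy_seqs = copy_seqs,
       insertion_sites = if (length(sites)) do.call(rbind, sites) else NULL,
       nahr_pair = nahr_pair, config = cfg)
}

#' Derive a sample genome by applying a planted event plan
#'
#' Applies the configured numbers of insertions (source copy + target-site
#' duplication), excisions (the TE is removed, leaving both TSD copies as
#' the footprint), solo-LTR deletions (internal sequence plus one LTR),
#' inter-copy recombination deletions (from the start of one pair copy to
#' the start of the other) and in-place inversions. Events use the
#' pre-cleared loci of the ancestral simulation so they never overlap. Every
#' event is recorded in a truth table whose coordinates are verified against
#' the emitted sequence before returning.
#'
#' @param anc output of [simulate_ancestral()].
#' @param sample_id which plan of the config to apply.
#' @param seed integer seed.
#' @return list with `genome` (the derived assembly) and `truth` (the event
#'   table: type, family, copies, ancestral and derived coordinates, TSD,
#'   mosaic fraction).
#' @export
derive_sample <- function(anc, sample_id, seed = 1) {
  cfg <- anc$config
  plan <- cfg$plans[[sample_id]]
  if (is.null(plan)) stop("no plan for sample '", sample_id, "'")
  set.seed(seed)
  ann <- anc$annotations
  used <- character(0)
  events <- list()
  add_event <- function(type, family, copy, contig, s, e, delta, tsd,
                        seq = NA_character_) {
    events[[length(events) + 1L]] <<- list(
      type = type, family = family, copy = copy, contig = contig,
      anc_start = s, anc_end = e, delta = delta, tsd = tsd, seq = seq)
  }
  # excisions: DNA transposon copies lose the TE, keep the TSD footprint
  excisable <- ann$copy_id[ann$class == "DNA_TIR"]
  if (plan$n_excisions > length(excisable))
    stop("plan infeasible: not enough DNA transposon copies to excise")
  exc <- sample(excisable, plan$n_excisions)
  for (id in exc) {
    a <- ann[ann$copy_id == id, ]
    add_event("excision", a$family_id, id, a$contig, a$start, a$end,
              -(a$end - a$start), a$tsd)
  }
  used <- c(used, exc)
  # solo-LTR deletions
  ltr_ok <- ann$copy_id[ann$class == "LTR" & !(ann$copy_id %in% anc$nahr_pair)]
  if (plan$n_solo_ltr > length(ltr_ok))
    stop("plan infeasible: not enough LTR copies for solo-LTR events")
  solo <- sample(ltr_ok, plan$n_solo_ltr)
  for (id in solo) {
    a <- ann[ann$copy_id == id, ]
    add_event("solo_ltr", a$family_id, id, a$contig, a$start,
              a$end - a$ltr_len, -(a$end - a$ltr_len - a$start), a$tsd)
  }
  used <- c(used, solo)
  # recombination deletion between the planted pair
  if (plan$n_nahr > 0) {
    if (is.null(anc$nahr_pair)) stop("plan infeasible: no recombination pair")
    p1 <- ann[ann$copy_id == anc$nahr_pair[1], ]
    p2 <- ann[ann$copy_id == anc$nahr_pair[2], ]
    add_event("nahr_deletion", p1$family_id, paste(anc$nahr_pair, collapse = "+"),
              p1$contig, p1$start, p2$start, -(p2$start - p1$start),
              NA_character_)
    used <- c(used, anc$nahr_pair)
  }
  # inversions
  inv_ok <- setdiff(ann$copy_id, used)
  inv <- sample(inv_ok, plan$n_inversions)
  for (id in inv) {
    a <- ann[ann$copy_id == id, ]
    add_event("inversion", a$family_id, id, a$contig, a$start, a$end, 0L,
              NA_character_, seq = revcomp(anc$copy_seqs[[id]]))
  }
  used <- c(used, inv)
  # insertions at the reserved sites of this sample
  sites <- anc$insertion_sites
  sites <- sites[sites$sample == sample_id, , drop = FALSE]
  if (is.null(sites) || nrow(sites) < plan$n_insertions)
    stop("plan infeasible: not enough reserved insertion sites")
  fams <- names(cfg$te_library)
  for (i in seq_len(plan$n_insertions)) {
    fam <- sample(fams, 1)
    sp <- cfg$te_library[[fam]]
    src <- sample(ann$copy_id[ann$family_id == fam], 1)
    seq <- anc$copy_seqs[[src]]
    if (sp$class == "LINE") {
      keep <- ceiling(nchar(seq) * runif(1, 0.4, 1))
      seq <- substr(seq, nchar(seq) - keep + 1, nchar(seq))
    }
    st <- sites[i, ]
    add_event("insertion", fam, src, st$contig, st$pos, st$pos,
              nchar(seq) + sp$tsd_len, NA_character_, seq = seq)
  }
  # apply edits per contig, descending ancestral coordinate
  contigs <- anc$genome$contigs
  ev_contig <- vapply(events, `[[`, character(1), "contig")
  ev_start <- vapply(events, function(e) e$anc_start, numeric(1))
  for (i in order(ev_start, decreasing = TRUE)) {
    e <- events[[i]]
    g <- contigs[[e$contig]]
    if (e$type == "insertion") {
      t <- cfg$te_library[[e$family]]$tsd_len
      tsd <- substr(g, e$anc_start + 1L, e$anc_start + t)
      events[[i]]$tsd <- tsd
      contigs[[e$contig]] <- paste0(substr(g, 1, e$anc_start + t), e$seq,
                                    substr(g, e$anc_start + 1L, nchar(g)))
    } else if (e$type == "inversion") {
      contigs[[e$contig]] <- paste0(substr(g, 1, e$anc_start), e$seq,
                                    substr(g, e$anc_end + 1L, nchar(g)))
    } else {
      contigs[[e$contig]] <- paste0(substr(g, 1, e$anc_start),
                                    substr(g, e$anc_end + 1L, nchar(g)))
    }
  }
  # derived coordinates from cumulative offsets, then verify by slicing
  truth <- list()
  for (ctg in unique(ev_contig)) {
    idx <- which(ev_contig == ctg)
    idx <- idx[order(ev_start[idx])]
    offset <- 0L
    for (i in idx) {
      e <- events[[i]]
      t <- if (e$type == "insertion") cfg$te_library[[e$family]]$tsd_len else 0L
      d_start <- e$anc_start + offset + t
      d_end <- if (e$type == "insertion") d_start + nchar(e$seq)
        else if (e$type == "inversion") e$anc_end + offset
        else d_start
      mosaic <- if (runif(1) < cfg$mosaic_fixed_prob) 1 else
        runif(1, cfg$mosaic_range[1], cfg$mosaic_range[2])
      truth[[length(truth) + 1L]] <- data.frame(
        sample_id = sample_id, type = e$type, family_id = e$family,
        copy_id = e$copy, contig = ctg,
        anc_start = e$anc_start, anc_end = e$anc_end,
        derived_start = d_start, derived_end = d_end,
        length = abs(if (e$type == "insertion") nchar(e$seq) else e$delta),
        tsd = e$tsd, mosaic_fraction = mosaic, stringsAsFactors = FALSE)
      if (e$type %in% c("insertion", "inversion")) {
        got <- substr(contigs[[ctg]], d_start + 1L, d_end)
        if (!identical(got, e$seq))
          stop("truth-table inconsistency for ", e$type, " at ", ctg, ":",
               d_start)
      }
      offset <- offset + e$delta
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(sample_id = character(0), type = character(0),
               family_id = character(0), copy_id = character(0),
               contig = character(0), anc_start = integer(0),
               anc_end = integer(0), derived_start = integer(0),
               derived_end = integer(0), length = integer(0),
               tsd = character(0), mosaic_fraction = numeric(0),
               stringsAsFactors = FALSE)
  truth <- truth[order(truth$contig, truth$anc_start), , drop = FALSE]
  rownames(truth) <- NULL
  list(genome = genome(contigs, id = sample_id), truth = truth)
}

#' Simulate read support for planted events
#'
#' Variant-allele support is Binomial(`total_reads`, mosaic fraction) per
#' event; reference support is the remainder. The number of agreeing caller
#' modules is 1 + Binomial(5, `caller_p`) drawn from a pool of six labels.
#'
#' @param truth a truth table from [derive_sample()] (or several row-bound).
#' @param total_reads reads covering each locus.
#' @param seed integer seed.
#' @param caller_p per-module agreement probability.
#' @return a [variant_calls()] table (positions on the derived genome).
#' @export
simulate_read_support <- function(truth, total_reads = 40, seed = 1,
                                  caller_p = 0.6) {
  if (total_reads < 1) stop("total_reads must be >= 1")
  set.seed(seed)
  n <- nrow(truth)
  alt <- rbinom(n, total_reads, truth$mosaic_fraction)
  pool <- paste0("module", 1:6)
  ncall <- 1L + rbinom(n, 5, caller_p)
  callers <- vapply(ncall, function(k)
    paste(sort(sample(pool, k)), collapse = ","), character(1))
  type <- c(insertion = "INS", excision = "DEL", solo_ltr = "DEL",
            nahr_deletion = "DEL", inversion = "INV")[truth$type]
  variant_calls(sample_id = truth$sample_id, contig = truth$contig,
                pos = truth$derived_start, type = unname(type),
                length = truth$length, ref_support = total_reads - alt,
                alt_support = alt, caller_ids = callers)
}

#' Simulate per-family depth profiles from copy numbers
#'
#' Per-position depth over each family consensus is negative binomial with
#' mean copy_number x the sample's raw single-copy coverage and the given
#' dispersion (size) parameter; zero-copy families receive near-zero
#' cross-mapping noise. Each sample also gets an observed single-copy median
#' (from a simulated single-copy region), so downstream normalization to the
#' target coverage is exercised for real.
#'
#' @param copy_numbers families x samples matrix (dimnames required).
#' @param consensus_len named vector of family consensus lengths.
#' @param base_cov target/typical single-copy coverage.
#' @param dispersion NB size parameter; large values approach Poisson.
#' @param raw_cov optional per-sample raw coverages; defaults to
#'   Uniform(1.1 x base_cov, 2 x base_cov) draws, so every sample sits above
#'   the normalization target and subsampling always applies.
#' @param seed integer seed.
#' @return list of depth profiles for [te_load_table()].
#' @export
simulate_depth_profiles <- function(copy_numbers, consensus_len,
                                    base_cov = 35, dispersion = 20,
                                    raw_cov = NULL, seed = 1) {
  if (base_cov <= 0) stop("base_cov must be positive")
  set.seed(seed)
  fams <- rownames(copy_numbers); smps <- colnames(copy_numbers)
  if (is.null(fams) || is.null(smps)) stop("copy_numbers needs dimnames")
  if (is.null(raw_cov))
    raw_cov <- runif(length(smps), 1.1 * base_cov, 2 * base_cov)
  lapply(seq_along(smps), function(j) {
    depths <- lapply(fams, function(f) {
      L <- consensus_len[[f]]
      mu <- max(copy_numbers[f, j] * raw_cov[j], 0.02 * raw_cov[j])
      rnbinom(L, size = dispersion, mu = mu)
    })
    names(depths) <- fams
    obs <- median(rnbinom(2000, size = dispersion, mu = raw_cov[j]))
    list(sample_id = smps[j], family_depths = depths,
         observed_single_copy_median = obs)
  })
}

#' Simulate per-read CpG methylation call records
#'
#' Every CpG dinucleotide of the genome gets a latent methylation frequency
#' drawn from a Beta distribution around its class mean (repeat vs
#' non-repeat, or a per-copy override), per-read calls are Bernoulli draws
#' from it, and read attributes (mapq, primary flag, aligned span) are drawn
#' so a configurable fraction fails each mapping filter.
#'
#' @param g a [genome()].
#' @param repeats a [annotations()] table of repeat intervals.
#' @param repeat_mean,nonrepeat_mean class mean methylation frequencies.
#' @param precision Beta precision (a+b); higher = tighter around the mean.
#' @param reads_per_site expected calls per site (Poisson, min 1).
#' @param copy_means optional named vector overriding the mean inside the
#'   named copies' intervals (e.g. hypomethylated source copies).
#' @param frac_low_mapq,frac_secondary,frac_short_span per-read failure
#'   fractions for the three filters.
#' @param max_sites cap on the number of CpG sites simulated (subsampled
#'   uniformly when exceeded).
#' @param seed integer seed.
#' @return a `data.frame` of per-read call records for [filter_reads()].
#' @export
simulate_methylation <- function(g, repeats, repeat_mean = 0.76,
                                 nonrepeat_mean = 0.20, precision = 10,
                                 reads_per_site = 20, copy_means = NULL,
                                 frac_low_mapq = 0.08, frac_secondary = 0.04,
                                 frac_short_span = 0.08, max_sites = Inf,
                                 seed = 1) {
  stopifnot(repeat_mean >= 0, repeat_mean <= 1,
            nonrepeat_mean >= 0, nonrepeat_mean <= 1)
  set.seed(seed)
  site_list <- lapply(names(g$contigs), function(ctg) {
    hits <- gregexpr("CG", g$contigs[[ctg]], fixed = TRUE)[[1]]
    if (hits[1] == -1) return(NULL)
    data.frame(contig = ctg, pos = as.integer(hits) - 1L,
               stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, site_list)
  if (is.null(sites) || nrow(sites) == 0) stop("genome contains no CpG sites")
  if (nrow(sites) > max_sites)
    sites <- sites[sort(sample(nrow(sites), max_sites)), , drop = FALSE]
  mean_of <- rep(nonrepeat_mean, nrow(sites))
  for (i in seq_len(nrow(repeats))) {
    sel <- sites$contig == repeats$contig[i] &
      sites$pos >= repeats$start[i] & sites$pos < repeats$end[i]
    m <- repeat_mean
    if (!is.null(copy_means) && repeats$copy_id[i] %in% names(copy_means))
      m <- copy_means[[repeats$copy_id[i]]]
    mean_of[sel] <- m
  }
  eps <- 1e-3
  mclamp <- pmin(pmax(mean_of, eps), 1 - eps)
  latent <- rbeta(nrow(sites), mclamp * precision, (1 - mclamp) * precision)
  nreads <- pmax(1L, rpois(nrow(sites), reads_per_site))
  idx <- rep(seq_len(nrow(sites)), nreads)
  n <- length(idx)
  mapq <- ifelse(runif(n) < frac_low_mapq, sample(0:59, n, replace = TRUE), 60L)
  primary <- as.integer(runif(n) >= frac_secondary)
  span <- ifelse(runif(n) < frac_short_span,
                 floor(runif(n, 500, 6000)), floor(runif(n, 6000, 20000)))
  records <- data.frame(
    read_id = paste0("r", idx, ".", sequence(nreads)),
    contig = sites$contig[idx], pos = sites$pos[idx],
    methylated = rbinom(n, 1, latent[idx]),
    mapq = as.integer(mapq), primary = primary, span = as.integer(span),
    stringsAsFactors = FALSE)
  attr(records, "latent") <- data.frame(sites, latent = latent,
                                        mean = mean_of)
  records
}

#' Simulate a haploid two-nucleotype genotype matrix
#'
#' Divergent sites separate the two groups (group A carries 0, group B
#' carries 1); their count is chosen so that the matrix-wide nucleotide
#' diversity over the callable length equals `pi`. Optionally a block of
#' `swap_k` consecutive sites in one sample is swapped to the other group's
#' allele, emulating a mitotic recombination / gene conversion tract.
#'
#' @param n_per_group haploid samples per nucleotype.
#' @param callable_length callable genome length in bp.
#' @param pi target nucleotide diversity.
#' @param swap_sample,swap_start,swap_k optional planted tract (sample id,
#'   1-based site index of the first swapped site, number of sites).
#' @param missing_rate per-call missingness.
#' @param seed integer seed.
#' @return `list(gm=, callable_length=, n_divergent=)`.
#' @export
simulate_genotypes <- function(n_per_group = 4, callable_length = 1e6,
                               pi = 0.0056, swap_sample = NULL,
                               swap_start = NULL, swap_k = 0,
                               missing_rate = 0, seed = 1) {
  set.seed(seed)
  g <- n_per_group
  n_pairs <- choose(2 * g, 2)
  d <- round(pi * n_pairs * callable_length / g^2)
  samples <- c(paste0("A", seq_len(g)), paste0("B", seq_len(g)))
  groups <- setNames(rep(c("A", "B"), each = g), samples)
  pos <- sort(sample.int(callable_length, d))
  geno <- matrix(rep(c(rep(0L, g), rep(1L, g)), each = d), nrow = d,
                 dimnames = list(NULL, samples))
  if (!is.null(swap_sample) && swap_k > 0) {
    if (is.null(swap_start)) swap_start <- sample.int(d - swap_k + 1L, 1)
    rows <- swap_start:(swap_start + swap_k - 1L)
    geno[rows, swap_sample] <- 1L - geno[rows, swap_sample]
  }
  if (missing_rate > 0)
    geno[runif(length(geno)) < missing_rate] <- NA_integer_
  gm <- genotype_matrix(data.frame(contig = "chr1", pos = pos), geno, groups)
  list(gm = gm, callable_length = callable_length, n_divergent = d,
       swap_start = if (swap_k > 0) swap_start else NA_integer_)
}

#' Run the full simulation bundle
#'
#' Ancestral genome, all configured derived samples (with truth tables), and
#' the read-support call set. Deterministic given (config, seed); per-sample
#' seeds are derived from the master seed.
#'
#' @param cfg a [sim_config()].
#' @param seed master seed.
#' @return list with `ancestral`, `samples` (named list of
#'   [derive_sample()] outputs), `truth` (row-bound) and `support`.
#' @export
simulate_dataset <- function(cfg = sim_config(), seed = 1) {
  anc <- simulate_ancestral(cfg, seed)
  samples <- list()
  for (i in seq_along(cfg$plans)) {
    smp <- names(cfg$plans)[i]
    samples[[smp]] <- derive_sample(anc, smp, seed = (seed * 131L + i) %% 2147483647L)
  }
  truth <- do.call(rbind, lapply(samples, `[[`, "truth"))
  rownames(truth) <- NULL
  support <- simulate_read_support(truth, total_reads = cfg$total_reads,
                                   seed = (seed * 131L + 99L) %% 2147483647L)
  list(ancestral = anc, samples = samples, truth = truth, support = support)
}
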