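#' Recover planted insertion/excision events from a simulated dataset
#'
#' Runs the honest end-to-end pipeline on a [simulate_dataset()] bundle:
#' each derived genome is annotated from the family consensus library with
#' [annotate_tes()] (no truth-table peeking), then empty sites are called in
#' both directions per sample — ancestral TEs against the derived genome
#' (detects excisions) and derived TEs against the ancestral genome (detects
#' insertions). Confirmed calls are matched to planted clean events by
#' junction proximity.
#'
#' @param sim a [simulate_dataset()] result.
#' @param match_tol junction matching tolerance in bp.
#' @param ... passed to [find_empty_sites()].
#' @return `list(n_events=, n_recovered=, n_false=, recovery=, calls=,
#'   matched=)`; `recovery` is the recovered fraction of planted clean
#'   insertions + excisions, `n_false` the confirmed calls matching no
#'   planted event.
#' @export
evaluate_empty_site_recovery <- function(sim, match_tol = 100, ...) {
  anc <- sim$ancestral
  all_calls <- list()
  for (smp in names(sim$samples)) {
    derived <- sim$samples[[smp]]$genome
    derived_ann <- annotate_tes(derived, anc$library)
    fw <- find_empty_sites(anc$genome, anc$annotations, derived, ...)
    bw <- find_empty_sites(derived, derived_ann, anc$genome, ...)
    fw$direction <- rep("ancestral_te_vs_derived", nrow(fw))
    fw$sample <- rep(smp, nrow(fw))
    bw$direction <- rep("derived_te_vs_ancestral", nrow(bw))
    bw$sample <- rep(smp, nrow(bw))
    all_calls[[smp]] <- rbind(fw, bw)
  }
  calls <- do.call(rbind, all_calls)
  rownames(calls) <- NULL
  conf <- calls[calls$status == "confirmed", , drop = FALSE]
  truth <- sim$truth
  clean <- truth[truth$type %in% c("insertion", "excision"), , drop = FALSE]
  matched <- logical(nrow(clean))
  call_used <- logical(nrow(conf))
  for (i in seq_len(nrow(clean))) {
    ev <- clean[i, ]
    if (ev$type == "excision") {
      # expect: ancestral TE queried against that sample's derived genome,
      # junction near the derived deletion point
      cand <- which(!call_used & conf$direction == "ancestral_te_vs_derived" &
                      conf$sample == ev$sample_id &
                      conf$target_contig == ev$contig &
                      abs(conf$junction - ev$derived_start) <= match_tol)
    } else {
      # insertion: derived TE queried against the ancestral genome,
      # junction near the ancestral target site
      cand <- which(!call_used & conf$direction == "derived_te_vs_ancestral" &
                      conf$sample == ev$sample_id &
                      conf$target_contig == ev$contig &
                      abs(conf$junction - ev$anc_start) <= match_tol)
    }
    if (length(cand)) { matched[i] <- TRUE; call_used[cand[1]] <- TRUE }
  }
  # a confirmed call is false only if it matches no planted event at all
  # (several donor copies can legitimately report the same locus)
  is_false <- vapply(seq_len(nrow(conf)), function(j) {
    cj <- conf[j, ]
    any_match <- FALSE
    for (i in seq_len(nrow(clean))) {
      ev <- clean[i, ]
      near <- if (ev$type == "excision")
        cj$direction == "ancestral_te_vs_derived" &&
          cj$sample == ev$sample_id && cj$target_contig == ev$contig &&
          abs(cj$junction - ev$derived_start) <= match_tol
      else
        cj$direction == "derived_te_vs_ancestral" &&
          cj$sample == ev$sample_id && cj$target_contig == ev$contig &&
          abs(cj$junction - ev$anc_start) <= match_tol
      if (near) { any_match <- TRUE; break }
    }
    !any_match
  }, logical(1))
  list(n_events = nrow(clean), n_recovered = sum(matched),
       n_false = sum(is_false), recovery = mean(matched),
       calls = calls, matched = matched)
}
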