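# a compact simulation configuration for module-level tests: one contig,
# a couple of planted copies, no derived events
small_cfg <- function(n_copies = 3, contig_length = 40000) {
  sim_config(
    n_contigs = 1, contig_length = contig_length,
    te_library = list(
      hAT_auto = list(class = "DNA_TIR", length = 600, tir_len = 28,
                      tir_group = "hAT", tsd_len = 8, autonomous = TRUE,
                      n_ancestral = n_copies)),
    plans = list(P1 = list(n_insertions = 0, n_excisions = 0, n_solo_ltr = 0,
                           n_nahr = 0, n_inversions = 0)))
}
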