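# Small in-code fixtures shared across tests.

toy_map <- function(k = 2, chrom = paste0("chr_", seq_len(k)), pos = rep(0, k)) {
  linkage_map(paste0("L", seq_len(k)), chrom, pos)
}

# two inbreds differing everywhere, plus their F1
toy_cross <- function(map) {
  p1 <- inbred_line("A", map)
  p2 <- inbred_line("C", map)
  list(p1 = p1, p2 = p2, f1 = make_f1(p1, p2))
}

toy_effects <- function(locus, effect, parent = "C", trait = "GY",
                        environment = "MET") {
  data.frame(locus_id = locus, trait = trait, environment = environment,
             additive_effect = effect, increasing_parent = parent,
             provenance = "synthetic", stringsAsFactors = FALSE)
}
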