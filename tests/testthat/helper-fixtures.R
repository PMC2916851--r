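# Small maps and configs shared across tests.

two_marker_map <- function(dist_kb = 320, scaffold = "sc1") {
  marker_map(scaffold = rep(scaffold, 2), marker = c("mA", "mB"),
             position_kb = c(100, 100 + dist_kb))
}

quiet_config <- function(...) {
  # no conversions, no diploids, single-spore recovery
  sim_config(conversion_rate_per_marker = 0, p_diploid = 0,
             p_recover_both_spores = 0, ...)
}

no_event_config <- function() {
  sim_config(kb_per_cM_baseline = 1e12, conversion_rate_per_marker = 0,
             p_diploid = 0, p_recover_both_spores = 0)
}

# Expected Haldane recombination fraction for a physical distance under a
# given map density.
expected_rf <- function(dist_kb, kb_per_cM) {
  m <- dist_kb / (100 * kb_per_cM)  # Morgans
  (1 - exp(-2 * m)) / 2
}
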