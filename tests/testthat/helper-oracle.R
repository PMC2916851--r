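# Independent brute-force oracle for the NG86 statistic: depth-first
# enumeration of all single-step mutational pathways between two codons and
# exhaustive single-base-neighbour site counting. Written against
# Biostrings::GENETIC_CODE directly, independent of the package internals.

oracle_code <- local({
  code <- Biostrings::GENETIC_CODE
  names(code) <- gsub("U", "T", names(code))
  code
})

oracle_sense_codons <- names(oracle_code)[oracle_code != "*"]

oracle_syn_sites <- function(codon) {
  bases <- c("A", "C", "G", "T")
  n_syn <- 0L
  for (pos in 1:3) {
    for (b in bases) {
      if (b == substr(codon, pos, pos)) next
      alt <- codon
      substr(alt, pos, pos) <- b
      if (oracle_code[[alt]] == oracle_code[[codon]]) n_syn <- n_syn + 1L
    }
  }
  n_syn / 3
}

# All pathways cur -> target, one differing position at a time, pruning
# branches that pass through a stop codon. Returns a list of c(s, n) step
# counts, one per surviving pathway.
oracle_paths <- function(cur, target, allow_stops = FALSE) {
  diff_pos <- which(strsplit(cur, "")[[1L]] != strsplit(target, "")[[1L]])
  if (!length(diff_pos)) return(list(c(s = 0, n = 0)))
  out <- list()
  for (p in diff_pos) {
    nxt <- cur
    substr(nxt, p, p) <- substr(target, p, p)
    if (!allow_stops && oracle_code[[nxt]] == "*") next
    syn_step <- oracle_code[[nxt]] == oracle_code[[cur]]
    for (tail_counts in oracle_paths(nxt, target, allow_stops)) {
      out[[length(out) + 1L]] <- tail_counts +
        c(s = as.numeric(syn_step), n = as.numeric(!syn_step))
    }
  }
  out
}

oracle_pair <- function(c1, c2) {
  S <- (oracle_syn_sites(c1) + oracle_syn_sites(c2)) / 2
  paths <- oracle_paths(c1, c2)
  if (!length(paths)) paths <- oracle_paths(c1, c2, allow_stops = TRUE)
  m <- do.call(rbind, paths)
  list(S_sites = S, N_sites = 3 - S,
       S_diffs = mean(m[, "s"]), N_diffs = mean(m[, "n"]))
}
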