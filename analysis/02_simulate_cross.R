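#!/usr/bin/env Rscript
# Simulates the study cross: one chromosome carrying both MAT regions (the
# two reference scaffolds joined at the IsocL-PAN6 junction) plus four
# autosomal scaffolds, a recombination hotspot (0.63 kb/cM over 27 kb) on
# the MIP side of the HD1/HD2 pair, a suppressed interval between HD1/HD2
# and PAN6, a 32 kb/cM background, sparse gene conversion, and teliospore
# packaging with asynchronous basidiospore germination and rare diploids.
# Writes (a) an eight-teliospore experiment mirroring the study's scale and
# (b) a 400-teliospore experiment for the mapping analyses of script 03.

suppressPackageStartupMessages(library(pseudobipolar))

out_dir <- "results"
if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
seed <- 101L

map <- mat_cross_map()
cfg <- sim_config(hotspots = mat_cross_hotspots())

small <- simulate_cross_experiment(map, cfg, n_teliospores = 8L,
                                   colonies_per_teliospore = 4L, seed = seed)
write_tsv_table(small$progeny, file.path(out_dir, "cross_progeny_8.tsv"))

large <- simulate_cross_experiment(map, cfg, n_teliospores = 400L,
                                   colonies_per_teliospore = 1L, seed = seed + 1L)
write_tsv_table(large$progeny, file.path(out_dir, "cross_progeny_400.tsv"))
write_tsv_table(as.data.frame(map), file.path(out_dir, "marker_map.tsv"))

outcomes <- table(vapply(large$truth, `[[`, "", "outcome"))
n_xo <- sum(vapply(large$truth, function(t) nrow(t$crossovers), integer(1)))
n_conv <- sum(vapply(large$truth, function(t) nrow(t$conversions), integer(1)))
truth_summary <- list(seed = seed + 1L, n_teliospores = 400L,
                      outcomes = as.list(outcomes),
                      total_crossovers = n_xo,
                      total_conversion_tracts = n_conv)
jsonlite::write_json(truth_summary, file.path(out_dir, "cross_truth_summary.json"),
                     auto_unbox = TRUE, pretty = TRUE)
write_manifest(out_dir, list(map = "mat_cross_map",
                             hotspots = "mat_cross_hotspots",
                             baseline_kb_per_cM = 32), seed)

cat("8-teliospore experiment:", nrow(small$progeny), "colonies;",
    "outcomes:", paste(names(table(vapply(small$truth, `[[`, "", "outcome"))),
                       table(vapply(small$truth, `[[`, "", "outcome")),
                       collapse = ", "), "\n")
cat("400-teliospore experiment:", n_xo, "true crossovers,", n_conv,
    "conversion tracts logged\n")
cat("wrote results/cross_progeny_{8,400}.tsv, marker_map.tsv,",
    "cross_truth_summary.json\n")
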