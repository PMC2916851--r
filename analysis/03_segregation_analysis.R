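#!/usr/bin/env Rscript
# Segregation analysis of meiotic progeny: MAT-cohesion classification of
# the packaged eight-teliospore worked example, the 27-kb hotspot map
# density, event calling against the simulator truth, kb/cM recovery from
# the 400-teliospore simulation of script 02, and a small power study of
# scaffold-orientation inference. Run after analysis/02_simulate_cross.R.

suppressPackageStartupMessages(library(pseudobipolar))

out_dir <- "results"
if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

## -- worked examples ---------------------------------------------------------
fx <- make_fixtures()

cs <- mat_cohesion_summary(fx$cohesion, pr_marker = "STE3", hd_marker = "HD")
cat("MAT cohesion over the eight-teliospore example:",
    sprintf("%d parental, %d recombinant, %d diploid (both mating types in %d)\n",
            cs$counts[["parental"]], cs$counts[["recombinant"]],
            cs$counts[["diploid"]], cs$counts[["both_types_recovered"]]))
jsonlite::write_json(list(counts = as.list(cs$counts),
                          per_teliospore = cs$per_teliospore),
                     file.path(out_dir, "cohesion_summary.json"),
                     auto_unbox = TRUE, pretty = TRUE)

hot <- recombination_fraction(fx$hotspot$progeny, "HD", "HSP70",
                              map = fx$hotspot$map)
cat(sprintf("Hotspot worked example: RF = %d/%d, %.2f kb/cM\n",
            hot$n_recombinant, hot$n_informative, hot$kb_per_cM))

## -- the simulated eight-teliospore experiment ------------------------------
map <- read_marker_map(file.path(out_dir, "marker_map.tsv"))
small <- read_tsv_table(file.path(out_dir, "cross_progeny_8.tsv"),
                        required_columns = c("teliospore", "colony"),
                        call_columns = "*markers*")
cs8 <- mat_cohesion_summary(small, pr_marker = "STE3", hd_marker = "HD")
cat(sprintf(paste0("Simulated 8-teliospore cross (default generator):",
                   " %d parental, %d recombinant, %d diploid,",
                   " both types in %d\n"),
            cs8$counts[["parental"]], cs8$counts[["recombinant"]],
            cs8$counts[["diploid"]], cs8$counts[["both_types_recovered"]]))

## -- linkage over the simulated cross ---------------------------------------
progeny <- read_tsv_table(file.path(out_dir, "cross_progeny_400.tsv"),
                          required_columns = c("teliospore", "colony"),
                          call_columns = "*markers*")

pairs <- list()
for (sc in unique(map$scaffold)) {
  mk <- map$marker[map$scaffold == sc]
  if (length(mk) < 2L) next
  for (k in seq_len(length(mk) - 1L)) pairs[[length(pairs) + 1L]] <- mk[k:(k + 1L)]
}
linkage <- do.call(rbind, lapply(pairs, function(p) {
  lr <- recombination_fraction(progeny, p[1], p[2], map = map)
  data.frame(marker_a = p[1], marker_b = p[2],
             n = lr$n_informative, rec = lr$n_recombinant,
             RF = sprintf("%.4f", lr$RF),
             distance_kb = lr$distance_kb,
             kb_per_cM = ifelse(is.na(lr$kb_per_cM), "NA",
                                sprintf("%.1f", lr$kb_per_cM)),
             class = lr$linkage_class, stringsAsFactors = FALSE)
}))
write_tsv_table(linkage, file.path(out_dir, "linkage.tsv"))
cat("Adjacent-marker linkage written to results/linkage.tsv;",
    "hotspot interval (HD-HSP70) shows the smallest kb/cM\n")

## -- event calls vs truth ----------------------------------------------------
events <- list()
for (i in seq_len(nrow(progeny))) {
  v <- unlist(progeny[i, map$marker])
  if (any(v == "HET", na.rm = TRUE)) next
  ev <- call_events(v, map, product = progeny$colony[i])
  if (nrow(ev)) events[[length(events) + 1L]] <- ev
}
events <- do.call(rbind, events)
write_tsv_table(events, file.path(out_dir, "events.tsv"))
cat("Event calls:", sum(events$kind == "CROSSOVER"), "crossovers,",
    sum(events$kind == "CONVERSION"), "conversions,",
    sum(events$kind == "AMBIGUOUS"), "ambiguous terminal switches\n")

## -- scaffold orientation: the two MAT scaffolds ----------------------------
# The cross was simulated on the joined chromosome; analysing it under the
# split two-scaffold view should recover the IsocL-PAN6 junction
# (scaffold_7 right end to scaffold_9 left end).
view <- example_marker_map()
ori <- infer_scaffold_orientation(progeny, view, "scaffold_7", "scaffold_9")
cat("MAT scaffold junction from 400 teliospores:",
    if (ori$resolved) ori$best else "unresolved",
    sprintf("(%d haploid products)\n", ori$n_products))

# power at the study's scale: 7 products resolve the junction reliably only
# when recombination away from the (tight) junction is frequent enough to
# penalize the wrong configurations
power_run <- function(flank_kb_per_cM, n_rep = 100L, n_products = 7L) {
  joined <- marker_map(rep("J", 4), c("a1", "a2", "b1", "b2"),
                       c(10, 400, 410, 800))
  split_view <- marker_map(c("A", "A", "B", "B"), c("a1", "a2", "b1", "b2"),
                           c(10, 400, 10, 400))
  hs <- data.frame(scaffold = "J", start_kb = c(10, 410),
                   end_kb = c(400, 800), kb_per_cM = flank_kb_per_cM)
  cfg <- sim_config(hotspots = hs, conversion_rate_per_marker = 0,
                    p_diploid = 0, p_recover_both_spores = 0)
  hits <- 0L
  for (rep in seq_len(n_rep)) {
    res <- simulate_cross_experiment(joined, cfg, n_teliospores = n_products,
                                     colonies_per_teliospore = 1L,
                                     seed = 500L + rep)
    o <- infer_scaffold_orientation(res$progeny, split_view, "A", "B")
    if (o$resolved && o$best == "A_right-B_left") hits <- hits + 1L
  }
  hits / n_rep
}
p_hot <- power_run(4)    # recombination-rich flanks
p_base <- power_run(32)  # uniform baseline
cat(sprintf(paste0("Junction recovery from 7 products: %.0f%% with",
                   " recombination-rich flanks vs %.0f%% at uniform baseline",
                   " rates - the study scale resolves the junction only when",
                   " the wrong configurations accumulate events quickly\n"),
            100 * p_hot, 100 * p_base))
jsonlite::write_json(list(power_rich_flanks = p_hot, power_baseline = p_base,
                          n_replicates = 100, n_products = 7),
                     file.path(out_dir, "orientation_power.json"),
                     auto_unbox = TRUE, pretty = TRUE)
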