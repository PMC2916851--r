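test_that("a no-event meiosis yields four pure parental products in a 2:2 ratio", {
  # single chromosome: with no crossovers and no conversions the four
  # products are entirely parental, two of each
  map <- marker_map(rep("s1", 4), c("m1", "m2", "m3", "m4"), c(10, 200, 400, 800))
  set.seed(1)
  mei <- simulate_meiosis(map, no_event_config())
  expect_equal(nrow(mei$crossovers), 0L)
  expect_equal(nrow(mei$conversions), 0L)
  per_product <- apply(mei$products, 1L, unique)
  expect_true(all(lengths(per_product) == 1L))
  expect_equal(sort(unlist(per_product)), c("P1", "P1", "P2", "P2"))
  # multi-chromosome map: purity holds per scaffold (chromosomes assort
  # independently), and the 2:2 ratio holds at every marker
  full <- example_marker_map()
  set.seed(2)
  mei2 <- simulate_meiosis(full, no_event_config())
  for (sc in unique(full$scaffold)) {
    sub <- mei2$products[, full$marker[full$scaffold == sc], drop = FALSE]
    expect_true(all(apply(sub, 1L, function(v) length(unique(v)) == 1L)))
  }
  expect_true(all(apply(mei2$products, 2L, function(v) sum(v == "P1")) == 2L))
})

test_that("meiotic products are reciprocal: 2:2 at every marker before conversion", {
  map <- example_marker_map()
  cfg <- quiet_config()
  set.seed(11)
  for (i in 1:30) {
    mei <- simulate_meiosis(map, cfg)
    counts <- apply(mei$products, 2L, function(col) sum(col == "P1"))
    expect_true(all(counts == 2L))
  }
})

test_that("conversions break the 2:2 ratio only at markers covered by logged tracts", {
  map <- example_marker_map()
  cfg <- sim_config(conversion_rate_per_marker = 0.1,
                    conversion_tract_mean_kb = 1, p_diploid = 0,
                    p_recover_both_spores = 0)
  set.seed(5)
  for (i in 1:20) {
    mei <- simulate_meiosis(map, cfg)
    counts <- apply(mei$products, 2L, function(col) sum(col == "P1"))
    skewed <- map$marker[counts != 2L]
    covered <- character(0)
    if (nrow(mei$conversions)) {
      for (k in seq_len(nrow(mei$conversions))) {
        cv <- mei$conversions[k, ]
        covered <- c(covered, map$marker[map$scaffold == cv$scaffold &
                                           map$position_kb >= cv$start_kb &
                                           map$position_kb <= cv$end_kb])
      }
    }
    expect_true(all(skewed %in% covered))
  }
})

test_that("recombinant fraction between two markers follows Haldane's map function", {
  map <- two_marker_map(dist_kb = 320)
  cfg <- quiet_config()  # baseline 32 kb/cM -> 10 cM
  set.seed(20)
  n_mei <- 2500L
  rec <- 0L
  for (i in seq_len(n_mei)) {
    prods <- simulate_meiosis(map, cfg)$products
    rec <- rec + sum(prods[, "mA"] != prods[, "mB"])
  }
  n_prod <- 4L * n_mei
  rf_hat <- rec / n_prod
  rf_exp <- expected_rf(320, 32)  # (1 - exp(-0.2)) / 2
  se <- sqrt(rf_exp * (1 - rf_exp) / n_prod)
  expect_lt(abs(rf_hat - rf_exp), 4 * se)
})

test_that("forced conversions appear as logged single-marker overwrites", {
  map <- example_marker_map()
  cfg <- sim_config(conversion_rate_per_marker = 1,
                    conversion_tract_mean_kb = 1e-4, p_diploid = 0,
                    p_recover_both_spores = 0)
  set.seed(9)
  mei <- simulate_meiosis(map, cfg)
  # every marker of every product initiates a tract too short to reach a
  # neighbouring marker
  expect_equal(nrow(mei$conversions), 4L * nrow(map))
  expect_true(all(mei$conversions$n_markers_changed == 1L))
})

test_that("crossover density inside a hotspot far exceeds the baseline", {
  map <- example_marker_map()
  cfg <- quiet_config(hotspots = example_hotspots())
  set.seed(31)
  inside <- 0L; outside <- 0L
  for (i in 1:1000) {
    xo <- simulate_meiosis(map, cfg)$crossovers
    xo <- xo[xo$scaffold == "scaffold_7", , drop = FALSE]
    in_hot <- xo$position_kb >= 250 & xo$position_kb <= 277
    inside <- inside + sum(in_hot)
    outside <- outside + sum(!in_hot)
  }
  span_in <- 27
  span_out <- (400 - 10) - span_in
  expect_gt(inside / span_in, 10 * (outside / span_out))
})

test_that("teliospore packaging follows the binucleate-spore recovery model", {
  map <- example_marker_map()
  set.seed(2)
  mei <- simulate_meiosis(map, quiet_config())

  set.seed(3)
  dip <- package_teliospore(mei$products, sim_config(p_diploid = 1))
  expect_identical(dip$outcome, "DIPLOID")
  expect_true(all(dip$genotypes == "HET"))

  set.seed(4)
  one <- package_teliospore(mei$products,
                            sim_config(p_diploid = 0, p_recover_both_spores = 0))
  expect_identical(one$outcome, "HAPLOID_ONE_SPORE")
  expect_equal(nrow(one$genotypes), 1L)

  set.seed(5)
  both <- package_teliospore(mei$products,
                             sim_config(p_diploid = 0, p_recover_both_spores = 1))
  expect_identical(both$outcome, "HAPLOID_BOTH_SPORES")
  expect_equal(nrow(both$genotypes), 2L)
  # the two products come from different basidiospores, hence different nuclei
  expect_equal(length(unique(both$product_ids)), 2L)

  expect_error(package_teliospore(mei$products[1:3, ], sim_config()), "4-row")
})

test_that("a simulated cross experiment has the study's table structure", {
  map <- example_marker_map()
  res <- simulate_cross_experiment(map, quiet_config(), n_teliospores = 8L,
                                   colonies_per_teliospore = 3L, seed = 1L)
  expect_equal(nrow(res$progeny), 24L)
  expect_equal(length(res$truth), 8L)
  # colonies within a teliospore are clones of at most two products
  for (tid in unique(res$progeny$teliospore)) {
    sub <- res$progeny[res$progeny$teliospore == tid, map$marker, drop = FALSE]
    expect_lte(nrow(unique(sub)), 2L)
  }
  # rate-0 config on one chromosome: every colony is pure parental
  map1 <- two_marker_map()
  res0 <- simulate_cross_experiment(map1, no_event_config(), n_teliospores = 4L,
                                    colonies_per_teliospore = 3L, seed = 2L)
  calls <- as.matrix(res0$progeny[, map1$marker])
  expect_true(all(apply(calls, 1L, function(v) length(unique(v)) == 1L)))
  # reproducibility
  res_again <- simulate_cross_experiment(map, quiet_config(), n_teliospores = 8L,
                                         colonies_per_teliospore = 3L, seed = 1L)
  expect_identical(res$progeny, res_again$progeny)
})

test_that("synthesized codon alignments honour their domain omegas", {
  # omega -> 0: no nonsynonymous substitutions accepted
  spec0 <- data.frame(name = "all", length_codons = 120L, omega = 1e-9,
                      subs_per_codon = 0.6)
  aln0 <- synthesize_coding_alignment(4L, spec0, seed = 2L)
  for (i in 1:3) {
    for (j in (i + 1):4) {
      p <- ng86_pair(aln0[[i]], aln0[[j]])
      expect_equal(p$N_diffs, 0)
      expect_gt(p$S_diffs, 0)
    }
  }
  # no stop codons anywhere
  code <- Biostrings::GENETIC_CODE
  names(code) <- gsub("U", "T", names(code))
  for (s in aln0) {
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    expect_false(any(code[cods] == "*"))
  }
  # degenerate input: a single allele
  one <- synthesize_coding_alignment(1L, default_domain_spec(), seed = 1L)
  expect_length(one, 1L)
  # three-domain gene recovers the omega ordering N-terminal > C-terminal > HD
  aln <- synthesize_coding_alignment(9L, default_domain_spec(), seed = 7L)
  dom <- domain_dnds(aln)
  ratios <- setNames(dom$dN_dS, dom$name)
  expect_gt(ratios[["N-terminal"]], ratios[["C-terminal"]])
  expect_gt(ratios[["C-terminal"]], ratios[["homeodomain"]])
})
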