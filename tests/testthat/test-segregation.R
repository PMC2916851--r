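parent1 <- c(STE3 = "a1", HD = "h1", M1 = "x1", M2 = "y1")
parent2 <- c(STE3 = "a2", HD = "h2", M1 = "x2", M2 = "y2")

test_that("parental origin assignment handles P1/P2/HET/missing and bad input", {
  raw <- data.frame(teliospore = c("T1", "T1", "T2"),
                    colony = c("T1.1", "T1.2", "T2.1"),
                    STE3 = c("a1", "a1/a2", "a2"),
                    HD = c("h1", "h2/h1", NA),
                    M1 = c("x1", "x1/x2", "x2"),
                    M2 = c("y1", "y2/y1", "y2"),
                    stringsAsFactors = FALSE)
  out <- assign_origin(raw, parent1, parent2)
  expect_equal(unlist(out[1, c("STE3", "HD", "M1", "M2")], use.names = FALSE),
               rep("P1", 4))
  expect_equal(unlist(out[2, c("STE3", "HD", "M1", "M2")], use.names = FALSE),
               rep("HET", 4))
  expect_true(is.na(out$HD[3]))
  expect_equal(out$STE3[3], "P2")

  expect_error(assign_origin(raw[, -6], parent1[1:3], parent2[1:3]),
               NA)  # M2 removed from both table and parents is fine
  expect_error(assign_origin(raw, parent1[1:3], parent2[1:3]), "absent")
  bad <- raw; bad$STE3[1] <- "weird"
  expect_error(assign_origin(bad, parent1, parent2), "neither parent")
  # identical parental alleles are dropped with a warning
  p2_same <- parent2; p2_same[["M2"]] <- "y1"
  expect_warning(dropped <- assign_origin(raw, parent1, p2_same), "identical")
  expect_false("M2" %in% names(dropped))
})

test_that("diploid detection uses the informative-marker HET fraction", {
  expect_true(detect_diploid(rep("HET", 13)))
  expect_false(detect_diploid(rep("P1", 13)))
  one_het <- c(rep("P1", 13), "HET")
  expect_false(detect_diploid(one_het))           # default: all must be HET
  expect_true(detect_diploid(one_het, min_het_fraction = 1 / 14))
  expect_true(detect_diploid(c("HET", "HET", NA)))  # missing are uninformative
  expect_false(detect_diploid(c(NA_character_, NA_character_)))
})

test_that("event calling follows minimal-event parsimony", {
  map4 <- marker_map(rep("s1", 4), c("m1", "m2", "m3", "m4"),
                     c(10, 40, 70, 100))

  xo <- call_events(c(m1 = "P1", m2 = "P1", m3 = "P2", m4 = "P2"), map4)
  expect_equal(xo$kind, "CROSSOVER")
  expect_equal(xo$start_kb, 40)
  expect_equal(xo$end_kb, 70)

  conv <- call_events(c(m1 = "P1", m2 = "P2", m3 = "P1", m4 = "P1"), map4)
  expect_equal(conv$kind, "CONVERSION")
  expect_equal(conv$markers, "m2")

  # an internal two-marker run is not a conversion at the default limit:
  # two crossovers are the parsimonious call once terminal runs are segments
  two <- call_events(c(m1 = "P1", m2 = "P2", m3 = "P2", m4 = "P1"), map4,
                     terminal_ambiguous = FALSE)
  expect_equal(two$kind, c("CROSSOVER", "CROSSOVER"))
  # with the terminal-ambiguity flag (default), the same single-marker
  # terminal runs are flagged AMBIGUOUS instead: one flank is unobserved
  amb <- call_events(c(m1 = "P1", m2 = "P2", m3 = "P2", m4 = "P1"), map4)
  expect_equal(sort(amb$kind), c("AMBIGUOUS", "AMBIGUOUS"))

  # conversion span limit: a physically wide internal run is not a conversion
  wide <- call_events(c(m1 = "P1", m2 = "P2", m3 = "P2", m4 = "P1"), map4,
                      max_conversion_markers = 2, max_conversion_kb = 10,
                      terminal_ambiguous = FALSE)
  expect_equal(wide$kind, c("CROSSOVER", "CROSSOVER"))
  narrow <- call_events(c(m1 = "P1", m2 = "P2", m3 = "P2", m4 = "P1"), map4,
                        max_conversion_markers = 2, max_conversion_kb = 100,
                        terminal_ambiguous = FALSE)
  expect_equal(narrow$kind, "CONVERSION")

  # missing markers are skipped and widen the crossover interval; the lone
  # observed P1 is terminal, so its switch is a crossover only when the
  # terminal-ambiguity flag is off
  gap <- call_events(c(m1 = "P1", m2 = NA, m3 = "P2", m4 = "P2"), map4,
                     terminal_ambiguous = FALSE)
  expect_equal(gap$kind, "CROSSOVER")
  expect_equal(gap$start_kb, 10)
  expect_equal(gap$end_kb, 70)
  gap_amb <- call_events(c(m1 = "P1", m2 = NA, m3 = "P2", m4 = "P2"), map4)
  expect_equal(gap_amb$kind, "AMBIGUOUS")

  # alternating single-marker mismatches resolve to two conversions on a
  # constant background, not three events
  alt <- call_events(c(m1 = "P1", m2 = "P2", m3 = "P1", m4 = "P2", m5 = "P1"),
                     marker_map(rep("s1", 5), paste0("m", 1:5),
                                c(10, 40, 70, 100, 130)))
  expect_equal(sort(alt$markers[alt$kind == "CONVERSION"]), c("m2", "m4"))
  expect_equal(nrow(alt), 2L)

  expect_error(call_events(c(m1 = "HET", m2 = "P1", m3 = "P1", m4 = "P1"), map4),
               "detect_diploid")

  # idempotence under P1/P2 relabeling: same kinds and intervals
  v <- c(m1 = "P1", m2 = "P2", m3 = "P1", m4 = "P1")
  flip <- ifelse(v == "P1", "P2", "P1")
  names(flip) <- names(v)
  e1 <- call_events(v, map4)
  e2 <- call_events(flip, map4)
  expect_equal(e1[, c("kind", "scaffold", "start_kb", "end_kb", "markers")],
               e2[, c("kind", "scaffold", "start_kb", "end_kb", "markers")])
})

test_that("recombination fractions reproduce the hotspot worked example", {
  fx <- make_fixtures()
  lr <- recombination_fraction(fx$hotspot$progeny, "HD", "HSP70",
                               map = fx$hotspot$map)
  expect_equal(lr$n_informative, 7L)
  expect_equal(lr$n_recombinant, 3L)
  expect_equal(lr$RF, 3 / 7)
  expect_equal(lr$map_distance_cM, 300 / 7)
  expect_equal(lr$kb_per_cM, 0.63, tolerance = 1e-12)

  # 0 recombinants: RF = 0, map density undefined
  all_par <- fx$hotspot$progeny
  all_par$HSP70 <- all_par$HD
  lr0 <- recombination_fraction(all_par, "HD", "HSP70", map = fx$hotspot$map)
  expect_equal(lr0$RF, 0)
  expect_true(is.na(lr0$kb_per_cM))
  expect_equal(lr0$linkage_class, "LINKED")

  # diploids and missing calls are not informative
  with_dip <- rbind(fx$hotspot$progeny,
                    data.frame(teliospore = "T8", colony = "T8.1",
                               HD = "HET", HSP70 = "HET"))
  lr2 <- recombination_fraction(with_dip, "HD", "HSP70", map = fx$hotspot$map)
  expect_equal(lr2$n_informative, 7L)
  expect_error(recombination_fraction(with_dip[8, ], "HD", "HSP70"),
               "no informative")
})

test_that("RF estimates from simulated data converge to the Haldane expectation", {
  map <- two_marker_map(dist_kb = 320)
  res <- simulate_cross_experiment(map, quiet_config(), n_teliospores = 2500L,
                                   colonies_per_teliospore = 1L, seed = 8L)
  lr <- recombination_fraction(res$progeny, "mA", "mB", map = map)
  expect_lt(abs(lr$RF - expected_rf(320, 32)), 0.015)
})

test_that("the cohesion summary reproduces the eight-teliospore classification", {
  fx <- make_fixtures()
  cs <- mat_cohesion_summary(fx$cohesion, pr_marker = "STE3", hd_marker = "HD")
  expect_equal(cs$counts[["parental"]], 6L)
  expect_equal(cs$counts[["recombinant"]], 1L)
  expect_equal(cs$counts[["diploid"]], 1L)
  expect_equal(cs$counts[["both_types_recovered"]], 1L)
  per <- cs$per_teliospore
  expect_equal(per$class[per$teliospore == "T7"], "RECOMBINANT")
  expect_equal(per$class[per$teliospore == "T8"], "DIPLOID")
  expect_true(per$both_types_recovered[per$teliospore == "T1"])
  expect_equal(sum(per$both_types_recovered), 1L)
  # the three classes partition the teliospores
  expect_equal(sum(cs$counts[c("parental", "recombinant", "diploid")]), 8L)

  # all-parental table: no recombinants
  par_only <- fx$cohesion[fx$cohesion$teliospore %in% c("T2", "T3"), ]
  cs2 <- mat_cohesion_summary(par_only, "STE3", "HD")
  expect_equal(cs2$counts[["recombinant"]], 0L)
})

test_that("recombinant teliospore counts scale with the intra-MAT map distance", {
  # PR and HD 160 kb apart at 32 kb/cM: per-product recombination fraction
  # r = Haldane(5 cM); teliospore-level recombinant count is Binomial(n, r)
  map <- marker_map(rep("mat", 2), c("STE3", "HD"), c(100, 260))
  r_exp <- expected_rf(160, 32)
  n <- 400L
  res <- simulate_cross_experiment(map, quiet_config(), n_teliospores = n,
                                   colonies_per_teliospore = 1L, seed = 13L)
  cs <- mat_cohesion_summary(res$progeny, "STE3", "HD")
  k <- cs$counts[["recombinant"]]
  se <- sqrt(n * r_exp * (1 - r_exp))
  expect_lt(abs(k - n * r_exp), 4 * se)
})

test_that("crossover calls on noise-free products match the observable truth", {
  map <- example_marker_map()
  res <- simulate_cross_experiment(map, quiet_config(), n_teliospores = 150L,
                                   colonies_per_teliospore = 1L, seed = 17L)
  for (tid in names(res$truth)) {
    truth <- res$truth[[tid]]
    for (p in 1:4) {
      called <- call_events(truth$products[p, ], map,
                            max_conversion_markers = 0L, product = p)
      expect_true(all(called$kind == "CROSSOVER"))
      want <- truth_observable_crossovers(truth, map, p)
      called <- called[order(called$scaffold, called$start_kb), , drop = FALSE]
      expect_equal(nrow(called), nrow(want))
      if (nrow(want)) {
        expect_equal(called$scaffold, want$scaffold)
        expect_equal(called$start_kb, want$start_kb)
        expect_equal(called$end_kb, want$end_kb)
      }
    }
  }
  # no hallucinated events when nothing happened
  quiet <- simulate_cross_experiment(map, no_event_config(), n_teliospores = 10L,
                                     colonies_per_teliospore = 1L, seed = 19L)
  for (tid in names(quiet$truth)) {
    for (p in 1:4) {
      expect_equal(nrow(call_events(quiet$truth[[tid]]$products[p, ], map)), 0L)
    }
  }
})

test_that("scaffold orientation is inferred by minimal junction events", {
  map <- marker_map(c("A", "A", "B", "B"), c("m1", "m2", "m3", "m4"),
                    c(10, 500, 10, 500))
  # hand-enumerated two-product toy: one product switches origin exactly at
  # the A-right:B-left junction; the alternative junctions need more events
  tab <- data.frame(teliospore = c("T1", "T2"), colony = c("T1.1", "T2.1"),
                    m1 = c("P1", "P1"), m2 = c("P2", "P2"),
                    m3 = c("P2", "P2"), m4 = c("P1", "P2"),
                    stringsAsFactors = FALSE)
  ori <- infer_scaffold_orientation(tab, map, "A", "B")
  expect_true(ori$resolved)
  expect_equal(ori$best, "A_right-B_left")

  # all-parental products: every junction ties, unresolved
  par <- data.frame(teliospore = c("T1", "T2"), colony = c("T1.1", "T2.1"),
                    m1 = c("P1", "P2"), m2 = c("P1", "P2"),
                    m3 = c("P1", "P2"), m4 = c("P1", "P2"),
                    stringsAsFactors = FALSE)
  tie <- infer_scaffold_orientation(par, map, "A", "B")
  expect_false(tie$resolved)
  expect_equal(length(tie$best), 4L)

  # fewer than two haploid products: unresolved by construction
  single <- infer_scaffold_orientation(par[1, ], map, "A", "B")
  expect_false(single$resolved)
})
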