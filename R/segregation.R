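ORIGIN_CALLS <- c("P1", "P2", "HET")

marker_columns <- function(table) {
  setdiff(names(table), c("teliospore", "colony", "product"))
}

#' Assign parental origin to raw progeny alleles
#'
#' Converts raw allele calls into parental-origin calls by matching each
#' progeny allele against the two parental genotypes at every marker: `P1`
#' and `P2` for the respective parent's allele, `HET` when both parental
#' alleles are present (written `"a/b"` in the raw table), `NA` for missing
#' data. Markers at which the parents carry identical alleles are
#' uninformative and dropped with a warning.
#'
#' @param raw Data.frame with columns `teliospore`, `colony`, then one raw
#'   allele column per marker. Heterozygous calls are written
#'   `"allele1/allele2"` (order-free); missing calls are `NA`.
#' @param parent1,parent2 Named character vectors of parental alleles,
#'   covering every marker column of `raw`.
#' @return The progeny table of origin calls (same shape, marker cells in
#'   `P1`/`P2`/`HET`/`NA`).
#' @export
assign_origin <- function(raw, parent1, parent2) {
  markers <- marker_columns(raw)
  missing_parent <- markers[!(markers %in% names(parent1)) |
                              !(markers %in% names(parent2))]
  if (length(missing_parent)) {
    stop("markers absent from parental genotypes: ",
         paste(missing_parent, collapse = ", "), call. = FALSE)
  }
  uninformative <- markers[parent1[markers] == parent2[markers]]
  if (length(uninformative)) {
    warning("dropping markers with identical parental alleles: ",
            paste(uninformative, collapse = ", "), call. = FALSE)
    raw <- raw[, !(names(raw) %in% uninformative), drop = FALSE]
    markers <- setdiff(markers, uninformative)
  }
  out <- raw
  for (m in markers) {
    p1 <- parent1[[m]]; p2 <- parent2[[m]]
    out[[m]] <- vapply(raw[[m]], function(a) {
      if (is.na(a)) return(NA_character_)
      parts <- strsplit(a, "/", fixed = TRUE)[[1L]]
      if (length(parts) == 2L && setequal(parts, c(p1, p2))) return("HET")
      if (identical(a, p1)) return("P1")
      if (identical(a, p2)) return("P2")
      stop(sprintf("allele '%s' at marker '%s' matches neither parent", a, m),
           call. = FALSE)
    }, character(1), USE.NAMES = FALSE)
  }
  out
}

#' Detect a diploid (failed-meiosis) product
#'
#' A product is flagged diploid when it is heterozygous at at least
#' `min_het_fraction` of its informative (non-missing) markers; the default
#' requires every informative marker to carry both parental alleles.
#'
#' @param origin Character vector of origin calls (`P1`/`P2`/`HET`/`NA`).
#' @param min_het_fraction Required HET fraction among informative markers.
#' @return Logical scalar.
#' @export
detect_diploid <- function(origin, min_het_fraction = 1) {
  informative <- origin[!is.na(origin)]
  if (!length(informative)) return(FALSE)
  mean(informative == "HET") >= min_het_fraction
}

#' Call crossover and gene-conversion events along one haploid product
#'
#' Minimal-event parsimony per scaffold: maximal runs of constant parental
#' origin are delimited; an internal run of at most `max_conversion_markers`
#' markers spanning at most `max_conversion_kb` (necessarily flanked on both
#' sides by the opposite origin) is called a gene conversion; every remaining
#' origin switch between adjacent runs is a crossover placed in the interval
#' between its flanking informative markers. Runs touching a scaffold end
#' have one flank unobserved and cannot be conversions: short terminal runs
#' are reported `AMBIGUOUS` when `terminal_ambiguous` is `TRUE` (the default)
#' and otherwise yield a crossover at their internal boundary. Markers with
#' missing calls are skipped; an event spanning a missing marker widens its
#' interval accordingly.
#'
#' @param origin Named character vector of origin calls (`P1`/`P2`/`NA`),
#'   names matching markers of `map`; `HET` calls are an error (run
#'   [detect_diploid()] first).
#' @param map A [marker_map()].
#' @param max_conversion_markers Maximum run length (markers) callable as a
#'   conversion; 0 disables conversion calling.
#' @param max_conversion_kb Maximum physical span (kb) of a conversion run.
#' @param terminal_ambiguous Report short terminal runs as `AMBIGUOUS`.
#' @param product Optional product identifier copied into the output.
#' @return Data.frame with columns `kind` (`CROSSOVER`/`CONVERSION`/
#'   `AMBIGUOUS`), `scaffold`, `start_kb`, `end_kb`, `markers`
#'   (comma-separated supporting markers) and `product`.
#' @export
call_events <- function(origin, map, max_conversion_markers = 1L,
                        max_conversion_kb = Inf, terminal_ambiguous = TRUE,
                        product = NA_character_) {
  stopifnot(inherits(map, "marker_map"))
  if (is.null(names(origin))) {
    if (length(origin) != nrow(map)) {
      stop("unnamed origin vector must match the map length", call. = FALSE)
    }
    names(origin) <- map$marker
  }
  if (any(origin == "HET", na.rm = TRUE)) {
    stop("HET calls present; run detect_diploid() before event calling",
         call. = FALSE)
  }
  events <- list()
  add <- function(kind, scaffold, start_kb, end_kb, markers) {
    events[[length(events) + 1L]] <<- data.frame(
      kind = kind, scaffold = scaffold, start_kb = start_kb, end_kb = end_kb,
      markers = paste(markers, collapse = ","), product = product,
      stringsAsFactors = FALSE)
  }
  for (sc in unique(map$scaffold)) {
    sub <- map[map$scaffold == sc, , drop = FALSE]
    obs <- origin[sub$marker]
    keep <- !is.na(obs)
    obs <- obs[keep]
    pos <- sub$position_kb[keep]
    mk <- sub$marker[keep]
    if (length(obs) < 2L) next
    r <- rle(obs)
    n_runs <- length(r$lengths)
    if (n_runs == 1L) next
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    span <- pos[run_end] - pos[run_start]
    short <- r$lengths <= max_conversion_markers & span <= max_conversion_kb
    is_internal <- seq_len(n_runs) > 1L & seq_len(n_runs) < n_runs
    cand <- which(is_internal & short)
    # exact minimal-event labeling: choose which candidate runs to explain as
    # conversion tracts (candidates must be separated by a surviving run so
    # each tract stays flanked by the opposite origin); remaining switches
    # are crossovers. Among equal-count labelings, prefer conversions.
    best <- NULL
    n_cand <- length(cand)
    for (mask in 0:(2^n_cand - 1L)) {
      chosen <- cand[bitwAnd(mask, 2^(seq_len(n_cand) - 1L)) > 0L]
      if (length(chosen) > 1L && any(diff(chosen) == 1L)) next
      keep <- setdiff(seq_len(n_runs), chosen)
      merged <- list()
      for (k in keep) {
        last <- if (length(merged)) merged[[length(merged)]] else NULL
        if (!is.null(last) && r$values[k] == last$value) {
          merged[[length(merged)]]$last_raw <- k
        } else {
          merged[[length(merged) + 1L]] <- list(value = r$values[k],
                                                first_raw = k, last_raw = k)
        }
      }
      n_switch <- if (length(merged) < 2L) 0L else length(merged) - 1L
      cost <- length(chosen) + n_switch
      if (is.null(best) || cost < best$cost ||
          (cost == best$cost && length(chosen) > length(best$chosen))) {
        best <- list(cost = cost, chosen = chosen, merged = merged)
      }
    }
    for (k in best$chosen) {
      add("CONVERSION", sc, pos[run_start[k]], pos[run_end[k]],
          mk[run_start[k]:run_end[k]])
    }
    merged <- best$merged
    if (length(merged) < 2L) next
    # every boundary between merged runs is an origin switch: a crossover,
    # unless its outer side is a short terminal run (one flank unobserved)
    run_is_short <- function(m) {
      first <- run_start[m$first_raw]; last <- run_end[m$last_raw]
      (last - first + 1L) <= max_conversion_markers &&
        (pos[last] - pos[first]) <= max_conversion_kb
    }
    for (q in seq_len(length(merged) - 1L)) {
      a <- merged[[q]]; b <- merged[[q + 1L]]
      terminal_short <- (q == 1L && run_is_short(a)) ||
        (q + 1L == length(merged) && run_is_short(b))
      kind <- if (terminal_ambiguous && terminal_short) "AMBIGUOUS" else "CROSSOVER"
      left_i <- run_end[a$last_raw]
      right_i <- run_start[b$first_raw]
      add(kind, sc, pos[left_i], pos[right_i], c(mk[left_i], mk[right_i]))
    }
  }
  if (!length(events)) {
    return(data.frame(kind = character(0), scaffold = character(0),
                      start_kb = numeric(0), end_kb = numeric(0),
                      markers = character(0), product = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, events)
}

#' Collapse clonal colonies to distinct meiotic products
#'
#' Colonies of one teliospore sharing an identical genotype are mitotic
#' clones of the same meiotic product and are collapsed to a single row.
#'
#' @param table Progeny table (`teliospore`, `colony`, marker columns).
#' @return Data.frame with columns `teliospore`, `product` (running id within
#'   teliospore) and the marker columns.
#' @export
collapse_clonal_products <- function(table) {
  markers <- marker_columns(table)
  out <- list()
  for (tid in unique(table$teliospore)) {
    sub <- table[table$teliospore == tid, markers, drop = FALSE]
    sub <- unique(sub)
    sub <- cbind(data.frame(teliospore = tid,
                            product = sprintf("%s.p%d", tid, seq_len(nrow(sub))),
                            stringsAsFactors = FALSE),
                 sub)
    out[[length(out) + 1L]] <- sub
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Recombination fraction and map density between two markers
#'
#' Counts recombinant meiotic products between two markers over the
#' informative (haploid, non-missing at both markers) products of a progeny
#' table, with clonal colonies collapsed so each meiosis contributes one
#' product unless both basidiospores were recovered with distinct genotypes.
#' Map distance uses the small-sample convention `cM = 100 * RF` (no mapping
#' function), the arithmetic under which 3 recombinants among 7 products
#' across 27 kb gives 0.63 kb/cM. Linkage is classed `UNLINKED` when an exact
#' binomial test cannot reject RF = 1/2 at level `alpha`, otherwise `LINKED`
#' or `PARTIAL` by an RF cutoff.
#'
#' @param table Progeny table of origin calls.
#' @param marker_a,marker_b Marker names.
#' @param map Optional [marker_map()] supplying physical positions (needed
#'   for `kb_per_cM`; only defined for markers on one scaffold).
#' @param collapse_clones Collapse identical genotypes within a teliospore.
#' @param alpha Significance level of the exact binomial linkage test.
#' @param linked_rf_max RF at or below which a significantly linked pair is
#'   classed `LINKED` rather than `PARTIAL`.
#' @return A list of class `linkage_result`: `marker_a`, `marker_b`,
#'   `n_informative`, `n_recombinant`, `RF`, `map_distance_cM`,
#'   `distance_kb`, `kb_per_cM` (`NA` when RF = 0 or positions unavailable),
#'   `linkage_class`, `p_value`.
#' @export
recombination_fraction <- function(table, marker_a, marker_b, map = NULL,
                                   collapse_clones = TRUE, alpha = 0.05,
                                   linked_rf_max = 0.1) {
  markers <- marker_columns(table)
  if (!(marker_a %in% markers) || !(marker_b %in% markers)) {
    stop("both markers must be columns of the progeny table", call. = FALSE)
  }
  products <- if (collapse_clones) collapse_clonal_products(table) else table
  a <- products[[marker_a]]
  b <- products[[marker_b]]
  ok <- !is.na(a) & !is.na(b) & a != "HET" & b != "HET"
  n <- sum(ok)
  if (n == 0L) stop("no informative products for this marker pair", call. = FALSE)
  n_rec <- sum(a[ok] != b[ok])
  rf <- n_rec / n
  cm <- 100 * rf
  dist_kb <- NA_real_
  if (!is.null(map)) {
    ia <- match(marker_a, map$marker)
    ib <- match(marker_b, map$marker)
    if (!is.na(ia) && !is.na(ib) && map$scaffold[ia] == map$scaffold[ib]) {
      dist_kb <- abs(map$position_kb[ia] - map$position_kb[ib])
    }
  }
  kb_per_cm <- if (!is.na(dist_kb) && cm > 0) dist_kb / cm else NA_real_
  p_val <- stats::binom.test(n_rec, n, p = 0.5, alternative = "less")$p.value
  class_lab <- if (p_val >= alpha) "UNLINKED" else if (rf <= linked_rf_max) "LINKED" else "PARTIAL"
  structure(list(marker_a = marker_a, marker_b = marker_b,
                 n_informative = n, n_recombinant = n_rec, RF = rf,
                 map_distance_cM = cm, distance_kb = dist_kb,
                 kb_per_cM = kb_per_cm, linkage_class = class_lab,
                 p_value = p_val),
            class = "linkage_result")
}

#' @export
print.linkage_result <- function(x, ...) {
  cat(sprintf("<linkage %s - %s: RF = %d/%d = %.3f (%s)%s>\n",
              x$marker_a, x$marker_b, x$n_recombinant, x$n_informative, x$RF,
              x$linkage_class,
              if (!is.na(x$kb_per_cM)) sprintf(", %.2f kb/cM", x$kb_per_cM) else ""))
  invisible(x)
}

#' Classify teliospores by MAT cohesion
#'
#' Each teliospore is classed `DIPLOID` (a product carries both parental
#' alleles throughout), `RECOMBINANT` (some haploid product carries a
#' non-parental receptor-HD combination), or `PARENTAL` (cohesion between the
#' two MAT regions maintained); parental teliospores from which both parental
#' mating types were recovered (two distinct receptor-HD classes among the
#' colonies) are additionally counted as `both_types_recovered`.
#'
#' @param table Progeny table of origin calls.
#' @param pr_marker,hd_marker Column names of the pheromone receptor and
#'   HD1/HD2 markers.
#' @param phase `"cis"` when parent 1's receptor travels with parent 1's HD
#'   allele (origin-call tables are always cis by construction), `"trans"`
#'   otherwise.
#' @return A list: `counts` (named vector `parental`, `recombinant`,
#'   `diploid`, `both_types_recovered`; the first three partition the
#'   teliospores) and `per_teliospore` (data.frame of classifications).
#' @export
mat_cohesion_summary <- function(table, pr_marker = "STE3", hd_marker = "HD",
                                 phase = c("cis", "trans")) {
  phase <- match.arg(phase)
  markers <- marker_columns(table)
  if (!(pr_marker %in% markers) || !(hd_marker %in% markers)) {
    stop("PR and HD markers must be columns of the progeny table", call. = FALSE)
  }
  parental_pairs <- if (phase == "cis") {
    list(c("P1", "P1"), c("P2", "P2"))
  } else {
    list(c("P1", "P2"), c("P2", "P1"))
  }
  is_parental_combo <- function(pr, hd) {
    any(vapply(parental_pairs, function(p) pr == p[1L] && hd == p[2L], logical(1)))
  }
  products <- collapse_clonal_products(table)
  tids <- unique(products$teliospore)
  cls <- character(length(tids))
  both <- logical(length(tids))
  for (i in seq_along(tids)) {
    sub <- products[products$teliospore == tids[i], , drop = FALSE]
    mk <- sub[, marker_columns(sub), drop = FALSE]
    diploid <- any(apply(mk, 1L, function(v) detect_diploid(unname(v))))
    if (diploid) { cls[i] <- "DIPLOID"; next }
    pr <- sub[[pr_marker]]
    hd <- sub[[hd_marker]]
    ok <- !is.na(pr) & !is.na(hd) & pr != "HET" & hd != "HET"
    combos <- unique(paste(pr[ok], hd[ok]))
    non_parental <- any(!vapply(seq_len(sum(ok)), function(k) {
      is_parental_combo(pr[ok][k], hd[ok][k])
    }, logical(1)))
    if (non_parental) {
      cls[i] <- "RECOMBINANT"
    } else {
      cls[i] <- "PARENTAL"
      both[i] <- length(combos) >= 2L
    }
  }
  counts <- c(parental = sum(cls == "PARENTAL"),
              recombinant = sum(cls == "RECOMBINANT"),
              diploid = sum(cls == "DIPLOID"),
              both_types_recovered = sum(both))
  list(counts = counts,
       per_teliospore = data.frame(teliospore = tids, class = cls,
                                   both_types_recovered = both,
                                   stringsAsFactors = FALSE))
}

#' Infer the relative orientation of two scaffolds from segregation data
#'
#' Evaluates the four possible junction configurations (which end of scaffold
#' A adjoins which end of scaffold B) and returns the configuration(s) under
#' which the total number of origin switches (minimal crossover-equivalent
#' events) summed over all haploid products is smallest; ties are reported as
#' unresolved.
#'
#' @param table Progeny table of origin calls.
#' @param map A [marker_map()] covering both scaffolds.
#' @param scaffold_a,scaffold_b Scaffold names.
#' @return A list: `orientations` (data.frame with `junction` labels and
#'   total `events`), `best` (labels attaining the minimum), `resolved`
#'   (TRUE when unique) and `n_products`.
#' @export
infer_scaffold_orientation <- function(table, map, scaffold_a, scaffold_b) {
  stopifnot(inherits(map, "marker_map"))
  products <- collapse_clonal_products(table)
  markers <- marker_columns(products)
  mk <- products[, markers, drop = FALSE]
  haploid <- apply(mk, 1L, function(v) !any(v == "HET", na.rm = TRUE))
  products <- products[haploid, , drop = FALSE]
  a_mk <- map$marker[map$scaffold == scaffold_a]
  b_mk <- map$marker[map$scaffold == scaffold_b]
  a_mk <- a_mk[a_mk %in% markers]
  b_mk <- b_mk[b_mk %in% markers]
  if (!length(a_mk) || !length(b_mk)) {
    stop("no genotyped markers on one of the scaffolds", call. = FALSE)
  }
  configs <- list(
    "A_right-B_left" = c(a_mk, b_mk),
    "A_right-B_right" = c(a_mk, rev(b_mk)),
    "A_left-B_left" = c(rev(a_mk), b_mk),
    "A_left-B_right" = c(rev(a_mk), rev(b_mk))
  )
  count_switches <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) return(0L)
    sum(v[-1L] != v[-length(v)])
  }
  events <- vapply(configs, function(ord) {
    sum(vapply(seq_len(nrow(products)), function(i) {
      count_switches(unlist(products[i, ord], use.names = FALSE))
    }, integer(1)))
  }, integer(1))
  res <- data.frame(junction = names(configs), events = unname(events),
                    stringsAsFactors = FALSE)
  if (nrow(products) < 2L) {
    return(list(orientations = res, best = res$junction, resolved = FALSE,
                n_products = nrow(products)))
  }
  best <- res$junction[res$events == min(res$events)]
  list(orientations = res, best = best, resolved = length(best) == 1L,
       n_products = nrow(products))
}

#' Reduce a simulation truth log to marker-observable crossovers
#'
#' A marker-based caller can only see crossovers that change the parental
#' origin between two adjacent genotyped markers; an even number of
#' crossovers hitting the same product within one inter-marker interval
#' cancels and is invisible. The simulator logs, for every crossover, the two
#' products whose parental origin flips there, so for one product the
#' observable truth is the set of intervals containing an odd number of
#' crossovers involving it. Exact only for conversion-free simulations (gene
#' conversion rewrites markers after the crossover history).
#'
#' @param truth One element of the `truth` list from
#'   [simulate_cross_experiment()] (or the output of [simulate_meiosis()]).
#' @param map The [marker_map()] used in the simulation.
#' @param product Nucleus index (1-4).
#' @return Data.frame with `scaffold`, `left_marker`, `right_marker`,
#'   `start_kb`, `end_kb` for each observable crossover.
#' @export
truth_observable_crossovers <- function(truth, map, product) {
  xo <- truth$crossovers
  out <- list()
  if (nrow(xo)) {
    involved <- vapply(xo$chromatids, function(ch) {
      product %in% as.integer(strsplit(ch, "-", fixed = TRUE)[[1L]])
    }, logical(1))
    xo <- xo[involved, , drop = FALSE]
  }
  for (sc in unique(map$scaffold)) {
    sub <- map[map$scaffold == sc, , drop = FALSE]
    pos <- sub$position_kb
    if (nrow(sub) < 2L) next
    x <- xo$position_kb[xo$scaffold == sc]
    x <- x[x > min(pos) & x < max(pos)]
    if (!length(x)) next
    interval <- findInterval(x, pos)
    counts <- table(interval)
    odd <- as.integer(names(counts))[counts %% 2L == 1L]
    for (i in sort(odd)) {
      out[[length(out) + 1L]] <- data.frame(
        scaffold = sc, left_marker = sub$marker[i], right_marker = sub$marker[i + 1L],
        start_kb = pos[i], end_kb = pos[i + 1L], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(scaffold = character(0), left_marker = character(0),
                      right_marker = character(0), start_kb = numeric(0),
                      end_kb = numeric(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$scaffold, res$start_kb), , drop = FALSE]
}
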