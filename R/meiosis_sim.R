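#' Construct a physical marker map
#'
#' Marker positions are 1-based kb coordinates of marker midpoints on named
#' scaffolds; inter-marker intervals are treated as half-open
#' `(pos_i, pos_{i+1}]`.
#'
#' @param scaffold Character vector of scaffold names.
#' @param marker Character vector of unique marker names.
#' @param position_kb Numeric vector of positions in kb (>= 0), strictly
#'   increasing within each scaffold.
#' @return A `data.frame` of class `marker_map` with columns `scaffold`,
#'   `marker`, `position_kb`.
#' @export
marker_map <- function(scaffold, marker, position_kb) {
  if (length(scaffold) != length(marker) || length(marker) != length(position_kb)) {
    stop("scaffold, marker and position_kb must have equal length", call. = FALSE)
  }
  if (length(marker) == 0L) stop("marker map must be non-empty", call. = FALSE)
  if (anyDuplicated(marker)) stop("marker names must be unique", call. = FALSE)
  if (any(is.na(position_kb)) || any(position_kb < 0)) {
    stop("positions must be non-negative kb coordinates", call. = FALSE)
  }
  map <- data.frame(scaffold = as.character(scaffold),
                    marker = as.character(marker),
                    position_kb = as.numeric(position_kb),
                    stringsAsFactors = FALSE)
  map <- map[order(map$scaffold, map$position_kb), , drop = FALSE]
  rownames(map) <- NULL
  for (sc in unique(map$scaffold)) {
    pos <- map$position_kb[map$scaffold == sc]
    if (any(diff(pos) <= 0)) {
      stop(sprintf("positions must be strictly increasing within scaffold '%s'", sc),
           call. = FALSE)
    }
  }
  class(map) <- c("marker_map", "data.frame")
  map
}

#' Simulation configuration for the meiosis/cross simulator
#'
#' Defaults emulate the study cross between a MAT A1 and a MAT A2 red-yeast
#' strain: a baseline autosomal map density of 32 kb/cM, an optional
#' recombination hotspot (the region adjacent to the HD1/HD2 pair recombines
#' at 0.63 kb/cM over 27 kb), sparse gene-conversion tracts, teliospores
#' packaging the four meiotic nuclei into two binucleate basidiospores of
#' which — because germination is asynchronous — usually only one clonal
#' product is recovered (both spores in about 1 teliospore in 8), and rare
#' failed-meiosis diploid products (about 1 in 8).
#'
#' @param kb_per_cM_baseline Baseline physical-to-genetic density, kb per cM.
#' @param hotspots `NULL` or a data.frame with columns `scaffold`, `start_kb`,
#'   `end_kb`, `kb_per_cM`; intervals must not overlap within a scaffold.
#' @param conversion_rate_per_marker Probability, per marker per meiotic
#'   product, that a gene-conversion tract initiates at that marker.
#' @param conversion_tract_mean_kb Mean of the exponential tract length (kb).
#' @param p_recover_both_spores Probability that a product of the second,
#'   later-germinating basidiospore is recovered in addition to the first.
#' @param p_diploid Probability that a teliospore bypasses meiosis and yields
#'   a single diploid product.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(kb_per_cM_baseline = 32,
                       hotspots = NULL,
                       conversion_rate_per_marker = 0.02,
                       conversion_tract_mean_kb = 5,
                       p_recover_both_spores = 1 / 8,
                       p_diploid = 1 / 8) {
  if (!is.numeric(kb_per_cM_baseline) || kb_per_cM_baseline <= 0) {
    stop("'kb_per_cM_baseline' must be > 0", call. = FALSE)
  }
  probs <- c(conversion_rate_per_marker, p_recover_both_spores, p_diploid)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (conversion_tract_mean_kb <= 0) stop("'conversion_tract_mean_kb' must be > 0", call. = FALSE)
  if (!is.null(hotspots)) {
    need <- c("scaffold", "start_kb", "end_kb", "kb_per_cM")
    if (!all(need %in% names(hotspots))) {
      stop("hotspots need columns scaffold, start_kb, end_kb, kb_per_cM", call. = FALSE)
    }
    if (any(hotspots$end_kb <= hotspots$start_kb) || any(hotspots$kb_per_cM <= 0)) {
      stop("malformed hotspot intervals", call. = FALSE)
    }
    for (sc in unique(hotspots$scaffold)) {
      h <- hotspots[hotspots$scaffold == sc, , drop = FALSE]
      h <- h[order(h$start_kb), , drop = FALSE]
      if (nrow(h) > 1L && any(h$start_kb[-1L] < h$end_kb[-nrow(h)])) {
        stop("hotspot intervals overlap within a scaffold", call. = FALSE)
      }
    }
  }
  structure(list(kb_per_cM_baseline = kb_per_cM_baseline,
                 hotspots = hotspots,
                 conversion_rate_per_marker = conversion_rate_per_marker,
                 conversion_tract_mean_kb = conversion_tract_mean_kb,
                 p_recover_both_spores = p_recover_both_spores,
                 p_diploid = p_diploid),
            class = "sim_config")
}

# Piecewise-constant crossover intensity over [lo, hi] on one scaffold.
# Returns a data.frame of segments with per-kb bundle intensity
# 2 / (100 * kb_per_cM): map distance in Morgans equals half the expected
# number of crossovers in the four-chromatid bundle, so that a chromatid
# (involved in each crossover with probability 1/2) accumulates crossovers at
# the Morgan rate and Haldane's RF = (1 - exp(-2 m)) / 2 holds.
crossover_segments <- function(scaffold, lo, hi, config) {
  cuts <- c(lo, hi)
  hs <- config$hotspots
  if (!is.null(hs)) {
    hs <- hs[hs$scaffold == scaffold, , drop = FALSE]
    cuts <- c(cuts, hs$start_kb, hs$end_kb)
  }
  cuts <- sort(unique(pmin(pmax(cuts, lo), hi)))
  if (length(cuts) < 2L) return(NULL)
  seg <- data.frame(start = cuts[-length(cuts)], end = cuts[-1L])
  seg$kb_per_cM <- config$kb_per_cM_baseline
  if (!is.null(hs) && nrow(hs)) {
    mid <- (seg$start + seg$end) / 2
    for (k in seq_len(nrow(hs))) {
      inside <- mid > hs$start_kb[k] & mid < hs$end_kb[k]
      seg$kb_per_cM[inside] <- hs$kb_per_cM[k]
    }
  }
  seg$intensity <- 2 / (100 * seg$kb_per_cM)  # bundle crossovers per kb
  seg$expected <- (seg$end - seg$start) * seg$intensity
  seg
}

# Draw crossover positions for one scaffold: Poisson number with piecewise
# intensity, positions by segment-weighted uniform placement.
draw_crossover_positions <- function(seg) {
  if (is.null(seg)) return(numeric(0))
  n <- stats::rpois(1L, sum(seg$expected))
  if (n == 0L) return(numeric(0))
  idx <- sample.int(nrow(seg), n, replace = TRUE, prob = seg$expected)
  sort(stats::runif(n, seg$start[idx], seg$end[idx]))
}

#' Simulate one meiosis over a marker map
#'
#' Crossovers are placed along each scaffold as a Poisson process on the
#' physical (kb) axis with piecewise-constant genetic rate (no chiasma
#' interference), at the four-chromatid bundle level; each crossover involves
#' one randomly chosen chromatid from each sister pair and exchanges the
#' distal segments reciprocally. Scaffolds assort independently. Gene
#' conversion then acts on each product: with probability
#' `conversion_rate_per_marker` a tract anchored at a marker (exponential
#' length) overwrites the covered markers with the homologous parent's
#' alleles, breaking the 2:2 segregation at those markers only.
#'
#' @param map A [marker_map()].
#' @param config A [sim_config()].
#' @return A list with `products` (4 x n_markers character matrix of
#'   `"P1"`/`"P2"` origin calls, columns named by marker), `crossovers`
#'   (data.frame: scaffold, position_kb, chromatids), and `conversions`
#'   (data.frame: scaffold, start_kb, end_kb, donor, product, n_markers_changed).
#' @export
simulate_meiosis <- function(map, config = sim_config()) {
  stopifnot(inherits(map, "marker_map"), inherits(config, "sim_config"))
  n_mark <- nrow(map)
  scaffolds <- unique(map$scaffold)
  products <- matrix(NA_character_, nrow = 4L, ncol = n_mark,
                     dimnames = list(NULL, map$marker))
  xo_log <- list()
  for (sc in scaffolds) {
    in_sc <- which(map$scaffold == sc)
    pos <- map$position_kb[in_sc]
    xo_pos <- draw_crossover_positions(
      crossover_segments(sc, min(pos), max(pos), config))
    # Strand-walk construction: all crossovers form simultaneously on the
    # aligned bundle of original strands (1,2 = parent-1 sisters; 3,4 =
    # parent-2 sisters). Each crossover joins one randomly chosen strand of
    # each homolog; chromatid c follows its strand from the left and jumps
    # to the partner strand at every crossover involving its current strand,
    # flipping its parental origin there. `on_strand[s]` is the chromatid
    # currently travelling on strand s.
    chrom <- matrix(NA_character_, 4L, length(in_sc))
    on_strand <- 1:4
    parent_of <- c("P1", "P1", "P2", "P2")
    fill_from <- 1L
    pair_log <- character(length(xo_pos))
    for (t in seq_along(xo_pos)) {
      upto <- sum(pos <= xo_pos[t])
      if (upto >= fill_from) {
        for (s in 1:4) chrom[on_strand[s], fill_from:upto] <- parent_of[s]
        fill_from <- upto + 1L
      }
      i <- sample(1:2, 1L)
      j <- sample(3:4, 1L)
      pair_log[t] <- paste(sort(c(on_strand[i], on_strand[j])), collapse = "-")
      tmp <- on_strand[i]
      on_strand[i] <- on_strand[j]
      on_strand[j] <- tmp
    }
    if (fill_from <= length(in_sc)) {
      for (s in 1:4) chrom[on_strand[s], fill_from:length(in_sc)] <- parent_of[s]
    }
    # independent assortment: random bijection of chromatids to nuclei
    nucleus_of <- sample(4L)
    products[nucleus_of, in_sc] <- chrom
    if (length(xo_pos)) {
      remap <- function(pair) {
        ij <- as.integer(strsplit(pair, "-", fixed = TRUE)[[1L]])
        paste(sort(nucleus_of[ij]), collapse = "-")
      }
      xo_log[[sc]] <- data.frame(scaffold = sc, position_kb = xo_pos,
                                 chromatids = vapply(pair_log, remap, ""),
                                 stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  crossovers <- if (length(xo_log)) do.call(rbind, c(xo_log, make.row.names = FALSE)) else
    data.frame(scaffold = character(0), position_kb = numeric(0),
               chromatids = character(0), stringsAsFactors = FALSE)
  # gene-conversion tracts, per product per marker
  conv_log <- list()
  if (config$conversion_rate_per_marker > 0) {
    for (p in 1:4) {
      hit <- which(stats::runif(n_mark) < config$conversion_rate_per_marker)
      for (m in hit) {
        sc <- map$scaffold[m]
        start <- map$position_kb[m]
        end <- start + stats::rexp(1L, 1 / config$conversion_tract_mean_kb)
        covered <- which(map$scaffold == sc &
                           map$position_kb >= start & map$position_kb <= end)
        donor <- if (products[p, m] == "P1") "P2" else "P1"
        changed <- sum(products[p, covered] != donor)
        products[p, covered] <- donor
        conv_log[[length(conv_log) + 1L]] <-
          data.frame(scaffold = sc, start_kb = start, end_kb = end,
                     donor = donor, product = p, n_markers_changed = changed,
                     stringsAsFactors = FALSE)
      }
    }
  }
  conversions <- if (length(conv_log)) do.call(rbind, conv_log) else
    data.frame(scaffold = character(0), start_kb = numeric(0), end_kb = numeric(0),
               donor = character(0), product = integer(0),
               n_markers_changed = integer(0), stringsAsFactors = FALSE)
  list(products = products, crossovers = crossovers, conversions = conversions)
}

#' Package four meiotic nuclei into a teliospore's recovered products
#'
#' With probability `p_diploid` the teliospore bypasses meiosis and yields a
#' single diploid product, heterozygous at every marker. Otherwise the four
#' nuclei are partitioned at random into two binucleate basidiospores; the
#' spore germinating first contributes one clonal product, and with
#' probability `p_recover_both_spores` one product of the later-germinating
#' spore is recovered as well.
#'
#' @param products 4 x n_markers origin matrix from [simulate_meiosis()].
#' @param config A [sim_config()].
#' @return A list with `outcome` (`"DIPLOID"`, `"HAPLOID_ONE_SPORE"` or
#'   `"HAPLOID_BOTH_SPORES"`), `genotypes` (matrix, one row per recovered
#'   product; `"HET"` everywhere for a diploid) and `product_ids` (indices
#'   into the nucleus rows, `NA` for a diploid).
#' @export
package_teliospore <- function(products, config = sim_config()) {
  if (!is.matrix(products) || nrow(products) != 4L) {
    stop("'products' must be the 4-row matrix of one meiosis", call. = FALSE)
  }
  if (stats::runif(1L) < config$p_diploid) {
    g <- matrix("HET", 1L, ncol(products), dimnames = list(NULL, colnames(products)))
    return(list(outcome = "DIPLOID", genotypes = g, product_ids = NA_integer_))
  }
  part <- sample(4L)
  spore1 <- part[1:2]
  spore2 <- part[3:4]
  recovered <- sample(spore1, 1L)
  outcome <- "HAPLOID_ONE_SPORE"
  if (stats::runif(1L) < config$p_recover_both_spores) {
    recovered <- c(recovered, sample(spore2, 1L))
    outcome <- "HAPLOID_BOTH_SPORES"
  }
  list(outcome = outcome,
       genotypes = products[recovered, , drop = FALSE],
       product_ids = recovered)
}

#' Simulate a full cross experiment
#'
#' Simulates `n_teliospores` meioses of a two-parent cross, packages each into
#' recovered products, and clones each recovered product into colonies
#' (mirroring the study design where three to six mitotic clones were typed
#' per germinated teliospore). When two products are recovered from one
#' teliospore, one randomly chosen colony descends from the later-germinating
#' spore and the rest from the first.
#'
#' @param map A [marker_map()].
#' @param config A [sim_config()].
#' @param n_teliospores Number of teliospores (meioses) to simulate.
#' @param colonies_per_teliospore Colonies typed per teliospore.
#' @param seed Integer seed.
#' @return A list with `progeny` (data.frame: `teliospore`, `colony`, then one
#'   origin-call column per marker) and `truth` (per-teliospore list of
#'   crossovers, conversions, outcome, the full 4-product matrix, and the
#'   recovered product ids).
#' @export
simulate_cross_experiment <- function(map, config = sim_config(),
                                      n_teliospores = 8L,
                                      colonies_per_teliospore = 3L,
                                      seed = 1L) {
  stopifnot(inherits(map, "marker_map"), n_teliospores >= 1L,
            colonies_per_teliospore >= 1L)
  set.seed(seed)
  rows <- list()
  truth <- vector("list", n_teliospores)
  for (t in seq_len(n_teliospores)) {
    mei <- simulate_meiosis(map, config)
    pk <- package_teliospore(mei$products, config)
    tid <- sprintf("T%d", t)
    n_col <- colonies_per_teliospore
    colony_product <- rep(1L, n_col)
    if (nrow(pk$genotypes) == 2L && n_col >= 2L) {
      colony_product[sample.int(n_col, 1L)] <- 2L
    }
    for (k in seq_len(n_col)) {
      g <- pk$genotypes[colony_product[k], ]
      rows[[length(rows) + 1L]] <- data.frame(
        teliospore = tid, colony = sprintf("%s.%d", tid, k),
        as.list(g), stringsAsFactors = FALSE, check.names = FALSE)
    }
    truth[[t]] <- list(teliospore = tid,
                       crossovers = mei$crossovers,
                       conversions = mei$conversions,
                       outcome = pk$outcome,
                       products = mei$products,
                       recovered_products = pk$product_ids,
                       colony_product = colony_product)
  }
  progeny <- do.call(rbind, rows)
  names(truth) <- vapply(truth, `[[`, "", "teliospore")
  list(progeny = progeny, truth = truth)
}

#' Marker map emulating the study cross
#'
#' A synthetic stand-in for the marker panel genotyped in the study cross:
#' five markers on the HD-bearing scaffold (the HD1/HD2 pair with the 27-kb
#' recombination hotspot on its MIP side, delimited by a neighbouring
#' marker), eight markers plus the pheromone receptor on the STE3-bearing
#' scaffold, and nine autosomal markers spread over four scaffolds at
#' 525-1870 kb spacings. The two MAT scaffolds are listed separately, the
#' way the reference assembly presents them; [mat_cross_map()] gives the
#' joined single-chromosome layout used to simulate the cross. Positions are
#' plausible round numbers, not the (unpublished) real coordinates.
#'
#' @return A [marker_map()].
#' @export
example_marker_map <- function() {
  marker_map(
    scaffold = c(rep("scaffold_7", 5),
                 rep("scaffold_9", 9),
                 rep("scaffold_1", 3), rep("scaffold_2", 2),
                 rep("scaffold_3", 2), rep("scaffold_10", 2)),
    marker = c("MIP", "RibL18ae", "HSP70", "HD", "IsocL",
               "PAN6", "NGP1", "AKOR2", "RNAPOL", "LSm7", "STE3", "RibL6",
               "KinC", "GEFsec7",
               "aut1a", "aut1b", "aut1c", "aut2a", "aut2b",
               "aut3a", "aut3b", "aut10a", "aut10b"),
    position_kb = c(10, 230, 250, 277, 400,
                    100, 340, 560, 700, 795, 800, 805, 980, 1200,
                    50, 575, 1920, 100, 1020,
                    200, 1170, 80, 945)
  )
}

#' Hotspot specification matching the default map
#'
#' The 27-kb interval adjacent to the HD1/HD2 pair (on its MIP side, away
#' from the receptor region) recombining at 0.63 kb/cM.
#'
#' @return A one-row hotspot data.frame for [sim_config()].
#' @export
example_hotspots <- function() {
  data.frame(scaffold = "scaffold_7", start_kb = 250, end_kb = 277,
             kb_per_cM = 0.63, stringsAsFactors = FALSE)
}

#' Joined single-chromosome map of the pseudo-bipolar MAT region
#'
#' The same markers as [example_marker_map()], but with the two MAT-bearing
#' scaffolds joined into one chromosome at the IsocL-PAN6 junction (the
#' orientation the segregation data support), so that the pheromone receptor
#' and HD1/HD2 regions are physically linked and recombine only through the
#' intervening interval. Autosomal scaffolds are unchanged.
#'
#' @return A [marker_map()].
#' @export
mat_cross_map <- function() {
  base <- example_marker_map()
  mat <- base$scaffold %in% c("scaffold_7", "scaffold_9")
  joined <- base[mat, , drop = FALSE]
  joined$position_kb[joined$scaffold == "scaffold_9"] <-
    joined$position_kb[joined$scaffold == "scaffold_9"] + 400
  joined$scaffold <- "MAT_chr"
  out <- rbind(joined, base[!mat, , drop = FALSE])
  marker_map(out$scaffold, out$marker, out$position_kb)
}

#' Rate heterogeneity of the joined MAT chromosome
#'
#' The 27-kb hotspot (0.63 kb/cM) on the MIP side of the HD1/HD2 pair, and a
#' 10-fold suppressed interval (320 kb/cM) between HD1/HD2 and PAN6 spanning
#' the scaffold junction, where the segregation data show no crossovers.
#'
#' @return A hotspot data.frame for [sim_config()].
#' @export
mat_cross_hotspots <- function() {
  data.frame(scaffold = c("MAT_chr", "MAT_chr"),
             start_kb = c(250, 277), end_kb = c(277, 500),
             kb_per_cM = c(0.63, 320), stringsAsFactors = FALSE)
}

#' Synthesize a codon alignment of diverging alleles
#'
#' Evolves `n_alleles` coding sequences independently from one random
#' stop-free ancestor by single-base codon substitutions. The gene is
#' partitioned into domains, each with a target dN/dS (omega): proposed
#' nonsynonymous changes are accepted with probability `min(1, omega)` and
#' synonymous changes with probability `min(1, 1/omega)`, so the realized
#' pairwise ratio approximates the target. Substitutions creating stop codons
#' are rejected; there are no indels. This emulates a homeodomain
#' transcription-factor gene with a hypervariable N-terminal self/non-self
#' recognition domain under diversifying selection and conserved homeodomain
#' and C-terminal domains.
#'
#' @param n_alleles Number of alleles to evolve.
#' @param domain_spec Data.frame with columns `name`, `length_codons`,
#'   `omega`, `subs_per_codon` (expected proposed substitutions per codon per
#'   allele lineage).
#' @param seed Integer seed.
#' @return A named character vector of aligned coding sequences, with a
#'   `domains` attribute (data.frame: name, start_codon, end_codon).
#' @export
synthesize_coding_alignment <- function(n_alleles = 9L,
                                        domain_spec = default_domain_spec(),
                                        seed = 1L) {
  stopifnot(n_alleles >= 1L)
  need <- c("name", "length_codons", "omega", "subs_per_codon")
  if (!all(need %in% names(domain_spec))) {
    stop("domain_spec needs columns name, length_codons, omega, subs_per_codon",
         call. = FALSE)
  }
  if (any(domain_spec$length_codons < 1L)) stop("invalid codon length", call. = FALSE)
  set.seed(seed)
  code <- genetic_code_table()
  sense <- names(code)[code != "*"]
  L <- sum(domain_spec$length_codons)
  ancestor <- sample(sense, L, replace = TRUE)
  ends <- cumsum(domain_spec$length_codons)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  domains <- data.frame(name = domain_spec$name, start_codon = starts,
                        end_codon = ends, stringsAsFactors = FALSE)
  bases <- c("A", "C", "G", "T")
  alleles <- matrix(rep(ancestor, n_alleles), nrow = n_alleles, byrow = TRUE)
  for (a in seq_len(n_alleles)) {
    for (d in seq_len(nrow(domain_spec))) {
      idx <- starts[d]:ends[d]
      omega <- domain_spec$omega[d]
      n_events <- stats::rpois(1L, domain_spec$subs_per_codon[d] * length(idx))
      for (e in seq_len(n_events)) {
        ci <- sample(idx, 1L)
        codon <- alleles[a, ci]
        pos <- sample(3L, 1L)
        old_base <- substr(codon, pos, pos)
        new_base <- sample(setdiff(bases, old_base), 1L)
        new_codon <- codon
        substr(new_codon, pos, pos) <- new_base
        if (code[[new_codon]] == "*") next
        syn <- code[[new_codon]] == code[[codon]]
        p_accept <- if (syn) min(1, 1 / omega) else min(1, omega)
        if (stats::runif(1L) < p_accept) alleles[a, ci] <- new_codon
      }
    }
  }
  seqs <- apply(alleles, 1L, paste, collapse = "")
  names(seqs) <- sprintf("allele_%02d", seq_len(n_alleles))
  attr(seqs, "domains") <- domains
  seqs
}

#' Default three-domain gene specification
#'
#' N-terminal hypervariable domain under diversifying selection (omega 1.5),
#' conserved homeodomain (omega 0.1) and C-terminal domain (omega 0.3), with
#' enough proposed substitutions for informative pairwise comparisons without
#' saturating synonymous sites.
#'
#' @return A data.frame usable as `domain_spec` in
#'   [synthesize_coding_alignment()].
#' @export
default_domain_spec <- function() {
  data.frame(name = c("N-terminal", "homeodomain", "C-terminal"),
             length_codons = c(80L, 60L, 60L),
             omega = c(1.5, 0.1, 0.3),
             subs_per_codon = c(0.5, 0.5, 0.5),
             stringsAsFactors = FALSE)
}
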