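#' Summarize receptor-HD allele association in a strain table
#'
#' Counts distinct pheromone-receptor and HD1/HD2 alleles among haploid
#' strains and records, for each receptor allele, the set of HD alleles
#' observed with it. HD alleles seen with both receptors (`shared_hd_alleles`)
#' indicate independent segregation; receptor-HD combinations carried by a
#' single strain while the HD allele otherwise travels with the other
#' receptor (`recombinant_pairs`) indicate cohesion breakage. Self-fertile or
#' diploid records (including strains carrying two receptor alleles, written
#' `"A1/A2"`) are excluded from the haploid counts and reported separately.
#'
#' @param strains Data.frame with columns `strain`, `species`, `receptor`,
#'   `hd`, `behaviour` (`A1`, `A2`, `SELF_FERTILE`, `ASEXUAL` or `UNKNOWN`).
#' @return A list of class `association_summary`: `n_strains`,
#'   `n_haploid`, `n_pr_alleles`, `n_hd_alleles`, `hd_alleles_per_receptor`
#'   (named list of character vectors), `shared_hd_alleles`,
#'   `recombinant_pairs` (data.frame), `non_haploid` (excluded records).
#' @export
association_summary <- function(strains) {
  need <- c("strain", "species", "receptor", "hd", "behaviour")
  if (!all(need %in% names(strains))) {
    stop("strain table needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (!nrow(strains)) stop("empty strain table", call. = FALSE)
  if (anyDuplicated(strains$strain)) stop("strain ids must be unique", call. = FALSE)
  two_receptors <- grepl("/", strains$receptor, fixed = TRUE)
  haploid <- !(strains$behaviour %in% c("SELF_FERTILE")) & !two_receptors
  hap <- strains[haploid, , drop = FALSE]
  if (!nrow(hap)) stop("no haploid records", call. = FALSE)
  receptors <- sort(unique(hap$receptor))
  hd_per_receptor <- lapply(receptors, function(r) sort(unique(hap$hd[hap$receptor == r])))
  names(hd_per_receptor) <- receptors
  shared <- character(0)
  if (length(receptors) >= 2L) {
    all_hd <- unique(unlist(hd_per_receptor))
    shared <- all_hd[vapply(all_hd, function(h) {
      sum(vapply(hd_per_receptor, function(s) h %in% s, logical(1))) >= 2L
    }, logical(1))]
  }
  # a receptor-HD pair is recombinant when the HD allele's majority
  # association is with a different receptor and the pair is seen in at most
  # as many strains as the majority pairing
  combos <- unique(hap[, c("receptor", "hd")])
  rec_rows <- lapply(seq_len(nrow(combos)), function(k) {
    h <- combos$hd[k]; r <- combos$receptor[k]
    with_h <- hap[hap$hd == h, , drop = FALSE]
    tab <- table(with_h$receptor)
    major <- names(tab)[which.max(tab)]
    if (major != r && tab[[r]] < tab[[major]]) combos[k, , drop = FALSE] else NULL
  })
  rec_rows <- rec_rows[!vapply(rec_rows, is.null, logical(1))]
  recombinant_pairs <- if (length(rec_rows)) {
    res <- do.call(rbind, rec_rows); rownames(res) <- NULL; res
  } else {
    data.frame(receptor = character(0), hd = character(0), stringsAsFactors = FALSE)
  }
  structure(list(n_strains = nrow(strains),
                 n_haploid = nrow(hap),
                 n_pr_alleles = length(receptors),
                 n_hd_alleles = length(unique(hap$hd)),
                 hd_alleles_per_receptor = hd_per_receptor,
                 shared_hd_alleles = shared,
                 recombinant_pairs = recombinant_pairs,
                 non_haploid = strains[!haploid, , drop = FALSE]),
            class = "association_summary")
}

#' @export
print.association_summary <- function(x, ...) {
  cat(sprintf("<allele survey: %d strains (%d haploid), %d PR alleles, %d HD alleles>\n",
              x$n_strains, x$n_haploid, x$n_pr_alleles, x$n_hd_alleles))
  for (r in names(x$hd_alleles_per_receptor)) {
    cat(sprintf("  %s: %d HD alleles\n", r, length(x$hd_alleles_per_receptor[[r]])))
  }
  if (length(x$shared_hd_alleles)) {
    cat("  shared HD alleles:", paste(x$shared_hd_alleles, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Classify a mating-system architecture from an allele survey
#'
#' Pattern-based classification: `BIPOLAR` when exactly two HD alleles exist,
#' one per receptor; `TETRAPOLAR` when some HD allele is seen with both
#' receptors (independent segregation); `PSEUDO_BIPOLAR` when more than two
#' HD alleles exist, each strictly associated with a single receptor. Surveys
#' of fewer than `min_haploid` haploid strains return `UNDETERMINED` to avoid
#' over-claiming from a thin sample.
#'
#' @param summary An [association_summary()].
#' @param min_haploid Minimum haploid sample size.
#' @return One of `"BIPOLAR"`, `"TETRAPOLAR"`, `"PSEUDO_BIPOLAR"`,
#'   `"UNDETERMINED"`.
#' @export
classify_system <- function(summary, min_haploid = 4L) {
  stopifnot(inherits(summary, "association_summary"))
  if (summary$n_haploid < min_haploid) return("UNDETERMINED")
  per <- summary$hd_alleles_per_receptor
  if (length(summary$shared_hd_alleles)) return("TETRAPOLAR")
  if (summary$n_hd_alleles == 2L && length(per) == 2L &&
      all(lengths(per) == 1L)) {
    return("BIPOLAR")
  }
  if (summary$n_hd_alleles > 2L) return("PSEUDO_BIPOLAR")
  "UNDETERMINED"
}
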