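#' Construct a haploid mating type
#'
#' A haploid strain's mating type is the pair of its pheromone receptor (PR)
#' allele and its HD1/HD2 homeodomain allele. The two fields are independent:
#' recombinant combinations not seen among natural isolates (such as an A1
#' receptor carried with an HD allele normally associated with A2 strains)
#' are representable.
#'
#' @param receptor_allele Character scalar, e.g. `"A1"` or `"A2"`.
#' @param hd_allele Character scalar, e.g. `"A1-3"` or `"A2-15"`.
#' @return An object of class `mating_type`.
#' @examples
#' mating_type("A1", "A2-15")  # a receptor-HD recombinant
#' @export
mating_type <- function(receptor_allele, hd_allele) {
  if (!is.character(receptor_allele) || length(receptor_allele) != 1L ||
      is.na(receptor_allele) || !nzchar(receptor_allele)) {
    stop("'receptor_allele' must be a non-empty character scalar", call. = FALSE)
  }
  if (!is.character(hd_allele) || length(hd_allele) != 1L ||
      is.na(hd_allele) || !nzchar(hd_allele)) {
    stop("'hd_allele' must be a non-empty character scalar", call. = FALSE)
  }
  structure(list(receptor_allele = receptor_allele, hd_allele = hd_allele),
            class = "mating_type")
}

#' @export
print.mating_type <- function(x, ...) {
  cat(sprintf("<mating type: PR %s / HD %s>\n", x$receptor_allele, x$hd_allele))
  invisible(x)
}

as_mating_type <- function(x) {
  if (inherits(x, "mating_type")) return(x)
  if (is.character(x) && length(x) == 2L) return(mating_type(x[[1L]], x[[2L]]))
  stop("cannot interpret input as a mating type", call. = FALSE)
}

#' Outcome of a cross between two haploid mating types
#'
#' Implements the two-checkpoint compatibility rule: cell-cell recognition
#' requires different pheromone receptor alleles, and progression through the
#' sexual cycle (dikaryotic mycelium with clamp connections, teliospores)
#' additionally requires different HD1/HD2 alleles, whose products must
#' heterodimerize across allele classes. Strains sharing the receptor allele
#' fail to initiate filamentous growth at all; strains differing at the
#' receptor but sharing the HD allele show pheromone-driven pseudohyphal
#' growth only.
#'
#' @param a,b `mating_type` objects (or length-2 character vectors
#'   `c(receptor, hd)`).
#' @return An object of class `cross_outcome`: a list with `category`
#'   (`"COMPLETE"`, `"PHEROMONE_ONLY"` or `"NONE"`), `mycelium_with_clamps`
#'   and `teliospores` (logicals).
#' @examples
#' cross_outcome(mating_type("A1", "A2-15"), mating_type("A2", "A1-3"))
#' @export
cross_outcome <- function(a, b) {
  a <- as_mating_type(a)
  b <- as_mating_type(b)
  pr_differ <- a$receptor_allele != b$receptor_allele
  hd_differ <- a$hd_allele != b$hd_allele
  category <- if (!pr_differ) "NONE" else if (hd_differ) "COMPLETE" else "PHEROMONE_ONLY"
  structure(list(category = category,
                 mycelium_with_clamps = category == "COMPLETE",
                 teliospores = category == "COMPLETE"),
            class = "cross_outcome")
}

#' @export
print.cross_outcome <- function(x, ...) {
  cat(sprintf("<cross outcome: %s | mycelium with clamps: %s | teliospores: %s>\n",
              x$category,
              if (x$mycelium_with_clamps) "+" else "-",
              if (x$teliospores) "+" else "-"))
  invisible(x)
}

#' Specify a MAT architecture for sib-mating calculations
#'
#' The three architectures differ only in the recombination fraction `r`
#' between the pheromone receptor and HD regions: `r = 0` for a fully linked
#' bipolar locus, `r = 0.5` for unlinked (tetrapolar) regions, and
#' `0 < r < 0.5` for a pseudo-bipolar locus where recombination between the
#' regions is infrequent but not suppressed.
#'
#' @param kind `"BIPOLAR"`, `"TETRAPOLAR"` or `"PSEUDO_BIPOLAR"`.
#' @param r Recombination fraction between the PR and HD regions. Defaults to
#'   0 for bipolar and 0.5 for tetrapolar; required (strictly inside (0, 0.5))
#'   for pseudo-bipolar.
#' @param n_pr_alleles,n_hd_alleles Population-level allele counts (>= 2).
#'   They do not affect within-meiosis sib-mating odds (one meiosis segregates
#'   at most two alleles per region) and are carried for population surveys.
#' @return An object of class `mating_system_spec`.
#' @export
mating_system_spec <- function(kind = c("BIPOLAR", "TETRAPOLAR", "PSEUDO_BIPOLAR"),
                               r = NULL, n_pr_alleles = 2L, n_hd_alleles = 2L) {
  kind <- match.arg(kind)
  if (is.null(r)) {
    r <- switch(kind, BIPOLAR = 0, TETRAPOLAR = 0.5,
                PSEUDO_BIPOLAR = stop("'r' is required for a pseudo-bipolar spec",
                                      call. = FALSE))
  }
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 0 || r > 0.5) {
    stop("'r' must be a single number in [0, 0.5]", call. = FALSE)
  }
  ok <- switch(kind,
               BIPOLAR = r == 0,
               TETRAPOLAR = r == 0.5,
               PSEUDO_BIPOLAR = r > 0 && r < 0.5)
  if (!ok) {
    stop(sprintf("r = %g is inconsistent with a %s architecture", r, kind),
         call. = FALSE)
  }
  if (n_pr_alleles < 2L || n_hd_alleles < 2L) {
    stop("allele counts must be >= 2", call. = FALSE)
  }
  structure(list(kind = kind, r = r,
                 n_pr_alleles = as.integer(n_pr_alleles),
                 n_hd_alleles = as.integer(n_hd_alleles)),
            class = "mating_system_spec")
}

# Meiotic genotype frequency distribution for a cross heterozygous at both
# regions (PR alleles p1/p2, HD alleles h1/h2, parental phase p1-h1 / p2-h2):
# the two parental products occur at (1-r)/2 each, the two recombinants at
# r/2 each.
sib_genotype_freqs <- function(spec) {
  r <- spec$r
  data.frame(pr = c("p1", "p2", "p1", "p2"),
             hd = c("h1", "h2", "h2", "h1"),
             freq = c((1 - r) / 2, (1 - r) / 2, r / 2, r / 2),
             stringsAsFactors = FALSE)
}

#' Sib-mating (inbreeding) compatibility probability
#'
#' Probability that two spores drawn independently (with replacement) from the
#' meiotic genotype frequency distribution of one cross heterozygous at both
#' MAT regions can complete the sexual cycle, i.e. differ at both the receptor
#' and the HD region. Computed by enumerating the 16 ordered genotype pairs;
#' algebraically this equals ((1-r)^2 + r^2) / 2, which is 1/2 for a bipolar
#' locus (r = 0), 1/4 for a tetrapolar system (r = 1/2), and strictly in
#' between for a pseudo-bipolar locus.
#'
#' @param spec A [mating_system_spec()].
#' @return A single probability.
#' @examples
#' sib_compatibility_probability(mating_system_spec("BIPOLAR"))     # 0.5
#' sib_compatibility_probability(mating_system_spec("TETRAPOLAR"))  # 0.25
#' @export
sib_compatibility_probability <- function(spec) {
  stopifnot(inherits(spec, "mating_system_spec"))
  g <- sib_genotype_freqs(spec)
  prob <- 0
  for (i in seq_len(nrow(g))) {
    for (j in seq_len(nrow(g))) {
      if (g$pr[i] != g$pr[j] && g$hd[i] != g$hd[j]) {
        prob <- prob + g$freq[i] * g$freq[j]
      }
    }
  }
  prob
}

#' Monte-Carlo estimate of the sib-mating compatibility probability
#'
#' Draws `n_pairs` independent spore pairs from the meiotic genotype
#' distribution and scores each pair with [cross_outcome()]; a stochastic
#' check of the closed form in [sib_compatibility_probability()].
#'
#' @param spec A [mating_system_spec()].
#' @param n_pairs Number of spore pairs to draw (>= 1).
#' @param seed Integer seed for reproducibility.
#' @return A list with `estimate`, `se` (binomial standard error) and
#'   `n_pairs`.
#' @export
simulate_sib_matings <- function(spec, n_pairs = 1e5, seed = 1L) {
  stopifnot(inherits(spec, "mating_system_spec"))
  if (!is.numeric(n_pairs) || n_pairs < 1) stop("'n_pairs' must be >= 1", call. = FALSE)
  n_pairs <- as.integer(n_pairs)
  set.seed(seed)
  g <- sib_genotype_freqs(spec)
  i <- sample.int(4L, n_pairs, replace = TRUE, prob = g$freq)
  j <- sample.int(4L, n_pairs, replace = TRUE, prob = g$freq)
  compatible <- vapply(seq_len(n_pairs), function(k) {
    cross_outcome(mating_type(g$pr[i[k]], g$hd[i[k]]),
                  mating_type(g$pr[j[k]], g$hd[j[k]]))$category == "COMPLETE"
  }, logical(1))
  p_hat <- mean(compatible)
  list(estimate = p_hat,
       se = sqrt(p_hat * (1 - p_hat) / n_pairs),
       n_pairs = n_pairs)
}
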